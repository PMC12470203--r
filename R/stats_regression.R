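# Ordinary linear regression with a confidence band, and the discontinuous
# two-phase (threshold) model: two independent OLS lines either side of a
# breakpoint, with an optional residual-sum-of-squares grid search for the
# breakpoint.

#' Ordinary least-squares fit with confidence band
#'
#' Simple linear regression of `y` on `x` with a pointwise confidence band
#' for the conditional mean.
#'
#' @param x,y Numeric vectors; at least 3 complete pairs and non-constant
#'   `x`.
#' @param conf Band coverage (default 0.95).
#' @return An object of class `linear_fit` with elements `slope`,
#'   `intercept`, `r_squared`, `p_value` (two-sided slope test), `conf`,
#'   `n` and the underlying `stats::lm` model.
#' @export
#' @examples
#' f <- linear_fit(1:10, 3 * (1:10) + 1)
#' coef(f)
linear_fit <- function(x, y, conf = 0.95) {
  ok <- complete.cases(x, y)
  d <- data.frame(x = as.numeric(x)[ok], y = as.numeric(y)[ok])
  if (nrow(d) < 3)
    stop("linear_fit: need at least 3 complete observations", call. = FALSE)
  if (sd(d$x) == 0) stop("linear_fit: 'x' is constant", call. = FALSE)
  fit <- lm(y ~ x, data = d)
  sm <- suppressWarnings(summary(fit))
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 conf = conf, n = nrow(d), model = fit),
            class = "linear_fit")
}

#' @export
coef.linear_fit <- function(object, ...)
  c(intercept = object$intercept, slope = object$slope)

#' @rdname linear_fit
#' @param object A `linear_fit`.
#' @param newdata Predictor values; defaults to the observed `x`.
#' @param ... Unused.
#' @export
predict.linear_fit <- function(object, newdata = NULL, ...) {
  nd <- if (is.null(newdata)) object$model$model["x"]
        else data.frame(x = as.numeric(newdata))
  as.data.frame(predict(object$model, nd, interval = "confidence",
                        level = object$conf))
}

#' @export
print.linear_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Linear fit (n = %d): y = %s + %s x, R2 = %s, slope p = %s\n",
              x$n, format(x$intercept, digits = digits),
              format(x$slope, digits = digits),
              format(x$r_squared, digits = digits),
              format(x$p_value, digits = digits)))
  invisible(x)
}

#' @export
plot.linear_fit <- function(x, ...) {
  d <- x$model$model
  plot(d$x, d$y, xlab = "x", ylab = "y", ...)
  xs <- seq(min(d$x), max(d$x), length.out = 100)
  pr <- predict(x, xs)
  lines(xs, pr$fit)
  lines(xs, pr$lwr, lty = 2)
  lines(xs, pr$upr, lty = 2)
  invisible(x)
}

# fit one segment and return its describing statistics
.segment_stats <- function(x, y) {
  d <- data.frame(x = x, y = y)
  fit <- lm(y ~ x, data = d)
  sm <- suppressWarnings(summary(fit))
  p <- if (nrow(sm$coefficients) >= 2) sm$coefficients[2, 4] else NA_real_
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared, p_value = p, n = nrow(d),
       sse = sum(fit$residuals^2), fit = fit)
}

#' Two-phase (threshold) regression
#'
#' Fits a discontinuous two-phase linear model: independent OLS lines below
#' (`x < breakpoint`) and above (`x >= breakpoint`) a threshold in the
#' predictor.  With `breakpoint = NULL` the threshold is searched over the
#' midpoints between consecutive sorted unique `x` values, selecting the
#' candidate minimizing the total residual sum of squares; ties break
#' toward the smaller breakpoint.  Every admissible split must leave at
#' least `min_points` observations per side.
#'
#' This is the model behind threshold effects such as the switch of the
#' Se-Cd relationship in tea tree fibrous roots around 2.0 mg kg^-1 Se:
#' a positive Cd-Se association below the threshold and an antagonistic
#' (negative) one above it.
#'
#' @param x Predictor (e.g. fibrous-root Se, mg kg^-1).
#' @param y Response (e.g. fibrous-root Cd, mg kg^-1, or its soil-
#'   normalized enrichment coefficient).
#' @param breakpoint Fixed threshold in predictor units, or `NULL` to
#'   search.
#' @param min_points Minimum observations per segment (default 3).
#' @return An object of class `threshold_fit`: `breakpoint`, per-segment
#'   lists `below` / `above` (`slope`, `intercept`, `r_squared`, `p_value`,
#'   `n`), `sse` (total), `search_grid` (empty if fixed) and the segment
#'   `lm` fits.
#' @export
#' @examples
#' set.seed(1)
#' x <- runif(60, 0.5, 3.5)
#' y <- ifelse(x < 2, 1 + 0.4 * (x - 2), 1 - 0.3 * (x - 2)) + rnorm(60, 0, 0.05)
#' threshold_fit(x, y)
threshold_fit <- function(x, y, breakpoint = NULL, min_points = 3) {
  ok <- complete.cases(x, y)
  x <- as.numeric(x)[ok]; y <- as.numeric(y)[ok]
  if (length(x) < 2 * min_points)
    stop("threshold_fit: need at least ", 2 * min_points, " observations",
         call. = FALSE)
  split_at <- function(bp) {
    below <- x < bp
    if (sum(below) < min_points || sum(!below) < min_points) return(NULL)
    lo <- .segment_stats(x[below], y[below])
    hi <- .segment_stats(x[!below], y[!below])
    list(below = lo, above = hi, sse = lo$sse + hi$sse)
  }
  if (!is.null(breakpoint)) {
    res <- split_at(breakpoint)
    if (is.null(res))
      stop(sprintf(paste0("threshold_fit: breakpoint %g leaves fewer than ",
                          "%d points on one side"), breakpoint, min_points),
           call. = FALSE)
    grid <- numeric(0)
    bp <- breakpoint
  } else {
    ux <- sort(unique(x))
    grid <- (head(ux, -1) + tail(ux, -1)) / 2
    fits <- lapply(grid, split_at)
    keep <- !vapply(fits, is.null, logical(1))
    if (!any(keep))
      stop("threshold_fit: no candidate breakpoint leaves ", min_points,
           " points per segment", call. = FALSE)
    grid <- grid[keep]; fits <- fits[keep]
    sses <- vapply(fits, `[[`, numeric(1), "sse")
    best <- which.min(sses)     # grid ascending => first minimum = smallest bp
    res <- fits[[best]]
    bp <- grid[best]
  }
  keep_stats <- function(s) s[c("slope", "intercept", "r_squared",
                                "p_value", "n")]
  structure(list(breakpoint = bp,
                 below = keep_stats(res$below), above = keep_stats(res$above),
                 sse = res$sse, search_grid = grid,
                 fits = list(below = res$below$fit, above = res$above$fit),
                 data = data.frame(x = x, y = y)),
            class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, digits = 4, ...) {
  mode <- if (length(x$search_grid)) "searched" else "fixed"
  cat(sprintf("Two-phase fit: breakpoint %s (%s), total SSE %s\n",
              format(x$breakpoint, digits = digits), mode,
              format(x$sse, digits = digits)))
  seg <- function(s, lab)
    cat(sprintf("  %s (n = %d): slope %s, intercept %s, R2 %s, p %s\n",
                lab, s$n, format(s$slope, digits = digits),
                format(s$intercept, digits = digits),
                format(s$r_squared, digits = digits),
                format(s$p_value, digits = digits)))
  seg(x$below, "below")
  seg(x$above, "above")
  invisible(x)
}

#' @export
summary.threshold_fit <- function(object, ...) {
  data.frame(segment = c("below", "above"),
             slope = c(object$below$slope, object$above$slope),
             intercept = c(object$below$intercept, object$above$intercept),
             r2 = c(object$below$r_squared, object$above$r_squared),
             p = c(object$below$p_value, object$above$p_value),
             n = c(object$below$n, object$above$n),
             breakpoint = object$breakpoint)
}

#' @export
coef.threshold_fit <- function(object, ...) {
  matrix(c(object$below$intercept, object$below$slope,
           object$above$intercept, object$above$slope),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("below", "above"), c("intercept", "slope")))
}

#' @rdname threshold_fit
#' @param object A `threshold_fit`.
#' @param newdata Predictor values; defaults to the observed `x`.
#' @param ... Unused.
#' @export
predict.threshold_fit <- function(object, newdata = NULL, ...) {
  xs <- if (is.null(newdata)) object$data$x else as.numeric(newdata)
  below <- xs < object$breakpoint
  out <- numeric(length(xs))
  out[below] <- object$below$intercept + object$below$slope * xs[below]
  out[!below] <- object$above$intercept + object$above$slope * xs[!below]
  out
}

#' @export
plot.threshold_fit <- function(x, ...) {
  plot(x$data$x, x$data$y, xlab = "x", ylab = "y", ...)
  bp <- x$breakpoint
  rngs <- list(c(min(x$data$x), bp), c(bp, max(x$data$x)))
  segs <- list(x$below, x$above)
  for (i in 1:2) {
    xs <- seq(rngs[[i]][1], rngs[[i]][2], length.out = 50)
    lines(xs, segs[[i]]$intercept + segs[[i]]$slope * xs)
  }
  abline(v = bp, lty = 3)
  invisible(x)
}
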
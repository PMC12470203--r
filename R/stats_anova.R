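# One-way ANOVA with Fisher's protected LSD and a compact letter display
# built by insert-and-absorb.  Two entry points share the post-hoc core:
# anova_lsd() on raw replicate data (omnibus F via stats::lm/anova) and
# anova_from_summary() on published mean / sd / n tables (exact algebra).

# compact letter display by insert-and-absorb over the significance graph;
# `sig` is a logical matrix over groups already ordered by descending mean
.cld_insert_absorb <- function(sig) {
  g <- nrow(sig)
  cols <- list(rep(TRUE, g))
  if (g > 1) for (i in 1:(g - 1)) for (j in (i + 1):g) if (sig[i, j]) {
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (col[i] && col[j]) {
        c2 <- col
        col[j] <- FALSE; c2[i] <- FALSE        # insert: split the pair
        cols[[ci]] <- col
        cols[[length(cols) + 1L]] <- c2
      }
    }
    cols <- unique(cols)
    # absorb: drop any column whose member set is a proper subset of another
    drop <- rep(FALSE, length(cols))
    for (a in seq_along(cols)) for (b in seq_along(cols)) {
      if (a == b || drop[a] || drop[b]) next
      if (all(cols[[b]][cols[[a]]]) && sum(cols[[b]]) > sum(cols[[a]]))
        drop[a] <- TRUE
    }
    cols <- cols[!drop]
  }
  ord <- order(vapply(cols, function(cc) which(cc)[1], numeric(1)))
  cols <- cols[ord]
  vapply(seq_len(g), function(i)
    paste(letters[which(vapply(cols, `[`, logical(1), i))], collapse = ""),
    "")
}

# shared post-hoc: pairwise LSD decisions + letters; protected by the
# omnibus p-value (no pairwise test is declared significant unless p < alpha)
.lsd_core <- function(labels, means, ns, mse, dfe, Fv, pv, alpha) {
  ord <- order(means, decreasing = TRUE)
  labels <- labels[ord]; means <- means[ord]; ns <- ns[ord]
  g <- length(means)
  sig <- matrix(FALSE, g, g)
  lsd <- matrix(NA_real_, g, g)
  if (is.finite(pv) && pv < alpha && g > 1) {
    tcrit <- if (dfe > 0) qt(1 - alpha / 2, dfe) else Inf
    for (i in 1:(g - 1)) for (j in (i + 1):g) {
      lsd[i, j] <- lsd[j, i] <- tcrit * sqrt(mse * (1 / ns[i] + 1 / ns[j]))
      sig[i, j] <- sig[j, i] <- abs(means[i] - means[j]) > lsd[i, j]
    }
  }
  structure(list(groups = labels, means = setNames(means, labels),
                 n = setNames(ns, labels), F = Fv, p = pv,
                 mse = mse, df_error = dfe, alpha = alpha,
                 significant = sig, lsd = lsd,
                 letters = setNames(.cld_insert_absorb(sig), labels)),
            class = "lsd_result")
}

#' One-way ANOVA with protected LSD letters
#'
#' Omnibus one-way ANOVA followed, only when the F test is significant at
#' `alpha` (Fisher's protected LSD), by all pairwise least-significant-
#' difference tests using the pooled error mean square and its degrees of
#' freedom.  Group letters come from an insert-and-absorb compact letter
#' display over the pairwise decisions, with groups ordered by descending
#' mean so the largest mean carries `"a"`.  If the omnibus test is not
#' significant every group shares `"a"`.
#'
#' @param values Numeric response.
#' @param groups Group labels, same length; at least two groups, each with
#'   at least two observations.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `lsd_result`: group means (descending), `n`,
#'   omnibus `F` and `p`, pooled `mse` and `df_error`, pairwise decision
#'   matrices and the per-group `letters`.
#' @export
#' @examples
#' anova_lsd(c(1, 1.1, 0.9, 9.8, 10, 10.2), rep(c("lo", "hi"), each = 3))
anova_lsd <- function(values, groups, alpha = 0.05) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  g <- factor(groups[ok])
  ns <- tabulate(g)
  if (nlevels(g) < 2)
    stop("anova_lsd: need at least two groups", call. = FALSE)
  if (any(ns < 2))
    stop("anova_lsd: every group needs n >= 2, offending group(s): ",
         paste(levels(g)[ns < 2], collapse = ", "), call. = FALSE)
  fit <- lm(values ~ g)
  an <- anova(fit)
  Fv <- an[["F value"]][1]
  pv <- an[["Pr(>F)"]][1]
  mse <- an[["Mean Sq"]][2]
  dfe <- an[["Df"]][2]
  if (!is.finite(Fv)) {    # zero within-group variance
    ssb <- an[["Sum Sq"]][1]
    if (ssb > 0) { Fv <- Inf; pv <- 0 } else { Fv <- NA_real_; pv <- 1 }
  }
  means <- tapply(values, g, mean)
  .lsd_core(levels(g), as.numeric(means), ns, mse, dfe, Fv, pv, alpha)
}

#' One-way ANOVA with LSD letters from summary statistics
#'
#' Reconstructs the between- and within-group sums of squares exactly from
#' per-group means, standard deviations and sizes (no resampling), then
#' proceeds as [anova_lsd()].  This makes published mean +/- sd tables
#' amenable to the same protected-LSD letter display; on summaries of raw
#' data it is algebraically identical to [anova_lsd()] on the raw data.
#'
#' @param means Per-group means.
#' @param sds Per-group sample standard deviations (n - 1 denominator),
#'   all nonnegative.
#' @param ns Per-group sizes, all at least 2.
#' @param alpha Significance level.
#' @param labels Group labels; defaults to `names(means)` or `g1`, `g2`,
#'   ...
#' @return An `lsd_result`, as for [anova_lsd()].
#' @export
anova_from_summary <- function(means, sds, ns, alpha = 0.05,
                               labels = names(means)) {
  k <- length(means)
  if (length(sds) != k || length(ns) != k)
    stop("anova_from_summary: 'means', 'sds', 'ns' must align", call. = FALSE)
  if (k < 2) stop("anova_from_summary: need at least two groups",
                  call. = FALSE)
  if (any(is.na(sds)) || any(sds < 0))
    stop("anova_from_summary: standard deviations must be nonnegative",
         call. = FALSE)
  if (any(is.na(ns)) || any(ns < 2))
    stop("anova_from_summary: every group needs n >= 2", call. = FALSE)
  if (is.null(labels)) labels <- paste0("g", seq_len(k))
  N <- sum(ns)
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  dfb <- k - 1
  dfe <- N - k
  mse <- ssw / dfe
  if (ssw > 0) {
    Fv <- (ssb / dfb) / mse
    pv <- pf(Fv, dfb, dfe, lower.tail = FALSE)
  } else if (ssb > 0) { Fv <- Inf; pv <- 0 } else { Fv <- NA_real_; pv <- 1 }
  .lsd_core(as.character(labels), as.numeric(means), as.numeric(ns),
            mse, dfe, Fv, pv, alpha)
}

#' @export
print.lsd_result <- function(x, digits = 4, ...) {
  cat(sprintf("One-way ANOVA: F = %s, p = %s (alpha = %g)\n",
              format(x$F, digits = digits), format(x$p, digits = digits),
              x$alpha))
  if (is.finite(x$p) && x$p >= x$alpha)
    cat("Omnibus test not significant; protected LSD assigns a common letter.\n")
  print(data.frame(group = x$groups, n = as.integer(x$n),
                   mean = round(x$means, digits), letter = x$letters,
                   row.names = NULL))
  invisible(x)
}
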
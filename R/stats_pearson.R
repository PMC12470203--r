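# Pairwise-complete Pearson correlation matrix with two-sided p-values and
# significance stars (* p <= 0.05, ** p <= 0.01; no multiplicity correction).

#' Pearson correlation matrix with significance
#'
#' Pairwise-complete product-moment correlations between the numeric columns
#' of a table, with two-sided p-values from the t statistic
#' `t = r sqrt((n - 2) / (1 - r^2))` and star annotations.  A constant
#' variable yields `NA` correlations for its pairs with a warning.
#'
#' @param data Data frame or matrix of observations x variables; non-numeric
#'   columns are dropped.
#' @param min_pairs Minimum number of complete pairs required per variable
#'   pair (default 3); pairs with fewer are `NA`.
#' @return An object of class `correlation_matrix`: list with `variables`,
#'   symmetric matrices `r`, `p`, `n`, and a character matrix `stars`
#'   (`""`, `"*"`, `"**"`).
#' @export
#' @examples
#' pearson_matrix(data.frame(x = 1:5, y = 2 * (1:5)))
pearson_matrix <- function(data, min_pairs = 3) {
  x <- as.data.frame(data)
  x <- x[vapply(x, is.numeric, logical(1))]
  if (ncol(x) < 2) stop("pearson_matrix: need at least two numeric variables",
                        call. = FALSE)
  vars <- names(x)
  k <- length(vars)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  nm <- matrix(0L, k, k, dimnames = list(vars, vars))
  constant <- character()
  for (i in seq_len(k)) for (j in i:k) {
    cc <- complete.cases(x[[i]], x[[j]])
    n <- sum(cc)
    nm[i, j] <- nm[j, i] <- n
    if (i == j) { r[i, i] <- 1; next }
    if (n < min_pairs) next
    xi <- x[[i]][cc]; xj <- x[[j]][cc]
    if (sd(xi) == 0) constant <- union(constant, vars[i])
    if (sd(xj) == 0) constant <- union(constant, vars[j])
    if (sd(xi) == 0 || sd(xj) == 0) next
    rij <- cor(xi, xj)
    r[i, j] <- r[j, i] <- rij
    pij <- if (abs(rij) >= 1) 0 else {
      tstat <- rij * sqrt((n - 2) / (1 - rij^2))
      2 * pt(-abs(tstat), df = n - 2)
    }
    p[i, j] <- p[j, i] <- pij
  }
  if (length(constant))
    warning("pearson_matrix: constant variable(s), correlations set NA: ",
            paste(constant, collapse = ", "), call. = FALSE)
  stars <- matrix("", k, k, dimnames = list(vars, vars))
  stars[!is.na(p) & p <= 0.05] <- "*"
  stars[!is.na(p) & p <= 0.01] <- "**"
  structure(list(variables = vars, r = r, p = p, n = nm, stars = stars),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  disp <- matrix(paste0(formatC(x$r, digits = digits, format = "f"), x$stars),
                 nrow = length(x$variables),
                 dimnames = list(x$variables, x$variables))
  disp[is.na(x$r)] <- "NA"
  cat("Pearson correlation matrix (* p <= 0.05, ** p <= 0.01)\n")
  print(disp, quote = FALSE)
  invisible(x)
}

#' Long-format view of a correlation matrix
#'
#' @param cm A [pearson_matrix()] result.
#' @return Data frame `var1`, `var2`, `r`, `p`, `stars`, one row per
#'   unordered variable pair.
#' @export
correlation_long <- function(cm) {
  stopifnot(inherits(cm, "correlation_matrix"))
  k <- length(cm$variables)
  idx <- which(upper.tri(cm$r), arr.ind = TRUE)
  data.frame(var1 = cm$variables[idx[, 1]], var2 = cm$variables[idx[, 2]],
             r = cm$r[idx], p = cm$p[idx], stars = cm$stars[idx],
             stringsAsFactors = FALSE)
}
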
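# Independent brute-force oracles, deliberately naive implementations of the
# textbook formulas, used to cross-check the package's statistical routines.

# product-moment correlation by explicit sums
oracle_pearson <- function(x, y) {
  cc <- !is.na(x) & !is.na(y)
  x <- x[cc]; y <- y[cc]
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# OLS by the closed-form normal equations
oracle_ols <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  c(intercept = yb - slope * xb, slope = slope)
}

# the least significant difference for two groups at a pooled MSE
oracle_lsd <- function(mse, dfe, ni, nj, alpha = 0.05)
  qt(1 - alpha / 2, dfe) * sqrt(mse * (1 / ni + 1 / nj))

# tiny wide helper: per-site concentration vector for one organ/element of
# the bundled survey
organ_means <- function(tabs, el, org) {
  d <- tabs$organs[tabs$organs$element == el & tabs$organs$organ == org, ]
  d$mean_mg_kg[match(tabs$soil$site_id, d$site_id)]
}
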
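test_that("identical groups share a single letter", {
  v <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("a", "b"), each = 3)
  res <- anova_lsd(v, g)
  expect_equal(unname(res$letters), c("a", "a"))
})

test_that("well-separated groups get distinct letters", {
  set.seed(21)
  v <- c(rnorm(3, 0, 0.1), rnorm(3, 10, 0.1), rnorm(3, 20, 0.1))
  g <- rep(c("low", "mid", "high"), each = 3)
  res <- anova_lsd(v, g)
  expect_equal(res$groups, c("high", "mid", "low"))   # descending means
  expect_equal(unname(res$letters), c("a", "b", "c"))
  expect_lt(res$p, 1e-6)
})

test_that("means closer than the hand-computed LSD share a letter", {
  set.seed(33)
  noise <- rnorm(6, 0, 0.1)
  v <- c(10.0 + noise[1:3], 10.05 + noise[4:6])
  res <- anova_lsd(v, rep(c("g1", "g2"), each = 3))
  lsd <- oracle_lsd(res$mse, res$df_error, 3, 3)
  expect_lt(abs(diff(res$means)), lsd)
  expect_equal(unname(res$letters), c("a", "a"))
})

test_that("protected LSD suppresses letters when the omnibus test fails", {
  set.seed(4)
  v <- rnorm(12, 5, 2)
  res <- anova_lsd(v, rep(letters[1:4], each = 3))
  expect_gte(res$p, 0.05)
  expect_true(all(res$letters == "a"))
})

test_that("group size contracts are enforced", {
  expect_error(anova_lsd(c(1, 2, 3), c("a", "a", "b")), "n >= 2")
  expect_error(anova_lsd(1:4, rep("a", 4)), "two groups")
  expect_error(anova_from_summary(c(1, 2), c(0.1, -0.1), c(3, 3)),
               "nonnegative")
  expect_error(anova_from_summary(c(1, 2), c(0.1, 0.1), c(3, 1)), "n >= 2")
})

test_that("summary-statistics ANOVA is algebraically identical to raw ANOVA", {
  set.seed(55)
  for (i in 1:10) {
    k <- sample(2:6, 1)
    ns <- sample(2:6, k, replace = TRUE)
    g <- rep(paste0("g", seq_len(k)), ns)
    v <- rnorm(sum(ns), mean = rep(runif(k, 0, 5), ns))
    raw <- anova_lsd(v, g)
    means <- tapply(v, g, mean)[raw$groups]
    sds <- tapply(v, g, sd)[raw$groups]
    nn <- tapply(v, g, length)[raw$groups]
    summ <- anova_from_summary(means, sds, nn, labels = raw$groups)
    expect_equal(summ$F, raw$F, tolerance = 1e-10)
    expect_equal(summ$p, raw$p, tolerance = 1e-10)
    expect_equal(summ$letters, raw$letters)
  }
})

test_that("degenerate summaries are handled: all-identical gives F = NA, one letter", {
  res <- anova_from_summary(c(2, 2, 2), c(0, 0, 0), c(3, 3, 3))
  expect_true(is.na(res$F))
  expect_true(all(res$letters == "a"))
  res2 <- anova_from_summary(c(1, 2), c(0, 0), c(3, 3))   # zero noise, gap
  expect_equal(res2$p, 0)
  expect_equal(length(unique(res2$letters)), 2)
})

test_that("the letter display is exhaustively consistent with pairwise LSD", {
  set.seed(77)
  for (i in 1:40) {
    k <- sample(2:6, 1)
    means <- runif(k, 0, 3)
    sds <- runif(k, 0.05, 1)
    ns <- sample(2:5, k, replace = TRUE)
    res <- anova_from_summary(means, sds, ns)
    protected_sig <- res$p < res$alpha
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      shares <- any(strsplit(res$letters[a], "")[[1]] %in%
                      strsplit(res$letters[b], "")[[1]])
      rejects <- protected_sig &&
        abs(res$means[a] - res$means[b]) >
          oracle_lsd(res$mse, res$df_error, res$n[a], res$n[b], res$alpha)
      # shared letter <=> the pairwise LSD test does not reject
      expect_equal(shares, !rejects)
    }
  }
})

test_that("survey leaching-rate letters separate the extreme sites", {
  tabs <- garden_survey_tables()
  inf <- tabs$infusion
  res <- anova_from_summary(inf$cd_leach_pct, inf$cd_leach_sd,
                            rep(3, nrow(inf)), labels = inf$site_id)
  l6 <- res$letters[["no.6"]]
  l11 <- res$letters[["no.11"]]
  expect_false(any(strsplit(l6, "")[[1]] %in% strsplit(l11, "")[[1]]))
  # no.11 has the highest leaching rate and so carries "a"
  expect_equal(res$groups[1], "no.11")
  expect_true(grepl("a", l11))
})
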
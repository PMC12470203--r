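test_that("pollution index is concentration over standard", {
  expect_equal(pollution_index(0.48), 1.60)
  expect_equal(pollution_index(0), 0)
  expect_equal(pollution_index(0.300), 1.0)
  expect_error(pollution_index(0.4, standard = 0), "positive")
  expect_equal(pollution_class(c(0.5, 0.8, 1.4)),
               c("safe", "below safety standard", "slight pollution"))
})

test_that("activation rate applies the ug->mg conversion exactly once", {
  expect_equal(activation_rate(50, 0.5), 10.0)
  expect_equal(round(activation_rate(46.56, 0.18), 2), 25.87)
  # conversion sentinel: available = total expressed in ug/kg => 100 %
  for (x in c(0.01, 0.37, 5))
    expect_equal(activation_rate(x * 1000, x), 100)
  expect_warning(out <- activation_rate(10, 0), "zero denominator")
  expect_true(is.na(out))
})

test_that("enrichment and transport coefficients are plain ratios with a guarded chain", {
  expect_equal(enrichment_coefficient(0.62, 0.34), 0.62 / 0.34)
  expect_equal(enrichment_coefficient(1.3, 1.3), 1.0)
  # equal printed concentrations in adjacent organs give TC = 1
  expect_equal(transport_coefficient(0.31, 0.31, "main_stem", "taproot"), 1.0)
  expect_error(transport_coefficient(1, 1, "young_leaf", "taproot"),
               "allowed steps")
  expect_error(transport_coefficient(1, 1, "fibrous_root", "taproot"),
               "allowed steps")   # direction matters
  expect_warning(out <- transport_coefficient(0.1, 0, "taproot", "fibrous_root"),
                 "zero denominator")
  expect_true(is.na(out))
})

test_that("leaching rate is the infusion/tea mass balance", {
  expect_equal(leaching_rate(0.1, 0.02), 10.0)
  expect_equal(leaching_rate(0, 0.02), 0)
  # doubling the tea mass at fixed infusion concentration halves the rate
  set.seed(7)
  for (i in 1:20) {
    inf <- runif(1, 0.01, 5); tea <- runif(1, 0.01, 2)
    base <- leaching_rate(inf, tea)
    expect_equal(leaching_rate(inf, tea, brew_spec(tea_mass = 0.010)),
                 base / 2)
  }
  expect_warning(out <- leaching_rate(0.1, 0), "zero denominator")
  expect_true(is.na(out))
})

test_that("group_summary gives mean, sample sd and a pooled row", {
  gs <- group_summary(c(1, 2, 3), rep("g", 3))
  expect_equal(gs$mean[1], 2)
  expect_equal(gs$sd[1], 1)
  single <- group_summary(5, "g")
  expect_equal(single$mean[1], 5)
  expect_true(is.na(single$sd[1]))
  gs2 <- group_summary(c(1, 3, 10, 20), c("a", "a", "b", "b"))
  expect_equal(gs2$group, c("a", "b", "Mean"))
  expect_equal(gs2$mean[3], mean(c(2, 15)))   # pooled over group means
  expect_error(group_summary(NA_real_, "g"), "no non-missing")
})

test_that("transport chain telescopes and is consistent with EC", {
  set.seed(11)
  for (i in 1:25) {
    conc <- runif(5, 0.01, 3)   # fibrous, taproot, main, lateral + soil
    soil <- conc[5]
    tc1 <- transport_coefficient(conc[2], conc[1], "taproot", "fibrous_root")
    tc2 <- transport_coefficient(conc[3], conc[2], "main_stem", "taproot")
    tc3 <- transport_coefficient(conc[4], conc[3], "lateral_stem", "main_stem")
    expect_equal(tc1 * tc2 * tc3, conc[4] / conc[1])
    # EC(child)/EC(parent) == TC(child, parent)
    expect_equal(enrichment_coefficient(conc[2], soil) /
                   enrichment_coefficient(conc[1], soil), tc1)
  }
})

test_that("EC and TC are scale invariant; Pi and AR scale as dictated", {
  k <- 3.7
  expect_equal(enrichment_coefficient(k * 0.62, k * 0.34),
               enrichment_coefficient(0.62, 0.34))
  expect_equal(transport_coefficient(k * 0.3, k * 0.9,
                                     "taproot", "fibrous_root"),
               transport_coefficient(0.3, 0.9, "taproot", "fibrous_root"))
  expect_equal(pollution_index(k * 0.3), k * pollution_index(0.3))
  expect_equal(activation_rate(k * 50, 0.5), k * activation_rate(50, 0.5))
  expect_equal(activation_rate(k * 50, k * 0.5), activation_rate(50, 0.5))
})

test_that("survey cross-site means reproduce the published summaries", {
  st <- garden_survey_study()
  im <- index_means(study_indices(st, "Cd"))
  get <- function(name, qual) {
    hit <- im$index_name == name &
      (if (is.na(qual)) is.na(im$qualifier) else im$qualifier %in% qual)
    im$mean[hit]
  }
  # stem-chain transport coefficients, one unit in the last printed decimal
  expect_lt(abs(get("TC", "fibrous_root->taproot") - 0.29), 0.011)
  expect_lt(abs(get("TC", "taproot->main_stem") - 0.97), 0.011)
  expect_lt(abs(get("TC", "main_stem->lateral_stem") - 1.16), 0.011)
  expect_lt(abs(get("TC", "lateral_stem->old_leaf") - 0.26), 0.011)
  expect_lt(abs(get("TC", "lateral_stem->young_leaf") - 0.07), 0.011)
  expect_equal(round(get("EC", "young_leaf"), 2), 0.06)
  # leaves accumulate far less Cd than roots
  expect_lt(get("EC", "young_leaf"), get("EC", "old_leaf"))
  expect_lt(get("EC", "old_leaf"), get("EC", "fibrous_root"))
})

test_that("study_indices aggregates replicate ratios before site ratios", {
  # two replicates with different ratios: site value must be the mean of the
  # per-replicate ratios, not the ratio of the means
  soil <- data.frame(site_id = "s1", cd_total_mg_kg = 0.5,
                     cd_avail_ug_kg = 50, se_total_mg_kg = 2,
                     se_avail_ug_kg = 40)
  organs <- data.frame(site_id = "s1",
                       organ = rep(c("fibrous_root", "taproot"), each = 2),
                       element = "Cd", replicate = c(1, 2, 1, 2),
                       conc_mg_kg = c(1.0, 2.0, 0.5, 0.5))
  inf <- data.frame(site_id = "s1", element = "Cd", conc_ug_L = 0.1,
                    tea_mass_kg = 0.005, water_volume_L = 0.1)
  idx <- study_indices(tea_study(soil, organs, inf), "Cd")
  tc <- idx$value[idx$index_name == "TC"]
  expect_equal(tc, mean(c(0.5 / 1.0, 0.5 / 2.0)))   # mean of ratios: 0.375
  expect_false(isTRUE(all.equal(tc, 0.5 / 1.5)))    # not ratio of means
})
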
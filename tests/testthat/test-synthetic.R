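test_that("the default configuration produces a valid full-shape study", {
  sim <- simulate_study(generator_config(seed = 42))
  st <- sim$study
  expect_s3_class(st, "tea_study")
  expect_equal(nrow(st$soil), 12)
  expect_equal(sum(st$organs$element == "Cd"), 12 * 6 * 3)
  expect_equal(sum(st$organs$element == "Se"), 12 * 6 * 3)
  expect_equal(nrow(st$infusion), 24)
  expect_true(all(st$organs$conc_mg_kg > 0))
  expect_true(all(st$soil$cd_total_mg_kg >= 0.18 &
                    st$soil$cd_total_mg_kg <= 0.55))
  expect_true(all(st$soil$ph >= 3 & st$soil$ph <= 10))
  # ground truth carries the latent chain but is a separate object
  expect_equal(nrow(sim$truth$latent_cd), 12)
  expect_named(sim$truth$latent_cd, tea_organs(), ignore.order = TRUE)
})

test_that("identical seed and config give identical studies and files", {
  cfg <- generator_config(seed = 99)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$study, b$study)
  expect_identical(a$truth$leach_cd_pct, b$truth$leach_cd_pct)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_study(cfg, out_dir = d1)
  simulate_study(cfg, out_dir = d2)
  for (f in c("soil.csv", "organs.csv", "infusion.csv", "truth.json"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  # a different seed changes the data
  expect_false(identical(simulate_study(generator_config(seed = 100))$study,
                         a$study))
})

test_that("a noiseless study returns the configured chain exactly", {
  cfg <- generator_config(seed = 7, noise_cv = 0)
  sim <- simulate_study(cfg)
  im <- index_means(study_indices(sim$study, "Cd"))
  tc <- function(q) im$mean[im$index_name == "TC" & im$qualifier == q]
  expect_equal(tc("fibrous_root->taproot"), 0.29, tolerance = 1e-12)
  expect_equal(tc("taproot->main_stem"), 0.97, tolerance = 1e-12)
  expect_equal(tc("main_stem->lateral_stem"), 1.16, tolerance = 1e-12)
  expect_equal(tc("lateral_stem->old_leaf"), 0.26, tolerance = 1e-12)
  expect_equal(tc("lateral_stem->young_leaf"), 0.07, tolerance = 1e-12)
})

test_that("default-config pipeline estimates recover the generating chain", {
  sim <- simulate_study(generator_config(seed = 42))
  im <- index_means(study_indices(sim$study, "Cd"))
  tc_est <- im$mean[im$index_name == "TC" &
                      im$qualifier == "fibrous_root->taproot"]
  expect_lt(abs(tc_est - 0.29) / 0.29, 0.10)
  # breakpoint recovery on the soil-normalized fibrous-root response
  org <- sim$study$organs
  fib_cd <- org[org$element == "Cd" & org$organ == "fibrous_root", ]
  fib_se <- org[org$element == "Se" & org$organ == "fibrous_root", ]
  m <- merge(fib_cd, fib_se, by = c("site_id", "replicate"))
  soil_cd <- sim$study$soil$cd_total_mg_kg[match(m$site_id,
                                                 sim$study$soil$site_id)]
  tf <- threshold_fit(m$conc_mg_kg.y, m$conc_mg_kg.x / soil_cd)
  step <- max(diff(tf$search_grid))
  expect_lt(abs(tf$breakpoint - 2.0), step + 1e-12)
  # sign recovery is a distributional property (>= 18/20 seeds, checked in
  # the acceptance suite); a single seed only pins the breakpoint
})

test_that("scaling the configured fibrous EC scales the estimate linearly", {
  # coupling disabled so the estimator's linearity is isolated
  base <- generator_config(seed = 5, slope_below = 0, slope_above = 0)
  scaled <- generator_config(seed = 5, slope_below = 0, slope_above = 0,
                             ec_fibrous = 3.49 * 2)
  ec_of <- function(cfg) {
    im <- index_means(study_indices(simulate_study(cfg)$study, "Cd"))
    im$mean[im$index_name == "EC" & im$qualifier == "fibrous_root"]
  }
  expect_equal(ec_of(scaled), 2 * ec_of(base), tolerance = 1e-10)
})

test_that("generated soil covariates carry the configured correlation signs", {
  # one large study so the signs are stable
  sim <- simulate_study(generator_config(seed = 31, n_sites = 200))
  soil <- sim$study$soil
  ar <- activation_rate(soil$cd_avail_ug_kg, soil$cd_total_mg_kg)
  expect_lt(cor(soil$ph, ar), 0)
  expect_gt(cor(soil$ak_mg_kg, ar), 0)
  expect_gt(cor(soil$tn_g_kg, ar), 0)
  expect_gt(cor(soil$cd_total_mg_kg, soil$cd_avail_ug_kg), 0)
})

test_that("config contract: mandatory seed and named chains", {
  expect_error(generator_config(), "seed")
  expect_error(generator_config(seed = 1, tc_chain = c(taproot = 0.3)),
               "named steps")
})
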
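# Synthetic-study generator.  Emulates a 12-garden survey with three
# replicates per garden: soil pools drawn uniformly in the survey ranges,
# availability via a lognormal activation rate, organ concentrations built
# multiplicatively along the transport chain from a fibrous-root anchor that
# carries a piecewise Se-Cd coupling (positive below the Se breakpoint,
# antagonistic above), and infusion concentrations via a site leaching rate.
# Ground truth (latent concentrations and configured parameters) is emitted
# alongside the data and is never consumed by the pipeline under test.

# lognormal with prescribed mean and coefficient of variation
.rlnorm_mean <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  s <- sqrt(log(1 + cv^2))
  mean * exp(rnorm(n, 0, s) - s^2 / 2)
}

#' Generator configuration
#'
#' Parameters of the synthetic study.  Defaults reproduce the reference
#' survey conditions: 12 gardens with 3 replicates, soil Cd 0.18-0.55 and
#' Se 1.46-5.50 mg kg^-1, a mean Cd activation rate of 20.93 %, a fibrous-
#' root enrichment coefficient of 3.49, the stem chain transport
#' coefficients 0.29 / 0.97 / 1.16 with leaf steps 0.26 / 0.07, a Se-Cd
#' coupling in the fibrous root that switches sign at 2.0 mg kg^-1 Se, and
#' a mean Cd leaching rate of 13.33 %.
#'
#' @param seed Integer seed; mandatory for reproducibility.
#' @param n_sites,n_reps Number of gardens and replicates per garden.
#' @param soil_cd_range,soil_se_range Uniform ranges of soil totals,
#'   mg kg^-1.
#' @param ar_cd_mean,ar_se_mean Mean activation rates, percent.
#' @param ar_site_cv Site-level lognormal CV of the activation rates.
#' @param ec_fibrous,ec_se_fibrous Fibrous-root enrichment coefficients of
#'   Cd and Se.
#' @param tc_chain,tc_se_chain Named transport-coefficient chains (taproot,
#'   main_stem, lateral_stem, old_leaf, young_leaf) for Cd and Se.
#' @param se_cd_breakpoint Fibrous-root Se threshold of the coupling,
#'   mg kg^-1.
#' @param slope_below,slope_above Coupling slopes (mg kg^-1 Cd per
#'   mg kg^-1 Se) below/above the breakpoint; positive then negative.
#' @param leach_mean_cd,leach_mean_se Mean leaching rates, percent.
#' @param leach_cv Site-level lognormal CV of the leaching rates.
#' @param noise_cv Replicate-level lognormal CV of organ concentrations.
#' @param covariate_cor Named correlations (Gaussian copula) between soil
#'   covariates and the latent Cd-activation scatter; signs encode the
#'   survey's observed directions (pH negative, AK and TN positive).
#' @param brew [brew_spec()] used for the infusion.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed,
                             n_sites = 12, n_reps = 3,
                             soil_cd_range = c(0.18, 0.55),
                             soil_se_range = c(1.46, 5.50),
                             ar_cd_mean = 20.93, ar_se_mean = 2.27,
                             ar_site_cv = 0.35,
                             ec_fibrous = 3.49, ec_se_fibrous = 0.66,
                             tc_chain = c(taproot = 0.29, main_stem = 0.97,
                                          lateral_stem = 1.16,
                                          old_leaf = 0.26, young_leaf = 0.07),
                             tc_se_chain = c(taproot = 0.51, main_stem = 0.72,
                                             lateral_stem = 0.63,
                                             old_leaf = 2.00,
                                             young_leaf = 0.95),
                             se_cd_breakpoint = 2.0,
                             slope_below = 0.4, slope_above = -0.3,
                             leach_mean_cd = 13.33, leach_mean_se = 22.62,
                             leach_cv = 0.25,
                             noise_cv = 0.05,
                             covariate_cor = c(ph = -0.6, ak_mg_kg = 0.5,
                                               tn_g_kg = 0.4),
                             brew = brew_spec()) {
  if (missing(seed) || is.null(seed))
    stop("generator_config: 'seed' is mandatory", call. = FALSE)
  stopifnot(n_sites >= 1, n_reps >= 1,
            length(soil_cd_range) == 2, diff(soil_cd_range) >= 0,
            soil_cd_range[1] > 0,
            length(soil_se_range) == 2, diff(soil_se_range) >= 0,
            soil_se_range[1] > 0,
            ar_cd_mean > 0, ar_se_mean > 0, ar_site_cv >= 0,
            ec_fibrous > 0, ec_se_fibrous > 0,
            all(tc_chain > 0), all(tc_se_chain > 0),
            se_cd_breakpoint > 0,
            leach_mean_cd > 0, leach_mean_se > 0, leach_cv >= 0,
            noise_cv >= 0, inherits(brew, "brew_spec"))
  need <- c("taproot", "main_stem", "lateral_stem", "old_leaf", "young_leaf")
  if (!all(need %in% names(tc_chain)) || !all(need %in% names(tc_se_chain)))
    stop("generator_config: TC chains need the five named steps: ",
         paste(need, collapse = ", "), call. = FALSE)
  structure(list(seed = as.integer(seed), n_sites = n_sites, n_reps = n_reps,
                 soil_cd_range = soil_cd_range, soil_se_range = soil_se_range,
                 ar_cd_mean = ar_cd_mean, ar_se_mean = ar_se_mean,
                 ar_site_cv = ar_site_cv,
                 ec_fibrous = ec_fibrous, ec_se_fibrous = ec_se_fibrous,
                 tc_chain = tc_chain[need], tc_se_chain = tc_se_chain[need],
                 se_cd_breakpoint = se_cd_breakpoint,
                 slope_below = slope_below, slope_above = slope_above,
                 leach_mean_cd = leach_mean_cd, leach_mean_se = leach_mean_se,
                 leach_cv = leach_cv, noise_cv = noise_cv,
                 covariate_cor = covariate_cor, brew = brew),
            class = "generator_config")
}

# latent organ chain for one element from its fibrous-root anchor
.chain_latent <- function(fibrous, chain) {
  taproot <- fibrous * chain[["taproot"]]
  main_stem <- taproot * chain[["main_stem"]]
  lateral_stem <- main_stem * chain[["lateral_stem"]]
  cbind(fibrous_root = fibrous, taproot = taproot, main_stem = main_stem,
        lateral_stem = lateral_stem,
        old_leaf = lateral_stem * chain[["old_leaf"]],
        young_leaf = lateral_stem * chain[["young_leaf"]])
}

#' Simulate a complete synthetic study
#'
#' Draws a full soil / organ / infusion study under a [generator_config()],
#' returning both the validated [tea_study()] bundle and the ground truth
#' (latent per-site concentrations, site leaching rates and the configured
#' parameters).  The same configuration and seed always produce identical
#' output; if `out_dir` is given the three CSVs are written via
#' [write_study()] together with a `truth.json`.
#'
#' @param config A [generator_config()].
#' @param out_dir Optional output directory.
#' @return List with elements `study` (a `tea_study`) and `truth`.
#' @export
#' @examples
#' sim <- simulate_study(generator_config(seed = 42))
#' sim$study
simulate_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_sites
  site_id <- paste0("no.", seq_len(n))

  soil_cd <- runif(n, config$soil_cd_range[1], config$soil_cd_range[2])
  soil_se <- runif(n, config$soil_se_range[1], config$soil_se_range[2])

  # latent activation scatter, shared with the covariate copula
  z_ar <- rnorm(n)
  s_ar <- sqrt(log(1 + config$ar_site_cv^2))
  arcd <- pmin(config$ar_cd_mean * exp(s_ar * z_ar - s_ar^2 / 2), 99)
  arse <- pmin(.rlnorm_mean(n, config$ar_se_mean, config$ar_site_cv), 99)
  cd_avail <- soil_cd * 1000 * arcd / 100
  se_avail <- soil_se * 1000 * arse / 100

  # soil covariates tied to the activation latent through a Gaussian copula;
  # marginals are plausible acidic tea-garden soils, magnitudes free
  cop <- function(rho) rho * z_ar + sqrt(1 - rho^2) * rnorm(n)
  rho <- config$covariate_cor
  z_ph <- cop(rho[["ph"]]); z_ak <- cop(rho[["ak_mg_kg"]])
  z_tn <- cop(rho[["tn_g_kg"]])
  soil <- data.frame(
    site_id = site_id,
    cd_total_mg_kg = soil_cd, cd_avail_ug_kg = cd_avail,
    se_total_mg_kg = soil_se, se_avail_ug_kg = se_avail,
    ph = pmin(pmax(4.8 + 0.5 * z_ph, 3), 10),
    som_g_kg = 25 * exp(0.3 * rnorm(n)),
    tn_g_kg = pmax(1.5 + 0.3 * z_tn, 0.1),
    tp_g_kg = pmax(0.6 + 0.15 * rnorm(n), 0.05),
    ap_mg_kg = 20 * exp(0.4 * rnorm(n)),
    ak_mg_kg = 120 * exp(0.3 * z_ak))

  # fibrous-root anchors: Se first, then Cd with the piecewise coupling.
  # The coupling slopes are enrichment-ratio units (EC per mg kg^-1 Se), so
  # the additive concentration term carries the site's soil Cd: the
  # soil-normalized fibrous-root response is then exactly piecewise linear
  # in Se with the configured slopes, switching sign at the breakpoint.
  lat_se_fib <- soil_se * config$ec_se_fibrous
  bp <- config$se_cd_breakpoint
  coupling <- ifelse(lat_se_fib < bp, config$slope_below,
                     config$slope_above) * (lat_se_fib - bp)
  lat_cd_fib <- soil_cd * (config$ec_fibrous + coupling)
  if (any(lat_cd_fib <= 0))
    stop(paste0("simulate_study: Se-Cd coupling drives latent fibrous-root ",
                "Cd nonpositive; weaken the coupling slopes"), call. = FALSE)
  latent <- list(Cd = .chain_latent(lat_cd_fib, config$tc_chain),
                 Se = .chain_latent(lat_se_fib, config$tc_se_chain))

  s_rep <- sqrt(log(1 + config$noise_cv^2))
  organs <- do.call(rbind, lapply(.ELEMENTS, function(el) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      do.call(rbind, lapply(colnames(latent[[el]]), function(organ) {
        mu <- latent[[el]][i, organ]
        conc <- mu * exp(rnorm(config$n_reps, 0, s_rep) - s_rep^2 / 2)
        data.frame(site_id = site_id[i], organ = organ, element = el,
                   replicate = seq_len(config$n_reps), conc_mg_kg = conc,
                   stringsAsFactors = FALSE)
      }))
    }))
  }))

  leach_cd <- pmin(.rlnorm_mean(n, config$leach_mean_cd, config$leach_cv), 100)
  leach_se <- pmin(.rlnorm_mean(n, config$leach_mean_se, config$leach_cv), 100)
  brew <- config$brew
  to_inf <- function(latent_yl, leach)
    latent_yl * leach / 100 * brew$tea_mass * 1000 / brew$water_volume
  infusion <- rbind(
    data.frame(site_id = site_id, element = "Cd",
               conc_ug_L = to_inf(latent$Cd[, "young_leaf"], leach_cd)),
    data.frame(site_id = site_id, element = "Se",
               conc_ug_L = to_inf(latent$Se[, "young_leaf"], leach_se)))
  infusion$tea_mass_kg <- brew$tea_mass
  infusion$water_volume_L <- brew$water_volume

  study <- tea_study(soil, organs, infusion, brew = brew)
  truth <- list(site_id = site_id,
                latent_cd = as.data.frame(latent$Cd),
                latent_se = as.data.frame(latent$Se),
                arcd_pct = arcd, arse_pct = arse,
                leach_cd_pct = leach_cd, leach_se_pct = leach_se,
                config = config[setdiff(names(config), "brew")])
  if (!is.null(out_dir)) {
    write_study(study, out_dir)
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(study = study, truth = truth)
}
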
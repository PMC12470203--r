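# Carcinogenic health-risk chain for Cd intake via brewed tea:
#   D = I x Ci x mu / W          (daily exposure dose, mg kg^-1 d^-1)
#   R = (1 - exp(-D q)) / A      (average individual annual risk, a^-1)
# with intake I, tea Cd concentration Ci, leaching fraction mu, body weight
# W, carcinogenic intensity coefficient q and annual-averaging divisor A.

#' Daily exposure dose of Cd from tea consumption
#'
#' `D = daily_intake x tea_conc x mu / body_weight`.
#'
#' @param tea_conc Cd concentration in dry tea, mg kg^-1.  Vectorized.
#' @param mu Leaching fraction in `[0, 1]` (not percent).
#' @param params [risk_params()].
#' @return Dose in mg kg^-1 d^-1.
#' @export
#' @examples
#' daily_dose(0.0354, 0.0698)   # ~4.02e-7 mg kg^-1 d^-1
daily_dose <- function(tea_conc, mu, params = risk_params()) {
  stopifnot(inherits(params, "risk_params"))
  if (any(!is.na(mu) & (mu < 0 | mu > 1)))
    stop("daily_dose: 'mu' is a fraction and must lie in [0, 1]",
         call. = FALSE)
  if (any(!is.na(tea_conc) & tea_conc < 0))
    stop("daily_dose: 'tea_conc' must be nonnegative", call. = FALSE)
  params$daily_intake * tea_conc * mu / params$body_weight
}

#' Average individual annual carcinogenic risk
#'
#' `R = (1 - exp(-dose x q_ig)) / averaging_constant`.  Monotone increasing
#' in dose, tends to 0 as the dose vanishes and is bounded above by
#' `1 / averaging_constant`.
#'
#' @param dose Daily exposure dose, mg kg^-1 d^-1.  Vectorized.
#' @param params [risk_params()].
#' @return Annual risk, a^-1.
#' @export
annual_risk <- function(dose, params = risk_params()) {
  stopifnot(inherits(params, "risk_params"))
  if (any(!is.na(dose) & dose < 0))
    stop("annual_risk: 'dose' must be nonnegative", call. = FALSE)
  # -expm1(-x) = 1 - exp(-x) without cancellation at the tiny doses typical
  # of tea consumption
  -expm1(-dose * params$q_ig) / params$averaging_constant
}

#' Tea concentration implied by a total-transfer risk
#'
#' Inverts the risk chain at `mu = 1`: given an annual risk under complete
#' transfer of tea Cd into the infusion, returns the dry-tea Cd
#' concentration that produces it.  Useful for validating published
#' per-site risks when the underlying (unrounded) tea concentrations are
#' not available.
#'
#' @param total_risk Annual risk under total transfer, a^-1; must be below
#'   the model's `1 / averaging_constant` bound.
#' @param params [risk_params()].
#' @return Tea Cd concentration, mg kg^-1.
#' @export
implied_tea_concentration <- function(total_risk, params = risk_params()) {
  stopifnot(inherits(params, "risk_params"))
  if (any(!is.na(total_risk) &
          (total_risk < 0 | total_risk >= 1 / params$averaging_constant)))
    stop("implied_tea_concentration: risk outside [0, 1/averaging_constant)",
         call. = FALSE)
  dose <- -log(1 - params$averaging_constant * total_risk) / params$q_ig
  dose * params$body_weight / params$daily_intake
}

#' Per-site risk table under measured and worst-case leaching
#'
#' Evaluates the risk chain for every site under two scenarios: the measured
#' leaching rate, and total transfer (`mu = 1`, every atom of Cd in the dry
#' tea assumed to reach the cup).  Pooled `"Mean"` rows (means of the
#' per-site doses and risks) are appended per scenario.
#'
#' @param tea_conc Per-site Cd concentration in dry tea, mg kg^-1.
#' @param leach_pct Per-site leaching rate in **percent** (as produced by
#'   [leaching_rate()]); converted to a fraction internally.
#' @param site_id Site labels aligned with the two vectors; must be unique.
#' @param params [risk_params()].
#' @return Data frame with columns `site_id`, `scenario`
#'   (`measured_leaching` / `total_transfer`), `dose_mg_kg_d`,
#'   `annual_risk_per_a`.
#' @export
risk_table <- function(tea_conc, leach_pct, site_id,
                       params = risk_params()) {
  if (length(tea_conc) != length(leach_pct) ||
      length(tea_conc) != length(site_id))
    stop("risk_table: 'tea_conc', 'leach_pct' and 'site_id' must align",
         call. = FALSE)
  if (anyDuplicated(site_id))
    stop("risk_table: duplicated site_id", call. = FALSE)
  message("risk_table: leaching rates interpreted as percent, divided by 100")
  mu <- leach_pct / 100
  one <- function(scenario, mu) {
    d <- daily_dose(tea_conc, mu, params)
    r <- annual_risk(d, params)
    rbind(data.frame(site_id = as.character(site_id), scenario = scenario,
                     dose_mg_kg_d = d, annual_risk_per_a = r,
                     stringsAsFactors = FALSE),
          data.frame(site_id = "Mean", scenario = scenario,
                     dose_mg_kg_d = mean(d, na.rm = TRUE),
                     annual_risk_per_a = mean(r, na.rm = TRUE)))
  }
  out <- rbind(one("measured_leaching", mu),
               one("total_transfer", rep(1, length(mu))))
  rownames(out) <- NULL
  out
}
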
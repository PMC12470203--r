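# Domain vocabulary, CSV schemas and validation for soil / organ / infusion
# tables.  All concentrations are stored in the units of the column name:
# totals in mg kg^-1, available fractions in ug kg^-1, infusions in ug L^-1.
# Unit conversions happen inside index computations, never at rest.

# organ vocabulary, proximal -> distal along the plant axis
.ORGANS <- c("fibrous_root", "taproot", "main_stem", "lateral_stem",
             "old_leaf", "young_leaf")
.ELEMENTS <- c("Cd", "Se")

# sanctioned adjacent (child, parent) steps of the transport chain; both leaf
# classes attach to the lateral stem, and the infusion to the young leaf
.CHAIN <- list(c("taproot",      "fibrous_root"),
               c("main_stem",    "taproot"),
               c("lateral_stem", "main_stem"),
               c("old_leaf",     "lateral_stem"),
               c("young_leaf",   "lateral_stem"),
               c("infusion",     "young_leaf"))

.SOIL_REQUIRED <- c("site_id", "cd_total_mg_kg", "cd_avail_ug_kg",
                    "se_total_mg_kg", "se_avail_ug_kg")
.SOIL_OPTIONAL <- c("ph", "som_g_kg", "tn_g_kg", "tp_g_kg", "ap_mg_kg",
                    "ak_mg_kg")
.ORGAN_COLS    <- c("site_id", "organ", "element", "replicate", "conc_mg_kg")
.INFUSION_COLS <- c("site_id", "element", "conc_ug_L", "tea_mass_kg",
                    "water_volume_L")

#' Tea tree organ vocabulary
#'
#' The closed six-organ set used throughout the package, ordered from the
#' proximal (fibrous root) to the distal (young leaf) end of the plant.
#'
#' @return Character vector of the six organ labels.
#' @export
#' @examples
#' tea_organs()
tea_organs <- function() .ORGANS

#' Sanctioned transport-chain steps
#'
#' Adjacent organ pairs along which a transport coefficient is defined.
#' Both leaf classes attach to the lateral stem; the brewed infusion is the
#' terminal compartment after the young leaf.
#'
#' @return A data frame with columns `child` and `parent`; the transport
#'   coefficient for a step is child concentration over parent concentration.
#' @export
transport_pairs <- function() {
  data.frame(child  = vapply(.CHAIN, `[`, "", 1),
             parent = vapply(.CHAIN, `[`, "", 2))
}

#' Brew specification
#'
#' Parameters of a single steeping.  Defaults reproduce the reference
#' protocol: 5.000 g of green tea infused in 100 mL of boiling deionized
#' water for 10 minutes.
#'
#' @param tea_mass Dry tea mass, kg.
#' @param water_volume Infusion water volume, L.
#' @param steep_minutes Steeping time, minutes.
#' @param water_temp Water temperature, degrees C.
#' @return An object of class `brew_spec`.
#' @export
#' @examples
#' brew_spec()          # the 5 g / 100 mL reference brew
brew_spec <- function(tea_mass = 0.005, water_volume = 0.100,
                      steep_minutes = 10, water_temp = 100) {
  stopifnot(is.numeric(tea_mass), length(tea_mass) == 1L,
            is.numeric(water_volume), length(water_volume) == 1L)
  if (!is.finite(tea_mass) || tea_mass <= 0)
    stop("brew_spec: 'tea_mass' must be a positive mass in kg", call. = FALSE)
  if (!is.finite(water_volume) || water_volume <= 0)
    stop("brew_spec: 'water_volume' must be a positive volume in L",
         call. = FALSE)
  structure(list(tea_mass = tea_mass, water_volume = water_volume,
                 steep_minutes = steep_minutes, water_temp = water_temp),
            class = "brew_spec")
}

#' @export
print.brew_spec <- function(x, ...) {
  cat(sprintf("Brew: %.3f kg tea in %.3f L water, %g min at %g degC\n",
              x$tea_mass, x$water_volume, x$steep_minutes, x$water_temp))
  invisible(x)
}

#' Exposure-model parameters
#'
#' Constants of the carcinogenic risk chain.  `daily_intake` is the average
#' daily dry-tea consumption (kg d^-1), `body_weight` the reference adult
#' body weight (kg), `q_ig` the carcinogenic intensity (slope-factor-like)
#' coefficient of Cd ((mg kg^-1 d^-1)^-1) and `averaging_constant` the
#' unitless divisor converting lifetime excess probability into an average
#' individual annual risk.  Both 70s are independently configurable.
#'
#' @param daily_intake Daily dry-tea intake, kg d^-1.
#' @param body_weight Body weight, kg.
#' @param q_ig Carcinogenic intensity coefficient of Cd.
#' @param averaging_constant Unitless annual-averaging divisor.
#' @return An object of class `risk_params`.
#' @export
risk_params <- function(daily_intake = 0.0114, body_weight = 70,
                        q_ig = 6.1, averaging_constant = 70) {
  vals <- c(daily_intake = daily_intake, body_weight = body_weight,
            q_ig = q_ig, averaging_constant = averaging_constant)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("risk_params: all parameters must be strictly positive",
         call. = FALSE)
  structure(as.list(vals), class = "risk_params")
}

#' @export
print.risk_params <- function(x, ...) {
  cat(sprintf(paste0("Risk parameters: intake %.4f kg/d, body weight %g kg, ",
                     "q_ig %.2f, averaging constant %g\n"),
              x$daily_intake, x$body_weight, x$q_ig, x$averaging_constant))
  invisible(x)
}

# ---- validation -----------------------------------------------------------

.check_cols <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: schema error, missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

.num <- function(x) suppressWarnings(as.numeric(x))

# Collect per-row validation messages; a positive-length return aborts the
# study constructor with all offending rows listed.
.validate_soil <- function(soil) {
  errs <- character()
  chk <- function(cond, row, msg)
    if (isTRUE(cond)) errs[[length(errs) + 1L]] <<- sprintf("soil row %d: %s", row, msg)
  if (anyDuplicated(soil$site_id))
    errs <- c(errs, sprintf("soil: duplicate site_id '%s'",
                            soil$site_id[duplicated(soil$site_id)][1]))
  for (i in seq_len(nrow(soil))) {
    if (is.na(soil$site_id[i]) || !nzchar(soil$site_id[i]))
      chk(TRUE, i, "empty site_id")
    if (!is.na(soil$cd_total_mg_kg[i]) && soil$cd_total_mg_kg[i] <= 0)
      chk(TRUE, i, "cd_total_mg_kg must be > 0")
    if (!is.na(soil$se_total_mg_kg[i]) && soil$se_total_mg_kg[i] <= 0)
      chk(TRUE, i, "se_total_mg_kg must be > 0")
    if (!is.na(soil$cd_avail_ug_kg[i]) && soil$cd_avail_ug_kg[i] < 0)
      chk(TRUE, i, "cd_avail_ug_kg must be >= 0")
    if (!is.na(soil$se_avail_ug_kg[i]) && soil$se_avail_ug_kg[i] < 0)
      chk(TRUE, i, "se_avail_ug_kg must be >= 0")
    if (!is.na(soil$ph[i]) && (soil$ph[i] < 3 || soil$ph[i] > 10))
      chk(TRUE, i, "ph outside the plausible range [3, 10]")
  }
  errs
}

.validate_organs <- function(organs) {
  errs <- character()
  for (i in seq_len(nrow(organs))) {
    if (!organs$organ[i] %in% .ORGANS)
      errs <- c(errs, sprintf(
        "organs row %d: unknown organ label '%s' (allowed: %s)",
        i, organs$organ[i], paste(.ORGANS, collapse = ", ")))
    if (!organs$element[i] %in% .ELEMENTS)
      errs <- c(errs, sprintf("organs row %d: unknown element '%s'",
                              i, organs$element[i]))
    if (!is.na(organs$conc_mg_kg[i]) && organs$conc_mg_kg[i] < 0)
      errs <- c(errs, sprintf("organs row %d: negative concentration", i))
    if (is.na(organs$replicate[i]) || organs$replicate[i] < 1 ||
        organs$replicate[i] != round(organs$replicate[i]))
      errs <- c(errs, sprintf("organs row %d: replicate must be a positive integer", i))
  }
  key <- paste(organs$site_id, organs$organ, organs$element, organs$replicate)
  if (anyDuplicated(key))
    errs <- c(errs, sprintf(
      "organs: duplicate (site, organ, element, replicate) key '%s'",
      key[duplicated(key)][1]))
  errs
}

.validate_infusion <- function(infusion) {
  errs <- character()
  for (i in seq_len(nrow(infusion))) {
    if (!infusion$element[i] %in% .ELEMENTS)
      errs <- c(errs, sprintf("infusion row %d: unknown element '%s'",
                              i, infusion$element[i]))
    if (!is.na(infusion$conc_ug_L[i]) && infusion$conc_ug_L[i] < 0)
      errs <- c(errs, sprintf("infusion row %d: negative concentration", i))
    if (!is.na(infusion$tea_mass_kg[i]) && infusion$tea_mass_kg[i] <= 0)
      errs <- c(errs, sprintf("infusion row %d: tea_mass_kg must be > 0", i))
    if (!is.na(infusion$water_volume_L[i]) && infusion$water_volume_L[i] <= 0)
      errs <- c(errs, sprintf("infusion row %d: water_volume_L must be > 0", i))
  }
  key <- paste(infusion$site_id, infusion$element)
  if (anyDuplicated(key))
    errs <- c(errs, sprintf("infusion: duplicate (site, element) key '%s'",
                            key[duplicated(key)][1]))
  errs
}

# ---- study bundle ---------------------------------------------------------

#' Assemble and validate a study bundle
#'
#' Bundles the three long-format tables of a soil-tea-infusion study into a
#' single validated object.  Missing values (`NA`) are allowed everywhere a
#' quantity can genuinely be unmeasured; indices consuming them propagate
#' `NA` rather than failing.
#'
#' @param soil Data frame with columns `site_id`, `cd_total_mg_kg`,
#'   `cd_avail_ug_kg`, `se_total_mg_kg`, `se_avail_ug_kg` and optionally
#'   `ph`, `som_g_kg`, `tn_g_kg`, `tp_g_kg`, `ap_mg_kg`, `ak_mg_kg`.
#' @param organs Data frame with columns `site_id`, `organ`, `element`,
#'   `replicate`, `conc_mg_kg` (dry weight).
#' @param infusion Data frame with columns `site_id`, `element`,
#'   `conc_ug_L`, `tea_mass_kg`, `water_volume_L`.
#' @param brew Default [brew_spec()] used to fill missing brew columns.
#' @return An object of class `tea_study`: a list with elements `soil`,
#'   `organs`, `infusion`, `brew`.
#' @export
tea_study <- function(soil, organs, infusion, brew = brew_spec()) {
  .check_cols(soil, .SOIL_REQUIRED, "soil")
  .check_cols(organs, .ORGAN_COLS, "organs")
  .check_cols(infusion, .INFUSION_COLS, "infusion")
  soil <- as.data.frame(soil); organs <- as.data.frame(organs)
  infusion <- as.data.frame(infusion)
  for (col in .SOIL_OPTIONAL) if (!col %in% names(soil)) soil[[col]] <- NA_real_
  soil <- soil[c(.SOIL_REQUIRED, .SOIL_OPTIONAL)]
  organs <- organs[.ORGAN_COLS]
  infusion <- infusion[.INFUSION_COLS]
  soil$site_id <- as.character(soil$site_id)
  organs$site_id <- as.character(organs$site_id)
  organs$organ <- as.character(organs$organ)
  organs$element <- as.character(organs$element)
  infusion$site_id <- as.character(infusion$site_id)
  infusion$element <- as.character(infusion$element)
  for (col in setdiff(names(soil), "site_id")) soil[[col]] <- .num(soil[[col]])
  organs$replicate <- .num(organs$replicate)
  organs$conc_mg_kg <- .num(organs$conc_mg_kg)
  for (col in c("conc_ug_L", "tea_mass_kg", "water_volume_L"))
    infusion[[col]] <- .num(infusion[[col]])
  infusion$tea_mass_kg[is.na(infusion$tea_mass_kg)] <- brew$tea_mass
  infusion$water_volume_L[is.na(infusion$water_volume_L)] <- brew$water_volume

  errs <- c(.validate_soil(soil), .validate_organs(organs),
            .validate_infusion(infusion))
  if (length(errs))
    stop("validation error:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  unknown <- setdiff(unique(c(organs$site_id, infusion$site_id)),
                     soil$site_id)
  if (length(unknown))
    stop("validation error:\n  site(s) absent from the soil table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  structure(list(soil = soil, organs = organs, infusion = infusion,
                 brew = brew), class = "tea_study")
}

#' @export
print.tea_study <- function(x, ...) {
  cat(sprintf(paste0("Soil-tea-infusion study: %d sites, %d organ ",
                     "measurements, %d infusion measurements\n"),
              nrow(x$soil), nrow(x$organs), nrow(x$infusion)))
  invisible(x)
}

#' Read a study bundle from CSV files
#'
#' Reads and validates the three long-format tables.  Validation failures
#' are reported with the offending row numbers; unknown organ labels,
#' negative concentrations and duplicate keys are all rejected.  Empty cells
#' become `NA`.
#'
#' @param soil_path,organ_path,infusion_path Paths to the soil, organ and
#'   infusion CSV files (schemas as in [tea_study()]).
#' @param brew Default [brew_spec()] for infusion rows lacking brew columns.
#' @return A validated [tea_study()] object.
#' @export
read_study <- function(soil_path, organ_path, infusion_path,
                       brew = brew_spec()) {
  for (p in c(soil_path, organ_path, infusion_path))
    if (!file.exists(p)) stop("read_study: no such file: ", p, call. = FALSE)
  rd <- function(p) read.csv(p, stringsAsFactors = FALSE,
                             na.strings = c("", "NA"), check.names = FALSE)
  tea_study(rd(soil_path), rd(organ_path), rd(infusion_path), brew = brew)
}

#' Write a study bundle to CSV files
#'
#' Writes `soil.csv`, `organs.csv` and `infusion.csv` under `out_dir` in the
#' same schemas [read_study()] consumes; missing values become empty cells
#' (never `"0"`), so `read_study(write_study(x))` round-trips up to float
#' formatting.
#'
#' @param study A [tea_study()] object.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_study <- function(study, out_dir) {
  stopifnot(inherits(study, "tea_study"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(soil = file.path(out_dir, "soil.csv"),
             organs = file.path(out_dir, "organs.csv"),
             infusion = file.path(out_dir, "infusion.csv"))
  write.csv(study$soil, paths[["soil"]], row.names = FALSE, na = "")
  write.csv(study$organs, paths[["organs"]], row.names = FALSE, na = "")
  write.csv(study$infusion, paths[["infusion"]], row.names = FALSE, na = "")
  invisible(paths)
}
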
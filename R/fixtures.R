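# Bundled reference survey: twelve Se-enriched tea gardens (southern Anhui,
# China), re-entered from the published per-site summary tables
# (mean +/- sd over three replicates per garden).

.extdata <- function(file) {
  p <- system.file("extdata", file, package = "teatrace")
  if (!nzchar(p)) stop("bundled fixture not found: ", file, call. = FALSE)
  p
}

#' Reference garden survey: summary tables
#'
#' The per-site summary tables of a field survey of twelve Se-enriched tea
#' gardens: soil Cd/Se pools with their activation rates and pollution
#' indices, Cd and Se concentrations in six tea tree organs, and infusion
#' concentrations with leaching rates and annual carcinogenic risks.  All
#' values are site means with their standard deviations (n = 3 quadrats per
#' garden); concentrations follow the package unit conventions (totals
#' mg kg^-1, available fractions ug kg^-1, infusions ug L^-1).
#'
#' @return A list of three data frames: `soil`, `organs`, `infusion`.
#' @seealso [garden_survey_study()] for the same data as a long-format
#'   [tea_study()] bundle.
#' @export
#' @examples
#' tabs <- garden_survey_tables()
#' nrow(tabs$soil)    # 12 gardens
garden_survey_tables <- function() {
  rd <- function(f) read.csv(.extdata(f), stringsAsFactors = FALSE,
                             na.strings = c("", "NA"))
  list(soil = rd("garden_soil_summary.csv"),
       organs = rd("garden_organs_summary.csv"),
       infusion = rd("garden_infusion_summary.csv"))
}

#' Reference garden survey as a study bundle
#'
#' Converts the summary tables of [garden_survey_tables()] into a validated
#' long-format [tea_study()].  Site means enter as a single pseudo-replicate
#' (`replicate = 1`); the sd columns are dropped (use
#' [anova_from_summary()] on the summary tables when letters are needed).
#' Soil covariates (pH, SOM, ...) were not tabulated per site in the source
#' survey and are left missing.
#'
#' @return A [tea_study()] with 12 soil rows, 144 organ rows
#'   (12 sites x 6 organs x 2 elements) and 24 infusion rows.
#' @export
garden_survey_study <- function() {
  tabs <- garden_survey_tables()
  soil <- data.frame(site_id = tabs$soil$site_id,
                     cd_total_mg_kg = tabs$soil$cd_total_mg_kg,
                     cd_avail_ug_kg = tabs$soil$cd_avail_ug_kg,
                     se_total_mg_kg = tabs$soil$se_total_mg_kg,
                     se_avail_ug_kg = tabs$soil$se_avail_ug_kg)
  organs <- data.frame(site_id = tabs$organs$site_id,
                       organ = tabs$organs$organ,
                       element = tabs$organs$element,
                       replicate = 1L,
                       conc_mg_kg = tabs$organs$mean_mg_kg)
  brew <- brew_spec()
  infusion <- rbind(
    data.frame(site_id = tabs$infusion$site_id, element = "Cd",
               conc_ug_L = tabs$infusion$cd_infusion_ug_L),
    data.frame(site_id = tabs$infusion$site_id, element = "Se",
               conc_ug_L = tabs$infusion$se_infusion_ug_L))
  infusion$tea_mass_kg <- brew$tea_mass
  infusion$water_volume_L <- brew$water_volume
  tea_study(soil, organs, infusion, brew = brew)
}
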
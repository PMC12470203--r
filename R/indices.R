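# Ratio indices of soil-plant transfer studies.  All computation is in full
# precision; display rounding is confined to the report layer.

# division with missing-with-warning semantics for zero denominators, so a
# below-LOQ zero in a field table does not abort a whole pipeline run
.safe_ratio <- function(num, den, what) {
  bad <- !is.na(den) & den == 0
  if (any(bad))
    warning(sprintf("%s: zero denominator in %d value(s); returning NA",
                    what, sum(bad)), call. = FALSE)
  out <- num / den
  out[bad] <- NA_real_
  out
}

#' Single-factor pollution index
#'
#' `Pi = Ci / Si`: measured soil Cd over the evaluation standard.  The
#' default standard is the tea-garden background limit of 0.300 mg kg^-1
#' (300 ug kg^-1).
#'
#' @param cd_total Soil total Cd, mg kg^-1.  Vectorized.
#' @param standard Evaluation standard, mg kg^-1; must be positive.
#' @return The unitless index; > 1 indicates pollution.
#' @export
#' @examples
#' pollution_index(0.48)   # 1.6: slight pollution
pollution_index <- function(cd_total, standard = 0.300) {
  if (!is.numeric(standard) || length(standard) != 1L ||
      !is.finite(standard) || standard <= 0)
    stop("pollution_index: 'standard' must be a single positive value",
         call. = FALSE)
  cd_total / standard
}

#' Verbal pollution class of a single-factor index
#'
#' Labels an index value: below 0.7 "safe", 0.7 to 1.0 "below safety
#' standard", above 1.0 "slight pollution".
#'
#' @param pi Pollution index values.
#' @return Character vector of class labels.
#' @export
pollution_class <- function(pi) {
  out <- rep(NA_character_, length(pi))
  out[!is.na(pi) & pi < 0.7] <- "safe"
  out[!is.na(pi) & pi >= 0.7 & pi <= 1.0] <- "below safety standard"
  out[!is.na(pi) & pi > 1.0] <- "slight pollution"
  out
}

#' Activation rate of a soil element
#'
#' `AR = available / total x 100%`, the extractant-soluble fraction of the
#' soil pool, a proxy for bioavailability.  The available fraction is given
#' in ug kg^-1 and the total in mg kg^-1, so the ug -> mg conversion
#' (factor 1000) is applied here exactly once.
#'
#' @param available Available (DTPA- or NaHCO3-extractable) fraction,
#'   ug kg^-1.  Vectorized.
#' @param total Soil total, mg kg^-1.
#' @return Percent.  A zero total yields `NA` with a warning.
#' @export
#' @examples
#' activation_rate(50, 0.5)    # 10 %
activation_rate <- function(available, total) {
  if (any(!is.na(total) & total < 0))
    stop("activation_rate: 'total' must be nonnegative", call. = FALSE)
  .safe_ratio(available, total * 1000, "activation_rate") * 100
}

#' Enrichment coefficient
#'
#' `EC = Xi / Xs`: organ concentration over soil concentration of the same
#' element, both mg kg^-1.  Measures the accumulation capacity of an organ.
#'
#' @param organ_conc Organ concentration, mg kg^-1 dry weight.  Vectorized.
#' @param soil_conc Soil total concentration, mg kg^-1.
#' @return Unitless ratio; zero soil concentration yields `NA` with a
#'   warning.
#' @export
enrichment_coefficient <- function(organ_conc, soil_conc) {
  if (any(!is.na(soil_conc) & soil_conc < 0))
    stop("enrichment_coefficient: 'soil_conc' must be nonnegative",
         call. = FALSE)
  .safe_ratio(organ_conc, soil_conc, "enrichment_coefficient")
}

#' Transport coefficient between adjacent organs
#'
#' `TC = Xj / Xk`: concentration in a distal (child) organ over its adjacent
#' proximal (parent) organ.  Only the sanctioned steps of the transport
#' chain are accepted (see [transport_pairs()]); asking for a non-adjacent
#' pair is a contract error.
#'
#' @param child_conc,parent_conc Concentrations, mg kg^-1.  Vectorized.
#' @param child,parent Organ labels identifying the step (the infusion is
#'   allowed as terminal child of the young leaf).
#' @return Unitless ratio; a zero parent concentration yields `NA` with a
#'   warning.
#' @export
#' @examples
#' transport_coefficient(0.31, 0.31, "main_stem", "taproot")  # 1
transport_coefficient <- function(child_conc, parent_conc, child, parent) {
  ok <- any(vapply(.CHAIN, function(p) p[1] == child && p[2] == parent,
                   logical(1)))
  if (!ok) {
    steps <- vapply(.CHAIN, function(p) paste(p[2], "->", p[1]), "")
    stop(sprintf(paste0("transport_coefficient: '%s' is not the sanctioned ",
                        "child of '%s'; allowed steps: %s"),
                 child, parent, paste(steps, collapse = ", ")),
         call. = FALSE)
  }
  if (any(!is.na(parent_conc) & parent_conc < 0))
    stop("transport_coefficient: 'parent_conc' must be nonnegative",
         call. = FALSE)
  .safe_ratio(child_conc, parent_conc, "transport_coefficient")
}

#' Leaching rate from dry tea to infusion
#'
#' Mass fraction of an element passing into the brewed infusion during one
#' steeping: `(C_infusion x V) / (C_tea x m x 1000) x 100`, i.e. the element
#' mass in the infusion (ug) over the element mass in the dry tea (mg,
#' converted to ug exactly once).
#'
#' @param infusion_ug_L Infusion concentration, ug L^-1.  Vectorized.
#' @param tea_conc_mg_kg Dry-tea concentration, mg kg^-1.
#' @param brew A [brew_spec()] giving tea mass (kg) and water volume (L).
#' @return Percent; a zero tea concentration yields `NA` with a warning.
#' @export
#' @examples
#' leaching_rate(0.1, 0.02)   # 10 % under the default 5 g / 100 mL brew
leaching_rate <- function(infusion_ug_L, tea_conc_mg_kg,
                          brew = brew_spec()) {
  stopifnot(inherits(brew, "brew_spec"))
  .safe_ratio(infusion_ug_L * brew$water_volume,
              tea_conc_mg_kg * brew$tea_mass * 1000, "leaching_rate") * 100
}

#' Grouped mean +/- sd summary with pooled row
#'
#' Summarizes values by group as mean and sample standard deviation (n - 1
#' denominator), appending a pooled `"Mean"` row computed over the group
#' means -- the convention of the bottom row of survey summary tables.
#'
#' @param values Numeric vector.
#' @param groups Grouping labels, same length; each group must contain at
#'   least one non-missing value.
#' @return Data frame with columns `group`, `n`, `mean`, `sd` (the sd is
#'   `NA` for singleton groups) plus the pooled `"Mean"` row.
#' @export
#' @examples
#' group_summary(c(1, 2, 3), c("a", "a", "a"))
group_summary <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  spl <- split(as.numeric(values), factor(groups, levels = unique(groups)))
  n <- vapply(spl, function(v) sum(!is.na(v)), integer(1))
  if (any(n < 1))
    stop("group_summary: group(s) with no non-missing values: ",
         paste(names(spl)[n < 1], collapse = ", "), call. = FALSE)
  m <- vapply(spl, function(v) mean(v, na.rm = TRUE), numeric(1))
  s <- vapply(spl, function(v)
    if (sum(!is.na(v)) >= 2) sd(v, na.rm = TRUE) else NA_real_, numeric(1))
  out <- data.frame(group = names(spl), n = n, mean = m, sd = s,
                    row.names = NULL, stringsAsFactors = FALSE)
  pooled <- data.frame(group = "Mean", n = length(m), mean = mean(m),
                       sd = if (length(m) >= 2) sd(m) else NA_real_)
  rbind(out, pooled)
}

# ---- study-level index table ---------------------------------------------

#' Per-site transfer indices of a study
#'
#' Computes every ratio index for one element of a study bundle: pollution
#' index (Cd only), activation rate, per-organ enrichment coefficients,
#' transport coefficients along the sanctioned chain, and the infusion
#' leaching rate.  Ratios are formed per replicate, then averaged to a site
#' value ("mean of ratios"); cross-site averages of the site values
#' reproduce the usual survey summaries (see [index_means()]).
#'
#' @param study A [tea_study()].
#' @param element `"Cd"` or `"Se"`.
#' @return Long data frame with columns `site_id`, `index_name`
#'   (`Pi`, `ARCd`/`ARSe`, `EC`, `TC`, `leaching`), `qualifier` (organ or
#'   `parent->child` step; `NA` for soil indices) and `value`.
#' @export
study_indices <- function(study, element = c("Cd", "Se")) {
  stopifnot(inherits(study, "tea_study"))
  element <- match.arg(element)
  soil <- study$soil
  soil_total <- if (element == "Cd") soil$cd_total_mg_kg else soil$se_total_mg_kg
  soil_avail <- if (element == "Cd") soil$cd_avail_ug_kg else soil$se_avail_ug_kg
  rows <- list()
  add <- function(site, name, qual, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      site_id = site, index_name = name, qualifier = qual, value = value,
      stringsAsFactors = FALSE)

  if (element == "Cd")
    add(soil$site_id, "Pi", NA_character_, pollution_index(soil$cd_total_mg_kg))
  add(soil$site_id, paste0("AR", element), NA_character_,
      activation_rate(soil_avail, soil_total))

  org <- study$organs[study$organs$element == element, , drop = FALSE]
  if (nrow(org)) {
    st <- soil_total[match(org$site_id, soil$site_id)]
    ec_rep <- enrichment_coefficient(org$conc_mg_kg, st)
    agg <- aggregate(ec_rep,
                     by = list(site_id = org$site_id, organ = org$organ),
                     FUN = mean, na.rm = TRUE)
    add(agg$site_id, "EC", agg$organ, agg$x)

    for (p in .CHAIN) {
      if (p[1] == "infusion") next
      ch <- org[org$organ == p[1], c("site_id", "replicate", "conc_mg_kg")]
      pa <- org[org$organ == p[2], c("site_id", "replicate", "conc_mg_kg")]
      if (!nrow(ch) || !nrow(pa)) next
      m <- merge(ch, pa, by = c("site_id", "replicate"),
                 suffixes = c("_child", "_parent"))
      if (!nrow(m)) next
      tc_rep <- transport_coefficient(m$conc_mg_kg_child, m$conc_mg_kg_parent,
                                      p[1], p[2])
      agg <- aggregate(tc_rep, by = list(site_id = m$site_id),
                       FUN = mean, na.rm = TRUE)
      add(agg$site_id, "TC", paste0(p[2], "->", p[1]), agg$x)
    }
  }

  inf <- study$infusion[study$infusion$element == element, , drop = FALSE]
  yl <- org[org$organ == "young_leaf", , drop = FALSE]
  if (nrow(inf) && nrow(yl)) {
    yl_site <- aggregate(yl$conc_mg_kg, by = list(site_id = yl$site_id),
                         FUN = mean, na.rm = TRUE)
    tea <- yl_site$x[match(inf$site_id, yl_site$site_id)]
    mu <- vapply(seq_len(nrow(inf)), function(i)
      leaching_rate(inf$conc_ug_L[i], tea[i],
                    brew_spec(tea_mass = inf$tea_mass_kg[i],
                              water_volume = inf$water_volume_L[i])),
      numeric(1))
    add(inf$site_id, "leaching", "young_leaf->infusion", mu)
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-site means of per-site indices
#'
#' Averages the site values of [study_indices()] within each index/qualifier
#' combination -- the "cross-site mean of per-site ratios" convention.
#'
#' @param indices Output of [study_indices()].
#' @return Data frame with columns `index_name`, `qualifier`, `n`, `mean`,
#'   `sd`.
#' @export
index_means <- function(indices) {
  qual <- ifelse(is.na(indices$qualifier), "", indices$qualifier)
  key <- factor(paste(indices$index_name, qual, sep = "\r"),
                levels = unique(paste(indices$index_name, qual, sep = "\r")))
  spl <- split(indices$value, key)
  parts <- strsplit(names(spl), "\r", fixed = TRUE)
  data.frame(
    index_name = vapply(parts, `[`, "", 1),
    qualifier = ifelse(vapply(parts, length, 0L) < 2L, NA_character_,
                       vapply(parts, function(p) p[2], "")),
    n = vapply(spl, function(v) sum(!is.na(v)), integer(1)),
    mean = vapply(spl, function(v) mean(v, na.rm = TRUE), numeric(1)),
    sd = vapply(spl, function(v)
      if (sum(!is.na(v)) >= 2) sd(v, na.rm = TRUE) else NA_real_, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
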
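# End-to-end orchestration: load or simulate a study, compute indices,
# letters, risks and the statistical layer, and write report tables that
# mirror the customary survey presentation (soil table, organ table,
# infusion/risk table).  Display rounding lives here and only here: ratios
# and concentrations to 2 decimals, risks in scientific notation with 3
# significant digits; every CSV cell is a pure formatting of the unrounded
# pipeline store returned invisibly.

.round2 <- function(x) round(x, 2)
.sci3 <- function(x) ifelse(is.na(x), NA_character_,
                            formatC(x, format = "e", digits = 2))

.default_config <- list(element = "Cd", alpha = 0.05, breakpoint = 2.0,
                        out_dir = "teatrace_out", log_level = "info")

#' Run the full transfer-analysis pipeline
#'
#' One-call orchestration.  `config` is a list (or path to a YAML file)
#' with exactly one of:
#'
#' * `input`: list with `soil`, `organs`, `infusion` CSV paths, or
#' * `simulate`: list of [generator_config()] arguments (a `seed` at
#'   minimum),
#'
#' plus optional `element` (`"Cd"`, default, or `"Se"`), `alpha`,
#' `breakpoint` (numeric, or `"search"`), `risk` (list of [risk_params()]
#' arguments) and `out_dir`.  Stages run in order -- load/simulate,
#' indices, letters, risk (Cd only; for Se the stage is skipped with a
#' logged notice), correlation, threshold regression, report -- and any
#' stage failure aborts with the stage name.
#'
#' Outputs written under `out_dir`: `table1.csv` (soil pools, activation
#' rates, pollution index), `table2.csv` (organ concentrations with
#' letters when replicates allow), `table3.csv` (infusion, leaching,
#' risks), `indices.csv` (unrounded long store), `correlation.csv`,
#' `segmented.csv`, `run.log` and the resolved `config.yaml`.
#'
#' @param config List or YAML path, see Details.
#' @return Invisibly, a list with the unrounded `study`, `indices`,
#'   `index_means`, `risk`, `correlation`, `segmented`, `letters`, the
#'   resolved `config` and the written `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  cfg <- utils::modifyList(.default_config, config)
  has_input <- !is.null(cfg$input); has_sim <- !is.null(cfg$simulate)
  if (has_input == has_sim)
    stop("run_pipeline: exactly one of 'input' or 'simulate' must be given",
         call. = FALSE)
  element <- match.arg(cfg$element, c("Cd", "Se"))
  params <- do.call(risk_params, as.list(cfg$risk))
  # no timestamps: a fixed config + seed must reproduce byte-identical output
  log <- character()
  note <- function(...) log[[length(log) + 1L]] <<- sprintf(...)
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s': %s", name, conditionMessage(e)),
           call. = FALSE))

  study <- stage("load", {
    if (has_input) {
      s <- read_study(cfg$input$soil, cfg$input$organs, cfg$input$infusion)
      note("loaded study from CSV inputs")
      s
    } else {
      sim <- simulate_study(do.call(generator_config, as.list(cfg$simulate)))
      note("simulated study (seed %d)", sim$truth$config$seed)
      sim$study
    }
  })
  note("records: %d soil, %d organ, %d infusion rows",
       nrow(study$soil), nrow(study$organs), nrow(study$infusion))

  idx <- stage("indices", study_indices(study, element))
  idx_means <- index_means(idx)
  note("indices: %d per-site values across %d index groups",
       nrow(idx), nrow(idx_means))

  # letters per organ across sites, when replicate structure allows
  letters_tab <- stage("letters", {
    org <- study$organs[study$organs$element == element, , drop = FALSE]
    reps <- tapply(org$replicate, org$site_id, function(r) length(unique(r)))
    if (nrow(org) && all(reps >= 2)) {
      out <- lapply(tea_organs(), function(oo) {
        d <- org[org$organ == oo & !is.na(org$conc_mg_kg), , drop = FALSE]
        res <- anova_lsd(d$conc_mg_kg, d$site_id, alpha = cfg$alpha)
        data.frame(organ = oo, site_id = res$groups, letter = res$letters,
                   stringsAsFactors = FALSE)
      })
      note("letter displays computed for %d organs", length(out))
      do.call(rbind, out)
    } else {
      note("letters skipped: fewer than 2 replicates per site")
      NULL
    }
  })

  risk <- stage("risk", {
    if (element != "Cd") {
      note("risk stage skipped: no Se risk model, indices still produced")
      NULL
    } else {
      yl <- study$organs[study$organs$element == "Cd" &
                           study$organs$organ == "young_leaf", , drop = FALSE]
      tea <- tapply(yl$conc_mg_kg, yl$site_id, mean, na.rm = TRUE)
      mu <- idx[idx$index_name == "leaching", , drop = FALSE]
      sites <- intersect(names(tea), mu$site_id)
      suppressMessages(
        risk_table(as.numeric(tea[sites]),
                   mu$value[match(sites, mu$site_id)], sites, params))
    }
  })

  corr <- stage("correlation", {
    soil <- study$soil
    d <- data.frame(soil[setdiff(names(soil), "site_id")],
                    arcd_pct = activation_rate(soil$cd_avail_ug_kg,
                                               soil$cd_total_mg_kg))
    d <- d[vapply(d, function(cc) sum(!is.na(cc)) >= 3, logical(1))]
    if (ncol(d) >= 2) suppressWarnings(pearson_matrix(d)) else NULL
  })

  segmented <- stage("threshold", {
    org <- study$organs
    fib <- merge(
      org[org$element == "Cd" & org$organ == "fibrous_root",
          c("site_id", "replicate", "conc_mg_kg")],
      org[org$element == "Se" & org$organ == "fibrous_root",
          c("site_id", "replicate", "conc_mg_kg")],
      by = c("site_id", "replicate"), suffixes = c("_cd", "_se"))
    fib$soil_cd <- study$soil$cd_total_mg_kg[match(fib$site_id,
                                                   study$soil$site_id)]
    fib <- fib[complete.cases(fib), , drop = FALSE]
    bp <- cfg$breakpoint
    if (nrow(fib) >= 6) {
      ec <- fib$conc_mg_kg_cd / fib$soil_cd
      if (identical(bp, "search"))
        threshold_fit(fib$conc_mg_kg_se, ec)
      else threshold_fit(fib$conc_mg_kg_se, ec, breakpoint = as.numeric(bp))
    } else {
      note("threshold stage skipped: fewer than 6 fibrous-root pairs")
      NULL
    }
  })

  paths <- stage("report", {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(f) file.path(cfg$out_dir, f)
    soil <- study$soil
    table1 <- data.frame(
      site_id = soil$site_id,
      cd_total_mg_kg = .round2(soil$cd_total_mg_kg),
      cd_avail_ug_kg = .round2(soil$cd_avail_ug_kg),
      arcd_pct = .round2(activation_rate(soil$cd_avail_ug_kg,
                                         soil$cd_total_mg_kg)),
      se_total_mg_kg = .round2(soil$se_total_mg_kg),
      se_avail_ug_kg = .round2(soil$se_avail_ug_kg),
      arse_pct = .round2(activation_rate(soil$se_avail_ug_kg,
                                         soil$se_total_mg_kg)),
      pollution_index = .round2(pollution_index(soil$cd_total_mg_kg)),
      pollution_class = pollution_class(pollution_index(soil$cd_total_mg_kg)))
    write.csv(table1, fp("table1.csv"), row.names = FALSE, na = "")

    org <- study$organs[study$organs$element == element, , drop = FALSE]
    site_mean <- aggregate(conc_mg_kg ~ site_id + organ, org, mean,
                           na.rm = TRUE, na.action = NULL)
    table2 <- data.frame(site_id = unique(study$soil$site_id))
    for (oo in tea_organs()) {
      v <- site_mean$conc_mg_kg[site_mean$organ == oo][
        match(table2$site_id, site_mean$site_id[site_mean$organ == oo])]
      table2[[oo]] <- .round2(v)
      if (!is.null(letters_tab)) {
        lt <- letters_tab[letters_tab$organ == oo, , drop = FALSE]
        table2[[paste0(oo, "_letter")]] <- lt$letter[match(table2$site_id,
                                                           lt$site_id)]
      }
    }
    write.csv(table2, fp("table2.csv"), row.names = FALSE, na = "")

    inf <- study$infusion[study$infusion$element == element, , drop = FALSE]
    mu <- idx[idx$index_name == "leaching", , drop = FALSE]
    table3 <- data.frame(
      site_id = inf$site_id,
      infusion_ug_L = round(inf$conc_ug_L, 3),
      leaching_pct = .round2(mu$value[match(inf$site_id, mu$site_id)]))
    if (!is.null(risk)) {
      rmeas <- risk[risk$scenario == "measured_leaching", ]
      rtot <- risk[risk$scenario == "total_transfer", ]
      table3$annual_risk_measured <-
        .sci3(rmeas$annual_risk_per_a[match(table3$site_id, rmeas$site_id)])
      table3$annual_risk_total <-
        .sci3(rtot$annual_risk_per_a[match(table3$site_id, rtot$site_id)])
      pooled <- data.frame(
        site_id = "Mean",
        infusion_ug_L = round(mean(inf$conc_ug_L, na.rm = TRUE), 3),
        leaching_pct = .round2(mean(mu$value, na.rm = TRUE)),
        annual_risk_measured =
          .sci3(rmeas$annual_risk_per_a[rmeas$site_id == "Mean"]),
        annual_risk_total =
          .sci3(rtot$annual_risk_per_a[rtot$site_id == "Mean"]))
      table3 <- rbind(table3, pooled)
    }
    write.csv(table3, fp("table3.csv"), row.names = FALSE, na = "")

    write.csv(idx, fp("indices.csv"), row.names = FALSE, na = "")
    if (!is.null(corr))
      write.csv(correlation_long(corr), fp("correlation.csv"),
                row.names = FALSE, na = "")
    if (!is.null(segmented))
      write.csv(summary(segmented), fp("segmented.csv"),
                row.names = FALSE, na = "")
    note("report written (%d tables)", 3L)
    resolved <- cfg
    resolved$risk <- unclass(params)
    yaml::write_yaml(resolved, fp("config.yaml"))
    writeLines(log, fp("run.log"))
    vapply(c("table1.csv", "table2.csv", "table3.csv", "indices.csv",
             "config.yaml", "run.log"), fp, "")
  })

  invisible(list(study = study, indices = idx, index_means = idx_means,
                 risk = risk, correlation = corr, segmented = segmented,
                 letters = letters_tab, config = cfg, log = log,
                 paths = paths))
}
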
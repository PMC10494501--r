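# End-to-end pipeline driver and output surfaces: flow counts,
# baseline-characteristics and exposure summaries, incidence tables, IRR
# tables with log-transformed columns for forest plots, and a
# machine-readable run log.

#' Build a study configuration
#'
#' @param inclusion_start,inclusion_end treatment inclusion window
#'   (defaults: 2014-01-01 to 2016-12-31).
#' @param study_end end of the study period (default 2018-12-31), used by
#'   the intent-to-treat censoring.
#' @param specs drug specification table.
#' @param code_map fracture code map.
#' @param covariate_codes covariate code configuration.
#' @param exclusion_codes cancer/Paget diagnosis prefixes.
#' @param modes analysis modes to run.
#' @param strata covariate columns to stratify on (possibly empty).
#' @param grace_days refill grace period.
#' @return a `study_config` list.
#' @export
study_config <- function(inclusion_start = "2014-01-01",
                         inclusion_end = "2016-12-31",
                         study_end = "2018-12-31",
                         specs = default_drug_specs(),
                         code_map = default_fracture_codes(),
                         covariate_codes = default_covariate_codes(),
                         exclusion_codes = default_exclusion_codes(),
                         modes = c("as_treated", "itt", "virtual_exposure"),
                         strata = character(),
                         grace_days = GRACE_DAYS) {
  stopifnot(as_day(study_end) >= as_day(inclusion_end))
  structure(
    list(
      inclusion_start = as_day(inclusion_start),
      inclusion_end = as_day(inclusion_end),
      study_end = as_day(study_end),
      specs = specs, code_map = code_map,
      covariate_codes = covariate_codes,
      exclusion_codes = exclusion_codes,
      modes = match.arg(modes, c("as_treated", "itt", "virtual_exposure"), several.ok = TRUE),
      strata = strata,
      grace_days = as.integer(grace_days)
    ),
    class = "study_config"
  )
}

#' Run the full own-control analysis pipeline
#'
#' Stages: read (or accept) claims; build new-user index dates and
#' treatment episodes; apply eligibility and the hierarchical cohort
#' assignment; identify and deduplicate fracture events; accumulate
#' person-time per analysis mode (with post-discontinuation cells in the
#' as-treated mode); estimate all IRRs; and assemble the descriptive
#' tables. Deterministic given its inputs; any stage failure aborts with
#' the stage name.
#'
#' @param claims either a directory path (read via [read_claims()]) or a
#'   list with `persons`, `dispensings`, `stays`.
#' @param config a [study_config()].
#' @param out_dir optional directory; when given, all tables are written
#'   as CSV plus a JSON run summary.
#' @param irr_method interval method for [irr_ci()].
#' @return list: `flow`, `assignment`, `covariates`, `characteristics`,
#'   `exposure`, `events`, `cells`, `incidence`, `irr`, `posthoc`
#'   (early-discontinuer cells + IRR), `log` (per-stage timings and
#'   record counts).
#' @export
run_pipeline <- function(claims, config = study_config(), out_dir = NULL,
                         irr_method = "exact") {
  log <- list()
  t0 <- Sys.time()
  stage <- function(name, expr) {
    st <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    log[[name]] <<- list(
      seconds = round(as.numeric(difftime(Sys.time(), st, units = "secs")), 3),
      records = if (is.data.frame(res)) nrow(res) else NA_integer_
    )
    res
  }

  if (is.character(claims)) claims <- stage("read_claims", read_claims(claims))
  persons <- claims$persons
  dispensings <- claims$dispensings
  stays <- claims$stays

  index_dates <- stage("index_dates", find_index_dates(
    dispensings, config$specs, config$inclusion_start, config$inclusion_end
  ))
  episodes <- stage("episodes", {
    build_episodes(dispensings, index_dates, config$specs, persons, config$grace_days) %>%
      detect_switches(index_dates)
  })
  elig_full <- stage("eligibility", apply_eligibility(
    persons, episodes, stays, dispensings, config$specs,
    exclusion_codes = config$exclusion_codes
  ))
  elig <- elig_full$flow
  assignment <- stage("assignment", assign_cohorts(elig_full$episode_flags, config$specs))
  covariates <- stage("covariates", extract_covariates(
    stays, dispensings, assignment, config$specs,
    config$covariate_codes, config$code_map
  ))
  events <- stage("events", {
    identify_raw_events(stays, config$code_map) %>% deduplicate_events()
  })

  cells <- stage("persontime", {
    bind_rows(lapply(config$modes, function(m) {
      women <- censor_days(assignment, persons, config$specs, m, config$study_end)
      cc <- accumulate_persontime(women, events)
      if (m == "as_treated") {
        cc <- bind_rows(
          cc,
          post_disc_cells(women, events, dispensings, config$specs, persons)
        )
      }
      cc
    }))
  })

  strat_cells <- NULL
  if (length(config$strata)) {
    strat_cells <- stage("strata", {
      women <- censor_days(assignment, persons, config$specs, "as_treated")
      bind_rows(lapply(config$strata, function(v) {
        stratified_cells(women, events, covariates, v)
      }))
    })
  }

  incidence <- stage("incidence", {
    bind_cols(
      cells %>% select("cohort", "site_group", "window", "mode"),
      rate_ci(cells$events, cells$person_years)
    )
  })
  irr <- stage("irr", run_irr(cells, method = irr_method))
  irr_strat <- if (!is.null(strat_cells)) run_irr(strat_cells, method = irr_method) else NULL

  posthoc <- stage("posthoc", {
    cells_ph <- posthoc_early_discontinuers(
      elig_full$episode_flags, events, persons, config$specs
    )
    list(cells = cells_ph, irr = if (nrow(cells_ph)) run_irr(cells_ph, method = irr_method) else NULL)
  })

  characteristics <- stage("characteristics", summarise_characteristics(assignment, covariates))
  exposure <- stage("exposure", summarise_exposure(assignment, cells))

  log$total_seconds <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3)
  bundle <- list(
    flow = elig, assignment = assignment, covariates = covariates,
    characteristics = characteristics, exposure = exposure,
    events = events, cells = cells, strat_cells = strat_cells,
    incidence = incidence, irr = irr, irr_strat = irr_strat,
    posthoc = posthoc, log = log
  )
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' Cohort characteristics at the index date (descriptive table)
#' @param assignment cohort assignment.
#' @param covariates covariate table.
#' @return one row per cohort: n, age mean and SD, covariate percentages.
#' @export
summarise_characteristics <- function(assignment, covariates) {
  covariates %>%
    group_by(.data$cohort) %>%
    summarise(
      n = n(),
      age_mean = mean(.data$age_at_index),
      age_sd = sd(.data$age_at_index),
      pct_fracture_history = 100 * mean(.data$hist_any),
      pct_prior_ot = 100 * mean(.data$prior_ot),
      pct_dementia = 100 * mean(.data$dementia),
      pct_nervous = 100 * mean(.data$nervous_disorder),
      pct_vitd_calcium = 100 * mean(.data$vitd_calcium),
      pct_densitometry = 100 * mean(.data$densitometry),
      comorbidity_score_mean = mean(.data$comorbidity_score),
      .groups = "drop"
    )
}

#' Treatment-exposure summary (descriptive table)
#' @param assignment cohort assignment.
#' @param cells accumulated cells (used for post-discontinuation
#'   person-time).
#' @return one row per cohort: median/IQR exposure months and
#'   end-of-exposure reason percentages.
#' @export
summarise_exposure <- function(assignment, cells) {
  months <- function(days) days / 30.4375
  assignment %>%
    group_by(.data$cohort) %>%
    summarise(
      n = n(),
      exposure_months_median = median(months(.data$duration_days)),
      exposure_months_q1 = quantile(months(.data$duration_days), 0.25),
      exposure_months_q3 = quantile(months(.data$duration_days), 0.75),
      pct_discontinuation = 100 * mean(.data$end_reason == "discontinuation"),
      pct_switch = 100 * mean(.data$end_reason == "switch"),
      pct_death = 100 * mean(.data$end_reason == "death"),
      pct_end_of_followup = 100 * mean(.data$end_reason == "end_of_followup"),
      .groups = "drop"
    )
}

#' Plot-ready forest data from an IRR table
#'
#' Rows with undefined or non-finite intervals are omitted (their count
#' is reported) and the remainder ordered by cohort, site group and
#' window, carrying the log-IRR and log bounds.
#'
#' @param irr_table output of [run_irr()].
#' @return list: `records` (plot-ready tibble), `n_omitted`.
#' @export
forest_data <- function(irr_table) {
  ok <- irr_table %>%
    filter(
      .data$defined,
      !is.na(.data$log_irr), !is.na(.data$log_ci_low), !is.na(.data$log_ci_high)
    )
  list(
    records = ok %>%
      arrange(.data$cohort, .data$site_group, .data$comparison) %>%
      mutate(label = paste(.data$cohort, .data$site_group, .data$comparison, sep = " | ")) %>%
      select(
        "label", "cohort", "site_group", "comparison",
        "irr", "ci_low", "ci_high", "log_irr", "log_ci_low", "log_ci_high"
      ),
    n_omitted = nrow(irr_table) - nrow(ok)
  )
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (!is.null(df) && is.data.frame(df)) {
      write.csv(df, file.path(out_dir, name), row.names = FALSE, na = "")
    }
  }
  wr(bundle$flow, "flow.csv")
  wr(bundle$characteristics, "characteristics.csv")
  wr(bundle$exposure, "exposure.csv")
  wr(bundle$cells, "cells.csv")
  wr(bundle$incidence, "incidence.csv")
  wr(bundle$irr, "irr.csv")
  wr(bundle$irr_strat, "irr_stratified.csv")
  if (!is.null(bundle$posthoc$irr)) wr(bundle$posthoc$irr, "irr_posthoc.csv")
  fd <- forest_data(bundle$irr)
  wr(fd$records, "forest.csv")
  jsonlite::write_json(
    list(log = bundle$log, n_forest_omitted = fd$n_omitted),
    file.path(out_dir, "run_log.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(out_dir)
}
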
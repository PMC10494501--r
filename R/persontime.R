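# Analysis windows, censoring rules and person-time accumulation.
#
# Windows are half-open day intervals relative to the index date:
# baseline [0, 91), the 3-12 month window [91, 365), 3-18 [91, 548) and
# 3-24 [91, 730). The post-discontinuation window is anchored at the
# discontinuation date instead. Baseline events never censor follow-up:
# a woman contributes person-time to every window regardless of events
# (incidence of independent events, not time-to-first-event).

#' The on-treatment analysis windows
#'
#' @return tibble `window`, `start`, `end` (days relative to index,
#'   half-open).
#' @export
window_specs <- function() {
  tribble(
    ~window,    ~start, ~end,
    "baseline", 0L,     91L,
    "m3_12",    91L,    365L,
    "m3_18",    91L,    548L,
    "m3_24",    91L,    730L
  )
}

#' Compute the censoring day (exclusive) per woman under an analysis mode
#'
#' * `as_treated` — end of the treatment episode (already the earliest of
#'   discontinuation, switch, death and end of data);
#' * `itt` — the end of the study period or death, whichever first,
#'   ignoring treatment;
#' * `virtual_exposure` — the episode end extended by the drug's
#'   carry-over days, capped at death and end of data.
#'
#' @param assignment cohort assignment (one episode per woman).
#' @param persons person table.
#' @param specs drug specification table.
#' @param mode one of "as_treated", "itt", "virtual_exposure".
#' @param study_end last day of the study period (inclusive), used by the
#'   intent-to-treat mode.
#' @return `assignment` with a `censor_day` column (exclusive bound of
#'   the at-risk interval).
#' @export
censor_days <- function(assignment, persons, specs,
                        mode = c("as_treated", "itt", "virtual_exposure"),
                        study_end = NULL) {
  mode <- match.arg(mode)
  x <- assignment %>%
    left_join(persons %>% select("person_id", "death_day", "data_end_day"), by = "person_id") %>%
    left_join(specs %>% select("drug_name", "virtual_extension_days"), by = "drug_name")
  death_bound <- ifelse(is.na(x$death_day), Inf, x$death_day + 1)
  censor <- switch(mode,
    as_treated = x$end_day,
    itt = {
      if (is.null(study_end)) stop("itt mode needs a study_end date")
      pmin(death_bound, as_day(study_end) + 1L)
    },
    virtual_exposure = pmin(
      x$end_day + x$virtual_extension_days,
      death_bound, x$data_end_day + 1L
    )
  )
  assignment %>% mutate(censor_day = as.integer(censor), mode = mode)
}

#' Accumulate events and person-time per (cohort, site group, window)
#'
#' For each woman, `person_days(window) = |[index + start, min(index +
#' end, censor))|` and an independent event is counted when its date lies
#' in that same interval. Totals are summed over women; every
#' (cohort, site group, window) cell is present, zero-filled.
#'
#' @param women assignment with `censor_day` (from [censor_days()]).
#' @param events deduplicated events ([deduplicate_events()]); only
#'   independent events are counted.
#' @param windows window table, default [window_specs()].
#' @param site_groups groups to tabulate.
#' @return cell table: `cohort`, `site_group`, `window`, `mode`,
#'   `events`, `person_days`, `person_years`, `n_women`.
#' @export
accumulate_persontime <- function(women, events, windows = window_specs(),
                                  site_groups = SITE_GROUPS) {
  mode <- if (nrow(women)) women$mode[1L] else NA_character_
  cohorts <- sort(unique(women$cohort))

  pt <- women %>%
    cross_join(windows) %>%
    mutate(
      abs_start = .data$index_day + .data$start,
      abs_end = pmin(.data$index_day + .data$end, .data$censor_day),
      pd = pmax(0L, .data$abs_end - .data$abs_start)
    )
  pt_sum <- pt %>%
    group_by(.data$cohort, .data$window) %>%
    summarise(
      person_days = sum(.data$pd),
      n_women = sum(.data$pd > 0L),
      .groups = "drop"
    )

  ev <- events %>%
    filter(.data$independent) %>%
    assign_site_groups() %>%
    inner_join(
      women %>% select("person_id", "cohort", "index_day", "censor_day"),
      by = "person_id"
    ) %>%
    cross_join(windows) %>%
    filter(
      .data$event_day >= .data$index_day + .data$start,
      .data$event_day < pmin(.data$index_day + .data$end, .data$censor_day)
    ) %>%
    count(.data$cohort, .data$site_group, .data$window, name = "events")

  expand_grid(
    cohort = cohorts, site_group = site_groups,
    window = windows$window
  ) %>%
    left_join(ev, by = c("cohort", "site_group", "window")) %>%
    left_join(pt_sum, by = c("cohort", "window")) %>%
    mutate(
      events = coalesce(.data$events, 0L),
      person_days = coalesce(.data$person_days, 0L),
      n_women = coalesce(.data$n_women, 0L),
      person_years = .data$person_days / DAYS_PER_YEAR,
      mode = mode
    ) %>%
    arrange(.data$cohort, .data$site_group, match(.data$window, windows$window))
}

#' Post-discontinuation cells for women whose episode ended by
#' discontinuation
#'
#' The window runs from the end of coverage up to the first dispensing of
#' any study medication after it, death, or end of data, whichever comes
#' first (as-treated women only; the window is undefined for women who
#' never discontinue).
#'
#' @param women as-treated assignment with `censor_day`.
#' @param events deduplicated events.
#' @param dispensings dispensing table (for reinitiation).
#' @param specs drug specification table.
#' @param persons person table.
#' @param site_groups groups to tabulate.
#' @return cell table with `window = "post_disc"` (empty when no woman
#'   discontinued).
#' @export
post_disc_cells <- function(women, events, dispensings, specs, persons,
                            site_groups = SITE_GROUPS) {
  disc <- women %>%
    filter(.data$end_reason == "discontinuation") %>%
    left_join(persons %>% select("person_id", "death_day", "data_end_day"), by = "person_id")
  empty <- tibble(
    cohort = character(), site_group = character(), window = character(),
    events = integer(), person_days = integer(), n_women = integer(),
    person_years = double(), mode = character()
  )
  if (nrow(disc) == 0L) return(empty)

  reinit <- dispensings %>%
    filter(.data$drug_code %in% unlist(specs$drug_codes)) %>%
    inner_join(disc %>% select("person_id", "end_day"), by = "person_id") %>%
    filter(.data$dispense_day >= .data$end_day)
  reinit <- if (nrow(reinit)) {
    reinit %>%
      group_by(.data$person_id) %>%
      summarise(reinit_day = min(.data$dispense_day), .groups = "drop")
  } else {
    tibble(person_id = character(), reinit_day = integer())
  }

  disc <- disc %>%
    left_join(reinit, by = "person_id") %>%
    mutate(
      pd_start = .data$end_day,
      pd_end = pmin(
        ifelse(is.na(.data$reinit_day), Inf, .data$reinit_day),
        ifelse(is.na(.data$death_day), Inf, .data$death_day + 1),
        .data$data_end_day + 1L
      ),
      pd = pmax(0L, as.integer(.data$pd_end) - .data$pd_start)
    )

  pt_sum <- disc %>%
    group_by(.data$cohort) %>%
    summarise(
      person_days = sum(.data$pd),
      n_women = sum(.data$pd > 0L),
      .groups = "drop"
    )
  ev <- events %>%
    filter(.data$independent) %>%
    assign_site_groups() %>%
    inner_join(
      disc %>% select("person_id", "cohort", "pd_start", "pd_end"),
      by = "person_id"
    ) %>%
    filter(.data$event_day >= .data$pd_start, .data$event_day < .data$pd_end) %>%
    count(.data$cohort, .data$site_group, name = "events")

  expand_grid(cohort = sort(unique(disc$cohort)), site_group = site_groups) %>%
    left_join(ev, by = c("cohort", "site_group")) %>%
    left_join(pt_sum, by = "cohort") %>%
    mutate(
      window = "post_disc",
      events = coalesce(.data$events, 0L),
      person_days = coalesce(.data$person_days, 0L),
      n_women = coalesce(.data$n_women, 0L),
      person_years = .data$person_days / DAYS_PER_YEAR,
      mode = if (nrow(women)) women$mode[1L] else NA_character_
    ) %>%
    select(all_of(names(empty)))
}

#' Recompute cells within strata of a covariate
#'
#' @param women assignment with `censor_day`.
#' @param events deduplicated events.
#' @param covariates covariate table from [extract_covariates()].
#' @param stratum_var name of the covariate column to stratify on.
#' @param windows window table.
#' @param site_groups groups to tabulate.
#' @return cell table with `stratum_var` and `stratum` columns; cell sums
#'   over strata equal the unstratified cells (additivity).
#' @export
stratified_cells <- function(women, events, covariates, stratum_var,
                             windows = window_specs(),
                             site_groups = SITE_GROUPS) {
  cov <- covariates %>% select("person_id", stratum = all_of(stratum_var))
  w <- women %>% inner_join(cov, by = "person_id")
  strata <- sort(unique(as.character(w$stratum)))
  bind_rows(lapply(strata, function(s) {
    accumulate_persontime(
      filter(w, as.character(.data$stratum) == s),
      events, windows, site_groups
    ) %>%
      mutate(stratum_var = stratum_var, stratum = s)
  }))
}

#' Post hoc cells for early oral-bisphosphonate discontinuers
#'
#' Women excluded from the main cohorts because their oral-bisphosphonate
#' episode lasted under 6 months — but otherwise eligible — are analysed
#' as-treated over the baseline window and the 3-6-month window
#' `[91, 183)`.
#'
#' @param episode_flags per-episode eligibility flags from
#'   [apply_eligibility()].
#' @param events deduplicated events.
#' @param persons person table.
#' @param specs drug specification table.
#' @param drug the cohort drug of interest (default "oral_bp").
#' @return cell table over windows baseline and `m3_6` (empty when there
#'   are no early discontinuers).
#' @export
posthoc_early_discontinuers <- function(episode_flags, events, persons, specs,
                                        drug = "oral_bp") {
  keep <- episode_flags %>%
    filter(
      .data$drug_name == drug,
      .data$treated_lt_6m,
      !.data$male, !.data$age_lt_55, !.data$lookback_lt_3y,
      !.data$followup_lt_2y, !.data$cancer_or_paget, !.data$multi_drug_index
    )
  if (nrow(keep) == 0L) {
    return(tibble(
      cohort = character(), site_group = character(), window = character(),
      events = integer(), person_days = integer(), n_women = integer(),
      person_years = double(), mode = character()
    ))
  }
  women <- keep %>%
    mutate(cohort = paste0(drug, "_early_disc")) %>%
    select(
      "person_id", "cohort", "drug_name", "index_day", "end_day",
      "disc_day", "end_reason", "duration_days", "age_at_index", "raw_cov_end"
    ) %>%
    mutate(censor_day = .data$end_day, mode = "as_treated")
  windows <- tribble(
    ~window,    ~start, ~end,
    "baseline", 0L,     91L,
    "m3_6",     91L,    183L
  )
  accumulate_persontime(women, events, windows)
}
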
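# Eligibility, flow counts and hierarchical cohort assignment.
#
# Calendar criteria are fixed in days: "at least 6 months of treatment"
# means >= 183 days, the look-back is 1095 days, the follow-up floor 730
# days and the cancer/Paget exclusion window 365 days before the index.
# The follow-up requirement is measured from index to end of data; dying
# within the two years does not disqualify a woman (deaths censor).

EXCLUSION_REASONS <- c(
  "male", "age_lt_55", "lookback_lt_3y", "followup_lt_2y",
  "treated_lt_6m", "cancer_or_paget", "multi_drug_index"
)

default_exclusion_codes <- function() c("C", "M88")

#' Apply eligibility criteria and produce flow-diagram counts
#'
#' Each candidate episode is checked against every criterion; a woman is
#' eligible when at least one of her episodes passes all of them. Reasons
#' are not mutually exclusive: an excluded woman is counted under every
#' reason that applies to any of her candidate episodes.
#'
#' @param persons person table.
#' @param episodes episodes (after [detect_switches()]).
#' @param stays long stay table (for the cancer/Paget's exclusion).
#' @param dispensings dispensing table (for the multi-drug-index
#'   exclusion).
#' @param specs drug specification table.
#' @param exclusion_codes diagnosis code prefixes triggering the
#'   cancer-or-Paget exclusion when found within 365 days before index.
#' @param min_treatment_days,lookback_days,followup_days day equivalents
#'   of the 6-month / 3-year / 2-year criteria.
#' @return list with `episode_flags` (per-episode criterion flags and
#'   `eligible`), `persons` (per-woman eligibility and reason set as a
#'   comma-separated string) and `flow` (counts: women with an index,
#'   per-reason exclusions, excluded, eligible, percentages w.r.t. the
#'   women with an index).
#' @export
apply_eligibility <- function(persons, episodes, stays, dispensings, specs,
                              exclusion_codes = default_exclusion_codes(),
                              min_treatment_days = DAYS_6M,
                              lookback_days = DAYS_3Y,
                              followup_days = DAYS_2Y) {
  ep <- episodes %>%
    left_join(
      persons %>% select("person_id", "sex", "birth_day", "data_start_day", "data_end_day"),
      by = "person_id"
    )

  # cancer/Paget within [index - 365, index)
  cancer_hit <- function(ep) {
    if (nrow(stays) == 0L) return(rep(FALSE, nrow(ep)))
    dx <- stays %>%
      filter(.data$code_type == "diagnosis") %>%
      mutate(is_excl = prefix_any(.data$code, exclusion_codes)) %>%
      filter(.data$is_excl) %>%
      select("person_id", "admission_day")
    hits <- ep %>%
      select("person_id", "drug_name", "index_day") %>%
      inner_join(dx, by = "person_id", relationship = "many-to-many") %>%
      filter(
        .data$admission_day >= .data$index_day - DAYS_1Y,
        .data$admission_day < .data$index_day
      ) %>%
      distinct(.data$person_id, .data$drug_name)
    paste(ep$person_id, ep$drug_name) %in% paste(hits$person_id, hits$drug_name)
  }

  # >1 distinct study drug dispensed on the index date
  multi_hit <- function(ep) {
    d <- dispensings %>%
      inner_join(specs_code_table(specs), by = "drug_code") %>%
      select("person_id", "dispense_day", dispensed_drug = "drug_name")
    counts <- ep %>%
      select("person_id", "drug_name", "index_day") %>%
      inner_join(d, by = "person_id", relationship = "many-to-many") %>%
      filter(.data$dispense_day == .data$index_day) %>%
      group_by(.data$person_id, .data$drug_name) %>%
      summarise(n_drugs = n_distinct(.data$dispensed_drug), .groups = "drop")
    ep %>%
      left_join(counts, by = c("person_id", "drug_name")) %>%
      mutate(multi = !is.na(.data$n_drugs) & .data$n_drugs > 1L) %>%
      pull("multi")
  }

  flags <- ep %>%
    mutate(
      male = .data$sex != "F",
      age_at_index = (.data$index_day - .data$birth_day) / DAYS_PER_YEAR,
      age_lt_55 = .data$age_at_index < 55,
      lookback_lt_3y = .data$index_day - .data$data_start_day < lookback_days,
      followup_lt_2y = .data$data_end_day - .data$index_day < followup_days,
      treated_lt_6m = .data$duration_days < min_treatment_days,
      cancer_or_paget = cancer_hit(ep),
      multi_drug_index = multi_hit(ep)
    ) %>%
    mutate(eligible = !(
      .data$male | .data$age_lt_55 | .data$lookback_lt_3y |
        .data$followup_lt_2y | .data$treated_lt_6m |
        .data$cancer_or_paget | .data$multi_drug_index
    ))

  person_res <- flags %>%
    group_by(.data$person_id) %>%
    summarise(
      eligible = any(.data$eligible),
      across(all_of(EXCLUSION_REASONS), any),
      .groups = "drop"
    )
  reason_mat <- as.matrix(person_res[EXCLUSION_REASONS])
  person_res$exclusion_reasons <- ifelse(
    person_res$eligible, "",
    apply(reason_mat, 1L, function(r) paste(EXCLUSION_REASONS[r], collapse = ","))
  )

  n_total <- nrow(person_res)
  excluded <- filter(person_res, !.data$eligible)
  reason_counts <- vapply(
    EXCLUSION_REASONS,
    function(r) sum(excluded[[r]]),
    integer(1)
  )
  flow <- bind_rows(
    tibble(step = "women_with_index", n = n_total),
    tibble(step = paste0("excluded_", EXCLUSION_REASONS), n = as.integer(reason_counts)),
    tibble(step = "excluded_total", n = nrow(excluded)),
    tibble(step = "eligible", n = n_total - nrow(excluded))
  ) %>%
    mutate(pct = if (n_total > 0) round(100 * .data$n / n_total, 1) else NA_real_)

  list(
    episode_flags = flags,
    persons = person_res %>% select("person_id", "eligible", "exclusion_reasons"),
    flow = flow
  )
}

prefix_any <- function(codes, prefixes) {
  hit <- rep(FALSE, length(codes))
  for (p in prefixes) hit <- hit | startsWith(codes, p)
  hit
}

#' Assign each eligible woman to exactly one cohort (hierarchical rule)
#'
#' Among a woman's eligible episodes, the episode of the drug with the
#' smallest hierarchy rank — i.e. the most recently marketed study
#' medication she initiated inside the inclusion window — defines her
#' cohort, and its index date becomes her index date.
#'
#' @param episode_flags per-episode eligibility table from
#'   [apply_eligibility()].
#' @param specs drug specification table (supplies `hierarchy_rank`).
#' @return one-row-per-woman assignment carrying the chosen episode's
#'   columns plus `cohort`.
#' @export
assign_cohorts <- function(episode_flags, specs) {
  eligible <- episode_flags %>% filter(.data$eligible)
  if (nrow(eligible) == 0L) {
    stop("no eligible episodes: cannot assign cohorts")
  }
  eligible %>%
    inner_join(specs %>% select("drug_name", "hierarchy_rank"), by = "drug_name") %>%
    group_by(.data$person_id) %>%
    slice_min(.data$hierarchy_rank, n = 1, with_ties = FALSE) %>%
    ungroup() %>%
    mutate(cohort = .data$drug_name) %>%
    select(
      "person_id", "cohort", "drug_name", "index_day", "end_day", "disc_day",
      "end_reason", "duration_days", "age_at_index", "raw_cov_end"
    ) %>%
    arrange(.data$person_id)
}

#' Default covariate code configuration (synthetic stand-in lists)
#'
#' Editable configuration for covariate extraction: ATC prefixes for
#' corticosteroids, vitamin D/calcium and the study drugs; ICD-10-style
#' prefixes for dementia and nervous-system disorders; a placeholder
#' densitometry procedure code; and the weight table of the simplified
#' comorbidity score (a configurable weighted-flag score, not a validated
#' Charlson implementation).
#'
#' @return named list of code vectors plus `comorbidity_weights` tibble.
#' @export
default_covariate_codes <- function() {
  list(
    corticosteroid = "H02",
    vitd_calcium = c("A11CC", "A12A"),
    dementia = c("F00", "F01", "F02", "F03", "G30"),
    nervous = "G",
    densitometry = "PAQK",
    comorbidity_weights = tribble(
      ~condition,        ~prefixes,              ~weight,
      "diabetes",        list("E10", "E11", "E12", "E13", "E14"), 1,
      "cardiovascular",  list("I"),              1,
      "rheumatoid",      list("M05", "M06"),     1,
      "ibd",             list("K50", "K51"),     1,
      "lupus",           list("M32"),            1,
      "nervous",         list("G"),              1
    )
  )
}

#' Extract per-woman covariate flags used by the stratified analyses
#'
#' Comorbidity and fracture-history flags come from the 3-year pre-index
#' look-back; prior osteoporosis medication, corticosteroid use and
#' vitamin D/calcium delivery from the 1-year look-back. Fracture history
#' applies the same event identification and 90-day independence rule as
#' the outcome module to the look-back window.
#'
#' @param stays,dispensings claims tables.
#' @param assignment cohort assignment from [assign_cohorts()].
#' @param specs drug specification table.
#' @param code_config see [default_covariate_codes()].
#' @param code_map fracture code map for history, see
#'   [default_fracture_codes()].
#' @return one row per assigned woman with age class, fracture-history
#'   flags and counts, prior-treatment flag, corticosteroid stratum,
#'   dementia / nervous-system flags, vitamin D or calcium flag,
#'   densitometry flag, and the simplified comorbidity score.
#' @export
extract_covariates <- function(stays, dispensings, assignment, specs,
                               code_config = default_covariate_codes(),
                               code_map = default_fracture_codes()) {
  base <- assignment %>% select("person_id", "cohort", "index_day", "age_at_index")

  lb3_stays <- stays %>%
    inner_join(base %>% select("person_id", "index_day"), by = "person_id") %>%
    filter(
      .data$admission_day >= .data$index_day - DAYS_3Y,
      .data$admission_day < .data$index_day
    )
  lb1_disp <- dispensings %>%
    inner_join(base %>% select("person_id", "index_day"), by = "person_id") %>%
    filter(
      .data$dispense_day >= .data$index_day - DAYS_1Y,
      .data$dispense_day < .data$index_day
    )

  # fracture history: independent events in the 3-year look-back
  hist_events <- identify_raw_events(lb3_stays, code_map) %>%
    deduplicate_events() %>%
    filter(.data$independent) %>%
    assign_site_groups()
  hist_flags <- hist_events %>%
    distinct(.data$person_id, .data$site_group) %>%
    mutate(flag = TRUE) %>%
    pivot_wider(
      names_from = "site_group", values_from = "flag",
      names_prefix = "hist_", values_fill = FALSE
    )
  hist_counts <- hist_events %>%
    distinct(.data$person_id, .data$stay_id, .data$event_day, .data$site) %>%
    count(.data$person_id, name = "n_prior_fractures")

  dx_flag <- function(prefixes, name) {
    hit <- lb3_stays %>%
      filter(.data$code_type == "diagnosis", prefix_any(.data$code, prefixes)) %>%
      distinct(.data$person_id) %>%
      mutate("{name}" := TRUE)
    hit
  }

  cortico <- lb1_disp %>%
    filter(prefix_any(.data$drug_code, code_config$corticosteroid)) %>%
    count(.data$person_id, name = "n_cortico")
  vitd <- lb1_disp %>%
    filter(prefix_any(.data$drug_code, code_config$vitd_calcium)) %>%
    distinct(.data$person_id) %>%
    mutate(vitd_calcium = TRUE)
  prior_ot <- lb1_disp %>%
    filter(.data$drug_code %in% unlist(specs$drug_codes)) %>%
    distinct(.data$person_id) %>%
    mutate(prior_ot = TRUE)
  densito <- lb3_stays %>%
    filter(.data$code_type == "procedure", prefix_any(.data$code, code_config$densitometry)) %>%
    distinct(.data$person_id) %>%
    mutate(densitometry = TRUE)

  w <- code_config$comorbidity_weights
  score <- bind_rows(lapply(seq_len(nrow(w)), function(i) {
    lb3_stays %>%
      filter(
        .data$code_type == "diagnosis",
        prefix_any(.data$code, unlist(w$prefixes[[i]]))
      ) %>%
      distinct(.data$person_id) %>%
      mutate(weight = w$weight[i])
  })) %>%
    group_by(.data$person_id) %>%
    summarise(comorbidity_score = sum(.data$weight), .groups = "drop")

  out <- base %>%
    mutate(age_class = cut(.data$age_at_index,
      breaks = c(-Inf, 65, 75, 80, Inf),
      labels = c("55-64", "65-74", "75-79", "80+"), right = FALSE
    )) %>%
    left_join(hist_flags, by = "person_id") %>%
    left_join(hist_counts, by = "person_id") %>%
    left_join(dx_flag(code_config$dementia, "dementia"), by = "person_id") %>%
    left_join(dx_flag(code_config$nervous, "nervous_disorder"), by = "person_id") %>%
    left_join(cortico, by = "person_id") %>%
    left_join(vitd, by = "person_id") %>%
    left_join(prior_ot, by = "person_id") %>%
    left_join(densito, by = "person_id") %>%
    left_join(score, by = "person_id")

  for (col in c("hist_hip", "hist_vertebral", "hist_wrist_forearm", "hist_nonhip_nonvertebral")) {
    if (!col %in% names(out)) out[[col]] <- FALSE
  }
  out %>%
    mutate(
      across(
        c(
          "hist_hip", "hist_vertebral", "hist_wrist_forearm",
          "hist_nonhip_nonvertebral", "dementia", "nervous_disorder",
          "vitd_calcium", "prior_ot", "densitometry"
        ),
        ~ !is.na(.x) & .x
      ),
      n_prior_fractures = coalesce(.data$n_prior_fractures, 0L),
      hist_any = .data$n_prior_fractures > 0L,
      fracture_history_class = cut(.data$n_prior_fractures,
        breaks = c(-Inf, 0, 1, Inf), labels = c("0", "1", "2+")
      ),
      n_cortico = coalesce(.data$n_cortico, 0L),
      cortico_class = ifelse(.data$n_cortico > 3L, ">3", "<=3"),
      comorbidity_score = coalesce(.data$comorbidity_score, 0)
    )
}
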
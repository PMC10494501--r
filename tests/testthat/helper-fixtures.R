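# Small in-code fixtures used across the unit tests.

d <- function(x) as_day(x)

mk_persons <- function(ids, birth = "1950-06-15",
                       data_start = "2010-01-01", data_end = "2018-12-31",
                       death = NA, sex = "F") {
  n <- length(ids)
  tibble::tibble(
    person_id = ids,
    sex = rep_len(sex, n),
    birth_day = rep_len(d(birth), n),
    death_day = rep_len(if (all(is.na(death))) NA_integer_ else d(death), n),
    data_start_day = rep_len(d(data_start), n),
    data_end_day = rep_len(d(data_end), n)
  )
}

mk_disp <- function(person_id, dates, drug_code, units = 1L) {
  n <- length(dates)
  tibble::tibble(
    person_id = rep_len(person_id, n),
    dispense_day = d(dates),
    drug_code = rep_len(drug_code, n),
    units = rep_len(as.integer(units), n)
  )
}

mk_stays <- function(person_id, days, code, position = "principal",
                     type = "diagnosis", id_start = 1L) {
  n <- length(days)
  tibble::tibble(
    stay_id = seq.int(id_start, length.out = n),
    person_id = rep_len(person_id, n),
    admission_day = d(days),
    discharge_day = d(days) + 3L,
    code = rep_len(code, n),
    code_type = rep_len(type, n),
    code_position = rep_len(position, n)
  )
}

empty_stays <- function() mk_stays(character(0), integer(0), character(0))

# one-cohort generator settings used by several simulation-based tests
lean_config <- function(n, seed, vertebral_hazard = 35,
                        on_irr = 1, post_irr = 1, ...) {
  hz <- default_baseline_hazards()
  hz["vertebral"] <- vertebral_hazard
  mult <- function(v) {
    m <- setNames(rep(1, length(hz)), names(hz))
    m["vertebral"] <- v
    m
  }
  sim_config(
    n_women_per_drug = c(denosumab = n),
    baseline_hazards = hz,
    on_treatment_irr = mult(on_irr),
    post_disc_irr = mult(post_irr),
    seed = seed,
    ...
  )
}

# run the core analysis (single mode) on a simulated dataset
run_core <- function(ds, mode = "as_treated", specs = default_drug_specs(),
                     with_post_disc = FALSE) {
  idx <- find_index_dates(ds$dispensings, specs, "2014-01-01", "2016-12-31")
  eps <- detect_switches(build_episodes(ds$dispensings, idx, specs, ds$persons), idx)
  el <- apply_eligibility(ds$persons, eps, ds$stays, ds$dispensings, specs)
  asg <- assign_cohorts(el$episode_flags, specs)
  ev <- deduplicate_events(identify_raw_events(ds$stays))
  w <- censor_days(asg, ds$persons, specs, mode, study_end = "2018-12-31")
  cells <- accumulate_persontime(w, ev)
  if (with_post_disc && mode == "as_treated") {
    cells <- dplyr::bind_rows(
      cells, post_disc_cells(w, ev, ds$dispensings, specs, ds$persons)
    )
  }
  list(
    index = idx, episodes = eps, eligibility = el, assignment = asg,
    events = ev, women = w, cells = cells
  )
}
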
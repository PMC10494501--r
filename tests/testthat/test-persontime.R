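specs <- default_drug_specs()

mk_women <- function(index, end_day, end_reason = "discontinuation",
                     censor = end_day, id = "a", cohort = "denosumab") {
  tibble::tibble(
    person_id = id, cohort = cohort, drug_name = cohort,
    index_day = index, end_day = end_day,
    disc_day = ifelse(end_reason == "discontinuation", end_day - 1L, NA_integer_),
    end_reason = end_reason, duration_days = end_day - index,
    age_at_index = 70, raw_cov_end = end_day,
    censor_day = censor, mode = "as_treated"
  )
}

no_events <- function() {
  tibble::tibble(
    person_id = character(), stay_id = integer(),
    event_day = integer(), site = character(), independent = logical()
  )
}

test_that("censoring dates follow the three analysis modes", {
  i0 <- d("2014-06-01")
  asg <- mk_women(i0, i0 + 300L)[, 1:10] # without censor/mode
  persons <- mk_persons("a", death = NA)

  # as-treated: episode end
  expect_equal(
    censor_days(asg, persons, specs, "as_treated")$censor_day, i0 + 300L
  )
  # virtual exposure for a bisphosphonate adds 365 days
  asg_bp <- dplyr::mutate(asg, drug_name = "oral_bp")
  expect_equal(
    censor_days(asg_bp, persons, specs, "virtual_exposure")$censor_day,
    i0 + 300L + 365L
  )
  # ... and 30 days for denosumab
  expect_equal(
    censor_days(asg, persons, specs, "virtual_exposure")$censor_day,
    i0 + 300L + 30L
  )
  # intent-to-treat runs to the study end (or death)
  expect_equal(
    censor_days(asg, persons, specs, "itt", study_end = "2018-12-31")$censor_day,
    d("2018-12-31") + 1L
  )
  p_death <- mk_persons("a", death = i0 + 500L)
  expect_equal(
    censor_days(asg, p_death, specs, "itt", study_end = "2018-12-31")$censor_day,
    i0 + 501L
  )
})

test_that("window person-time is the intersection with the at-risk interval", {
  i0 <- d("2014-06-01")
  # on treatment beyond 730 days: full windows
  w <- mk_women(i0, i0 + 800L)
  cells <- accumulate_persontime(w, no_events())
  get <- function(win) cells$person_days[cells$window == win & cells$site_group == "hip"]
  expect_equal(get("baseline"), 91L)
  expect_equal(get("m3_12"), 274L)
  expect_equal(get("m3_18"), 457L)
  expect_equal(get("m3_24"), 639L)

  # discontinuation at day 200: the 3-12-month window holds 109 days
  w2 <- mk_women(i0, i0 + 200L)
  cells2 <- accumulate_persontime(w2, no_events())
  expect_equal(
    cells2$person_days[cells2$window == "m3_12" & cells2$site_group == "hip"],
    109L
  )
})

test_that("events are attributed to windows by date and censoring", {
  i0 <- d("2014-06-01")
  w <- mk_women(i0, i0 + 800L)
  ev <- tibble::tibble(
    person_id = "a", stay_id = 1L, event_day = i0 + 50L,
    site = "hip", independent = TRUE
  )
  cells <- accumulate_persontime(w, ev)
  hip <- cells[cells$site_group == "hip", ]
  expect_equal(hip$events[hip$window == "baseline"], 1L)
  expect_true(all(hip$events[hip$window != "baseline"] == 0L))

  # non-independent events are never counted
  ev2 <- dplyr::mutate(ev, independent = FALSE)
  cells2 <- accumulate_persontime(w, ev2)
  expect_true(all(cells2$events == 0L))

  # an event after the censor date is not counted
  ev3 <- dplyr::mutate(ev, event_day = i0 + 820L)
  expect_true(all(accumulate_persontime(w, ev3)$events == 0L))
})

test_that("window nesting gives monotone person-days and events", {
  ds <- simulate_claims(lean_config(200, seed = 8, on_irr = 0.7))
  res <- run_core(ds)
  wide_pd <- tidyr::pivot_wider(
    res$cells[res$cells$site_group == "vertebral", c("window", "person_days", "events")],
    names_from = "window", values_from = c("person_days", "events")
  )
  expect_lte(wide_pd$person_days_m3_12, wide_pd$person_days_m3_18)
  expect_lte(wide_pd$person_days_m3_18, wide_pd$person_days_m3_24)
  expect_lte(wide_pd$events_m3_12, wide_pd$events_m3_18)
  expect_lte(wide_pd$events_m3_18, wide_pd$events_m3_24)
  # person-time conservation per woman implies it in aggregate
  n_w <- nrow(res$assignment)
  expect_lte(
    wide_pd$person_days_baseline + wide_pd$person_days_m3_24,
    sum(res$women$censor_day - res$women$index_day)
  )
})

test_that("ITT person-time >= virtual-exposure >= as-treated in every cell", {
  ds <- simulate_claims(lean_config(150, seed = 12))
  pd_of <- function(mode) {
    run_core(ds, mode = mode)$cells$person_days
  }
  at <- pd_of("as_treated")
  ve <- pd_of("virtual_exposure")
  itt <- pd_of("itt")
  expect_true(all(ve >= at))
  expect_true(all(itt >= ve))
})

test_that("accumulation equals the day-by-day oracle on simulated women", {
  ds <- simulate_claims(lean_config(80, seed = 31, vertebral_hazard = 60))
  res <- run_core(ds)
  w <- res$women
  ev <- dplyr::filter(res$events, independent, site == "vertebral")
  wins <- window_specs()
  for (k in seq_len(nrow(wins))) {
    want_pd <- 0L
    want_ev <- 0L
    for (i in seq_len(nrow(w))) {
      e_days <- ev$event_day[ev$person_id == w$person_id[i]]
      o <- oracle_window(
        w$index_day[i], w$censor_day[i], wins$start[k], wins$end[k], e_days
      )
      want_pd <- want_pd + o$person_days
      want_ev <- want_ev + o$events
    }
    got <- res$cells[res$cells$window == wins$window[k] &
      res$cells$site_group == "vertebral", ]
    expect_equal(got$person_days, want_pd)
    expect_equal(got$events, want_ev)
  }
})

test_that("post-discontinuation window runs to reinitiation, death or data end", {
  i0 <- d("2014-06-01")
  w <- mk_women(i0, i0 + 200L)
  persons <- mk_persons("a", data_end = i0 + 1000L)
  # no reinitiation: to data end
  cells <- post_disc_cells(w, no_events(), mk_disp(character(0), integer(0), character(0)), specs, persons)
  expect_equal(unique(cells$person_days), 801L) # data_end day itself is observed
  # reinitiation at day 500 caps the window
  reinit <- mk_disp("a", i0 + 500L, "G03XC01")
  cells2 <- post_disc_cells(w, no_events(), reinit, specs, persons)
  expect_equal(unique(cells2$person_days), 300L)
  # a woman who never discontinues contributes no post-discontinuation rows
  w3 <- mk_women(i0, i0 + 200L, end_reason = "switch")
  expect_equal(nrow(post_disc_cells(w3, no_events(), reinit, specs, persons)), 0L)
})

test_that("stratified cells add up to the pooled cells", {
  ds <- simulate_claims(lean_config(150, seed = 44, vertebral_hazard = 50))
  res <- run_core(ds)
  cov <- extract_covariates(ds$stays, ds$dispensings, res$assignment, specs)
  sc <- stratified_cells(res$women, res$events, cov, "age_class")
  pooled <- res$cells
  summed <- sc %>%
    dplyr::group_by(cohort, site_group, window) %>%
    dplyr::summarise(
      events = sum(events), person_days = sum(person_days), .groups = "drop"
    )
  j <- dplyr::inner_join(
    pooled, summed,
    by = c("cohort", "site_group", "window"), suffix = c("", ".s")
  )
  expect_equal(j$events, j$events.s)
  expect_equal(j$person_days, j$person_days.s)

  # all women in one stratum: stratified equals pooled
  cov1 <- dplyr::mutate(cov, onestrat = "all")
  sc1 <- stratified_cells(res$women, res$events, cov1, "onestrat")
  expect_equal(sc1$events, pooled$events)
  expect_equal(sc1$person_days, pooled$person_days)
})

test_that("early oral-BP discontinuers are analysed over baseline and months 3-6", {
  # women with short oral-BP episodes, otherwise eligible
  profiles <- default_drug_profiles()
  profiles$duration_min_days[profiles$drug_name == "oral_bp"] <- 45
  profiles$duration_median_days[profiles$drug_name == "oral_bp"] <- 100
  ds <- simulate_claims(sim_config(
    n_women_per_drug = c(oral_bp = 250), drug_profiles = profiles, seed = 9,
    baseline_hazards = replace(default_baseline_hazards(), "vertebral", 60)
  ))
  idx <- find_index_dates(ds$dispensings, specs, "2014-01-01", "2016-12-31")
  eps <- detect_switches(build_episodes(ds$dispensings, idx, specs, ds$persons), idx)
  el <- apply_eligibility(ds$persons, eps, ds$stays, ds$dispensings, specs)
  ev <- deduplicate_events(identify_raw_events(ds$stays))
  ph <- posthoc_early_discontinuers(el$episode_flags, ev, ds$persons, specs)
  expect_setequal(unique(ph$window), c("baseline", "m3_6"))
  expect_true(all(ph$cohort == "oral_bp_early_disc"))
  # as-treated: no woman contributes more than 183 - 91 days to m3_6
  n_short <- sum(el$episode_flags$treated_lt_6m & el$episode_flags$drug_name == "oral_bp")
  expect_lte(
    max(ph$person_days[ph$window == "m3_6"]),
    n_short * 92L
  )
  # an empty population gives an empty table
  ph0 <- posthoc_early_discontinuers(
    el$episode_flags[0, ], ev, ds$persons, specs
  )
  expect_equal(nrow(ph0), 0L)
})
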
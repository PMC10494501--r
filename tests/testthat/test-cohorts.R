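specs <- default_drug_specs()

elig_of <- function(persons, disp, stays = empty_stays()) {
  idx <- find_index_dates(disp, specs, "2014-01-01", "2016-12-31")
  eps <- detect_switches(build_episodes(disp, idx, specs, persons), idx)
  apply_eligibility(persons, eps, stays, disp, specs)
}

test_that("each eligibility criterion excludes and is reported in the flow", {
  i0 <- d("2015-06-01")
  long_disp <- function(id, code = "M05BX04") mk_disp(id, c(i0, i0 + 182L), code)

  # aged 54 at index
  p <- mk_persons("a", birth = i0 - round(54 * 365.25))
  el <- elig_of(p, long_disp("a"))
  expect_false(el$persons$eligible)
  expect_match(el$persons$exclusion_reasons, "age_lt_55")

  # 120-day episode: treated under 6 months
  p2 <- mk_persons("b")
  d2 <- mk_disp("b", c(i0, i0 + 30L, i0 + 60L, i0 + 90L), "M05BA04") # covers 120 d
  el2 <- elig_of(p2, d2)
  expect_match(el2$persons$exclusion_reasons, "treated_lt_6m")

  # look-back under 3 years
  p3 <- mk_persons("c", data_start = i0 - 1000L)
  el3 <- elig_of(p3, long_disp("c"))
  expect_match(el3$persons$exclusion_reasons, "lookback_lt_3y")

  # follow-up under 2 years
  p4 <- mk_persons("e", data_end = i0 + 600L)
  el4 <- elig_of(p4, long_disp("e"))
  expect_match(el4$persons$exclusion_reasons, "followup_lt_2y")

  # death within 2 years does NOT disqualify (censoring handles it)
  p5 <- mk_persons("f", death = i0 + 400L)
  el5 <- elig_of(p5, long_disp("f"))
  expect_true(el5$persons$eligible)

  # cancer diagnosis within the prior year
  p6 <- mk_persons("g")
  el6 <- elig_of(p6, long_disp("g"), mk_stays("g", i0 - 100L, "C509"))
  expect_match(el6$persons$exclusion_reasons, "cancer_or_paget")
  # ... but not an older one
  el6b <- elig_of(p6, long_disp("g"), mk_stays("g", i0 - 400L, "C509"))
  expect_true(el6b$persons$eligible)

  # two study drugs dispensed on the index date
  p7 <- mk_persons("h")
  d7 <- dplyr::bind_rows(long_disp("h"), mk_disp("h", i0, "G03XC01"))
  el7 <- elig_of(p7, d7)
  expect_match(el7$persons$exclusion_reasons, "multi_drug_index")

  # men are excluded
  p8 <- mk_persons("i", sex = "M")
  el8 <- elig_of(p8, long_disp("i"))
  expect_match(el8$persons$exclusion_reasons, "male")

  # flow counts: per-reason rows plus totals
  expect_setequal(
    el$flow$step,
    c(
      "women_with_index", paste0("excluded_", c(
        "male", "age_lt_55", "lookback_lt_3y", "followup_lt_2y",
        "treated_lt_6m", "cancer_or_paget", "multi_drug_index"
      )),
      "excluded_total", "eligible"
    )
  )
})

test_that("with no planted exclusions every simulated woman is eligible", {
  ds <- simulate_claims(sim_config(n_women_per_drug = 60, seed = 3))
  res <- run_core(ds)
  flow <- res$eligibility$flow
  expect_equal(
    flow$n[flow$step == "eligible"],
    flow$n[flow$step == "women_with_index"]
  )
})

test_that("hierarchical assignment picks the highest-priority eligible drug", {
  i0 <- d("2014-03-01")
  i1 <- d("2016-02-01")
  persons <- mk_persons("a")
  # oral BP initiated 2014 (kept >6 months), denosumab initiated 2016:
  # denosumab cohort with the denosumab start as index date
  disp <- dplyr::bind_rows(
    mk_disp("a", i0 + seq(0L, 210L, by = 30L), "M05BA04"),
    mk_disp("a", c(i1, i1 + 182L), "M05BX04")
  )
  idx <- find_index_dates(disp, specs, "2014-01-01", "2016-12-31")
  eps <- detect_switches(build_episodes(disp, idx, specs, persons), idx)
  el <- apply_eligibility(persons, eps, empty_stays(), disp, specs)
  asg <- assign_cohorts(el$episode_flags, specs)
  expect_equal(asg$cohort, "denosumab")
  expect_equal(asg$index_day, i1)

  # raloxifene only
  disp2 <- mk_disp("b", d("2015-01-01") + seq(0L, 190L, by = 30L), "G03XC01")
  idx2 <- find_index_dates(disp2, specs, "2014-01-01", "2016-12-31")
  eps2 <- detect_switches(build_episodes(disp2, idx2, specs, mk_persons("b")), idx2)
  el2 <- apply_eligibility(mk_persons("b"), eps2, empty_stays(), disp2, specs)
  expect_equal(assign_cohorts(el2$episode_flags, specs)$cohort, "raloxifene")

  # zoledronic acid (rank 2) outranks teriparatide (rank 3)
  disp3 <- dplyr::bind_rows(
    mk_disp("c", d("2014-05-01"), "M05BA08"),
    mk_disp("c", d("2016-05-01") + seq(0L, 190L, by = 28L), "H05AA02")
  )
  idx3 <- find_index_dates(disp3, specs, "2014-01-01", "2016-12-31")
  eps3 <- detect_switches(build_episodes(disp3, idx3, specs, mk_persons("c")), idx3)
  el3 <- apply_eligibility(mk_persons("c"), eps3, empty_stays(), disp3, specs)
  expect_equal(assign_cohorts(el3$episode_flags, specs)$cohort, "zoledronic_acid")
})

test_that("cohort sizes partition the eligible women and survive row shuffling", {
  ds <- simulate_claims(sim_config(
    n_women_per_drug = 80, seed = 21,
    exclusion_fractions = list(cancer = 0.1, age_lt_55 = 0.05, multi_drug_index = 0.05)
  ))
  res <- run_core(ds)
  flow <- res$eligibility$flow
  expect_equal(nrow(res$assignment), flow$n[flow$step == "eligible"])
  expect_equal(anyDuplicated(res$assignment$person_id), 0L)

  # shuffle input rows: assignment unchanged
  ds2 <- ds
  set.seed(1)
  ds2$dispensings <- ds2$dispensings[sample(nrow(ds2$dispensings)), ]
  ds2$persons <- ds2$persons[sample(nrow(ds2$persons)), ]
  res2 <- run_core(ds2)
  expect_equal(
    dplyr::arrange(res$assignment, person_id),
    dplyr::arrange(res2$assignment, person_id)
  )
})

test_that("planted exclusion fractions are recovered within binomial bounds", {
  fr <- list(cancer = 0.15, age_lt_55 = 0.08, multi_drug_index = 0.05)
  n <- 5 * 400
  ds <- simulate_claims(sim_config(n_women_per_drug = 400, seed = 17, exclusion_fractions = fr))
  res <- run_core(ds)
  flow <- res$eligibility$flow
  for (nm in c("cancer_or_paget", "age_lt_55", "multi_drug_index")) {
    got <- flow$n[flow$step == paste0("excluded_", nm)]
    p <- switch(nm,
      cancer_or_paget = fr$cancer, age_lt_55 = fr$age_lt_55,
      multi_drug_index = fr$multi_drug_index
    )
    bounds <- qbinom(c(0.005, 0.995), n, p)
    expect_gte(got, bounds[1])
    expect_lte(got, bounds[2])
  }
})

test_that("covariate extraction reproduces planted history", {
  i0 <- d("2015-06-01")
  persons <- mk_persons("a")
  disp <- dplyr::bind_rows(
    mk_disp("a", c(i0, i0 + 182L), "M05BX04"),
    mk_disp("a", i0 - c(30L, 60L, 90L, 120L), "H02AB06"), # 4 corticosteroid deliveries
    mk_disp("a", i0 - 200L, "A11CC05"),                   # vitamin D
    mk_disp("a", i0 - 100L, "M05BA04")                    # prior oral BP
  )
  stays <- dplyr::bind_rows(
    mk_stays("a", c(i0 - 900L, i0 - 700L), "S7200"),      # two prior hip fractures, 200 d apart
    mk_stays("a", i0 - 300L, "G301", id_start = 10L),     # dementia
    mk_stays("a", i0 - 250L, "E119", id_start = 20L)      # diabetes
  )
  idx <- find_index_dates(disp, specs, "2014-01-01", "2016-12-31")
  eps <- detect_switches(build_episodes(disp, idx, specs, persons), idx)
  el <- apply_eligibility(persons, eps, stays, disp, specs)
  # prior oral BP dispensing within the washout year does not block a
  # denosumab index; assignment is to denosumab
  asg <- assign_cohorts(el$episode_flags, specs)
  cov <- extract_covariates(stays, disp, asg, specs)
  expect_equal(cov$cortico_class, ">3")
  expect_true(cov$vitd_calcium)
  expect_true(cov$prior_ot)
  expect_true(cov$dementia)
  expect_true(cov$nervous_disorder) # G30 is within the nervous chapter
  expect_true(cov$hist_hip)
  expect_equal(cov$n_prior_fractures, 2L)
  expect_equal(as.character(cov$fracture_history_class), "2+")
  expect_equal(cov$comorbidity_score, 2) # diabetes + nervous
  expect_equal(as.character(cov$age_class), "55-64")
})

test_that("women with no look-back claims have empty covariates and score zero", {
  ds <- simulate_claims(sim_config(n_women_per_drug = 30, seed = 2))
  res <- run_core(ds)
  cov <- extract_covariates(empty_stays(), ds$dispensings, res$assignment, specs)
  expect_true(all(!cov$dementia))
  expect_true(all(cov$comorbidity_score == 0))
  expect_true(all(cov$n_prior_fractures == 0L))
})
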
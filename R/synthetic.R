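# Synthetic claims generator with known ground truth.
#
# Each simulated woman initiates exactly one study medication inside the
# inclusion window and experiences fracture events from a
# piecewise-constant Poisson process on three timeline segments:
# [index, index + 91) at the configured baseline hazard, [index + 91,
# end of exposure) at baseline x on-treatment multiplier, and
# [end of exposure, end of observation) at baseline x
# post-discontinuation multiplier. True index, discontinuation and event
# dates are returned alongside the claims, so downstream estimates can be
# compared with the planted truth.
#
# Hazards are keyed by anatomical site (not by the overlapping analysis
# groups, which would make the planted group-level IRRs ill-defined);
# group rates follow from the site-to-group memberships.

canonical_site_codes <- c(
  hip = "S7200", vertebral = "S2200", wrist_forearm = "S5250",
  humerus = "S4220", clavicle = "S4200", ribs = "S2220",
  pelvis = "S3210", leg = "S8210"
)

#' Default per-drug simulation profiles
#'
#' Age distributions and exposure-duration distributions per cohort drug,
#' on the scale reported for real initiators of these medications: the
#' raloxifene population is the youngest (mean 64 y) and the teriparatide
#' population the oldest (mean 76 y); median exposure runs from about 12
#' months (denosumab, zoledronic acid) to about 17 months (teriparatide).
#' Durations are log-normal, truncated at 183 days so that the generated
#' population is the included (>= 6 months treated) one; lower the
#' truncation to generate early discontinuers.
#'
#' @return tibble, one row per drug.
#' @export
default_drug_profiles <- function() {
  tribble(
    ~drug_name,        ~age_mean, ~age_sd, ~duration_median_days, ~duration_sdlog, ~duration_min_days, ~refill_jitter_mean, ~refill_jitter_sd, ~refill_jitter_max,
    "denosumab",       74.3,      9.2,     360,                   0.6,             183,                3,                   6,                 20,
    "zoledronic_acid", 74.1,      9.8,     365,                   0.6,             183,                3,                   6,                 20,
    "teriparatide",    76.1,      9.2,     520,                   0.4,             183,                3,                   6,                 20,
    "oral_bp",         71.4,      9.4,     455,                   0.6,             183,                3,                   6,                 20,
    "raloxifene",      63.7,      6.7,     494,                   0.6,             183,                3,                   6,                 20
  )
}

#' Default baseline hazards per site (events per 1000 person-years)
#'
#' Scaled to the magnitudes seen in treated osteoporotic populations:
#' vertebral and hip near 9 per 1000 PY, wrist/forearm near 8, and the
#' remaining peripheral sites summing with wrist to roughly 22 for the
#' non-hip/nonvertebral group.
#'
#' @return named numeric vector over the eight sites.
#' @export
default_baseline_hazards <- function() {
  c(
    hip = 8.7, vertebral = 8.8, wrist_forearm = 8.2,
    humerus = 4, clavicle = 1, ribs = 3, pelvis = 4, leg = 2
  )
}

default_on_treatment_irr <- function() {
  c(
    hip = 0.8, vertebral = 0.6, wrist_forearm = 0.9,
    humerus = 0.9, clavicle = 0.9, ribs = 0.9, pelvis = 0.9, leg = 0.9
  )
}

default_post_disc_irr <- function() {
  c(
    hip = 1.5, vertebral = 1.5, wrist_forearm = 1.2,
    humerus = 1.2, clavicle = 1.2, ribs = 1.2, pelvis = 1.2, leg = 1.2
  )
}

# normalise multiplier input (named vector by site, or tibble with
# drug_name/site/irr) to a complete (drug, site) table
normalise_irr <- function(x, drugs, default = 1) {
  if (is.numeric(x) && !is.null(names(x))) {
    x <- expand_grid(drug_name = drugs, site = names(x)) %>%
      mutate(irr = unname(x[.data$site]))
  }
  stopifnot(is.data.frame(x), all(c("drug_name", "site", "irr") %in% names(x)))
  expand_grid(drug_name = drugs, site = FRACTURE_SITES) %>%
    left_join(as_tibble(x), by = c("drug_name", "site")) %>%
    mutate(irr = coalesce(.data$irr, default))
}

#' Build and validate a simulation configuration
#'
#' @param n_women_per_drug women per cohort drug (single number or vector
#'   named by drug).
#' @param drug_profiles per-drug age / duration / refill-jitter profiles,
#'   see [default_drug_profiles()].
#' @param inclusion_start,inclusion_end inclusion window (the study
#'   design's 2014-01-01 to 2016-12-31 by default).
#' @param study_end end of the study period (2018-12-31 by default); all
#'   women are observed to this date unless they die.
#' @param baseline_hazards named vector, events per 1000 PY per site
#'   during the 3-month baseline.
#' @param on_treatment_irr true hazard multiplier after month 3 while
#'   exposed; named vector by site, or tibble (drug_name, site, irr).
#' @param post_disc_irr true multiplier after the end of exposure.
#' @param death_rate_per_1000py death hazard.
#' @param death_start_day deaths are drawn from this day post-index
#'   onwards (183 by default, so the generated population reproduces an
#'   included population in which everyone completed 6 months of
#'   treatment alive).
#' @param assoc_dx_fraction fraction of fracture codes placed in
#'   associated (rather than principal) diagnosis position.
#' @param exclusion_fractions list with elements `cancer`, `age_lt_55`,
#'   `multi_drug_index`: fractions of women planted to fail eligibility.
#'   With all fractions zero every generated woman is eligible.
#' @param grace_days refill grace period assumed by the generator.
#' @param seed integer seed; identical configuration and seed give
#'   byte-identical output.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_women_per_drug = 500,
                       drug_profiles = default_drug_profiles(),
                       inclusion_start = "2014-01-01",
                       inclusion_end = "2016-12-31",
                       study_end = "2018-12-31",
                       baseline_hazards = default_baseline_hazards(),
                       on_treatment_irr = default_on_treatment_irr(),
                       post_disc_irr = default_post_disc_irr(),
                       death_rate_per_1000py = 10,
                       death_start_day = DAYS_6M,
                       assoc_dx_fraction = 0.1,
                       exclusion_fractions = list(cancer = 0, age_lt_55 = 0, multi_drug_index = 0),
                       grace_days = GRACE_DAYS,
                       seed = 1L) {
  cfg <- list(
    n_women_per_drug = n_women_per_drug,
    drug_profiles = drug_profiles,
    inclusion_start = as_day(inclusion_start),
    inclusion_end = as_day(inclusion_end),
    study_end = as_day(study_end),
    baseline_hazards = baseline_hazards,
    on_treatment_irr = on_treatment_irr,
    post_disc_irr = post_disc_irr,
    death_rate_per_1000py = death_rate_per_1000py,
    death_start_day = as.integer(death_start_day),
    assoc_dx_fraction = assoc_dx_fraction,
    exclusion_fractions = exclusion_fractions,
    grace_days = as.integer(grace_days),
    seed = as.integer(seed)
  )
  if (cfg$inclusion_start > cfg$inclusion_end) stop("empty inclusion window")
  if (any(cfg$baseline_hazards < 0)) stop("hazards must be >= 0")
  if (cfg$death_rate_per_1000py < 0) stop("death rate must be >= 0")
  miss <- setdiff(FRACTURE_SITES, names(cfg$baseline_hazards))
  if (length(miss)) stop("baseline_hazards missing site(s): ", paste(miss, collapse = ", "))
  fr <- unlist(cfg$exclusion_fractions)
  if (any(fr < 0 | fr > 1)) stop("exclusion fractions must lie in [0, 1]")
  structure(cfg, class = "sim_config")
}

per_day <- function(rate_per_1000py) rate_per_1000py / 1000 / DAYS_PER_YEAR

# truncated-normal sampler via inverse CDF (lower truncation only)
rtnorm_min <- function(n, mean, sd, lower) {
  u <- runif(n, pnorm(lower, mean, sd), 1)
  qnorm(u, mean, sd)
}

#' Generate a synthetic claims dataset with known ground truth
#'
#' @param config a [sim_config()].
#' @param specs drug specification table (codes, coverage per unit).
#' @return list: `persons`, `dispensings`, `stays` (the three claims
#'   tables), `ground_truth` (one row per woman: assigned drug, true
#'   index / discontinuation / death days, exclusion plantings),
#'   `true_events` (one row per planted fracture event with its timeline
#'   segment), and the `config`.
#' @export
simulate_claims <- function(config, specs = default_drug_specs()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_claims_impl(config, specs))
}

simulate_claims_impl <- function(config, specs) {
  profiles <- config$drug_profiles %>%
    inner_join(
      specs %>% select("drug_name", "drug_codes", "coverage_days_per_unit"),
      by = "drug_name"
    )
  drugs <- profiles$drug_name
  n_per <- config$n_women_per_drug
  if (length(n_per) == 1L && is.null(names(n_per))) {
    n_per <- setNames(rep(as.integer(n_per), length(drugs)), drugs)
  }
  on_irr <- normalise_irr(config$on_treatment_irr, drugs)
  post_irr <- normalise_irr(config$post_disc_irr, drugs)
  if (any(on_irr$irr <= 0) || any(post_irr$irr <= 0)) stop("multipliers must be > 0")

  all_codes_first <- vapply(specs$drug_codes, `[`, character(1), 1L)
  names(all_codes_first) <- specs$drug_name

  persons <- list(); dispensings <- list(); stays <- list()
  ground_truth <- list(); true_events <- list()

  for (d in drugs) {
    pr <- profiles[profiles$drug_name == d, ]
    n <- if (d %in% names(n_per)) as.integer(n_per[[d]]) else 0L
    if (is.na(n) || n <= 0L) next
    codes <- pr$drug_codes[[1L]]
    cov <- pr$coverage_days_per_unit

    id <- sprintf("%s_%06d", d, seq_len(n))
    age <- rtnorm_min(n, pr$age_mean, pr$age_sd, 55)
    excl_age <- runif(n) < config$exclusion_fractions$age_lt_55
    age[excl_age] <- runif(sum(excl_age), 50, 54.9)
    index <- config$inclusion_start +
      floor(runif(n) * (config$inclusion_end - config$inclusion_start + 1L))
    birth <- as.integer(index - round(age * DAYS_PER_YEAR))
    data_start <- as.integer(index - DAYS_3Y - floor(runif(n) * 366))
    data_end <- rep(config$study_end, n)

    dur <- pmax(
      pr$duration_min_days,
      round(rlnorm(n, log(pr$duration_median_days), pr$duration_sdlog))
    )
    death <- index + config$death_start_day +
      floor(rexp(n, per_day(config$death_rate_per_1000py)))
    death[death > data_end] <- NA_integer_
    obs_end_excl <- as.integer(ifelse(is.na(death), data_end + 1L, death + 1L))

    # dispensing schedule: refill k at index + k*coverage + jitter while
    # the planned (un-jittered) refill time is inside the planned duration
    n_refill <- pmax(1L, ceiling(dur / cov))
    row <- rep(seq_len(n), n_refill)
    k <- sequence(n_refill) - 1L
    jitter <- pmin(
      pr$refill_jitter_max,
      pmax(0, round(rnorm(length(k), pr$refill_jitter_mean, pr$refill_jitter_sd)))
    )
    jitter[k == 0L] <- 0
    ddate <- as.integer(index[row] + k * cov + jitter)
    keep <- ddate < obs_end_excl[row]
    row <- row[keep]; ddate <- ddate[keep]
    drug_code <- sample(codes, n, replace = TRUE)[row]

    # realised continuous coverage, chained with the same grace convention
    # the analysis assumes; the true end of exposure caps at observation
    cov_end_raw <- vapply(
      split(ddate, factor(row, levels = seq_len(n))),
      function(dd) {
        if (length(dd) == 0L) return(NA_integer_)
        as.integer(chain_coverage(dd, rep(1L, length(dd)), cov, config$grace_days)$cov_end)
      },
      integer(1)
    )
    exp_end_excl <- pmin(cov_end_raw, obs_end_excl, na.rm = FALSE)
    exp_end_excl[is.na(cov_end_raw)] <- NA_integer_

    # piecewise-constant event process per site
    t_base_end <- pmin(index + DAYS_3M, exp_end_excl)
    seg <- bind_rows(
      tibble(
        woman = seq_len(n), segment = "baseline",
        start = index, end = pmin(t_base_end, obs_end_excl), mult_kind = "base"
      ),
      tibble(
        woman = seq_len(n), segment = "on_treatment",
        start = pmin(index + DAYS_3M, exp_end_excl), end = exp_end_excl, mult_kind = "on"
      ),
      tibble(
        woman = seq_len(n), segment = "post_disc",
        start = exp_end_excl, end = obs_end_excl, mult_kind = "post"
      )
    ) %>%
      filter(!is.na(.data$start), !is.na(.data$end), .data$end > .data$start)

    site_mult <- tibble(site = FRACTURE_SITES) %>%
      mutate(
        base = unname(config$baseline_hazards[.data$site]),
        on = .data$base * on_irr$irr[match(paste(d, .data$site), paste(on_irr$drug_name, on_irr$site))],
        post = .data$base * post_irr$irr[match(paste(d, .data$site), paste(post_irr$drug_name, post_irr$site))]
      ) %>%
      pivot_longer(c("base", "on", "post"), names_to = "mult_kind", values_to = "rate")

    segsite <- seg %>%
      cross_join(tibble(site = FRACTURE_SITES)) %>%
      inner_join(site_mult, by = c("site", "mult_kind")) %>%
      mutate(
        len = .data$end - .data$start,
        n_events = rpois(n(), per_day(.data$rate) * .data$len)
      ) %>%
      filter(.data$n_events > 0L)

    ev <- if (nrow(segsite)) {
      idx <- rep(seq_len(nrow(segsite)), segsite$n_events)
      segsite[idx, ] %>%
        mutate(event_day = as.integer(.data$start + floor(runif(n()) * .data$len))) %>%
        transmute(
          person_id = id[.data$woman], site = .data$site,
          event_day = .data$event_day, segment = .data$segment
        ) %>%
        arrange(.data$person_id, .data$event_day, .data$site)
    } else {
      tibble(
        person_id = character(), site = character(),
        event_day = integer(), segment = character()
      )
    }

    st <- ev %>% transmute(
      person_id = .data$person_id,
      admission_day = .data$event_day,
      discharge_day = .data$event_day + 3L,
      code = unname(canonical_site_codes[.data$site]),
      code_type = "diagnosis",
      code_position = ifelse(runif(nrow(ev)) < config$assoc_dx_fraction,
        "associated", "principal"
      )
    )

    # planted eligibility failures
    excl_cancer <- runif(n) < config$exclusion_fractions$cancer
    if (any(excl_cancer)) {
      st <- bind_rows(st, tibble(
        person_id = id[excl_cancer],
        admission_day = as.integer(index[excl_cancer] - (30L + floor(runif(sum(excl_cancer)) * 270))),
        discharge_day = NA_integer_, code = "C509",
        code_type = "diagnosis", code_position = "principal"
      ) %>% mutate(discharge_day = .data$admission_day + 5L))
    }
    excl_multi <- runif(n) < config$exclusion_fractions$multi_drug_index
    extra_disp <- if (any(excl_multi)) {
      other <- setdiff(drugs, d)[1L]
      tibble(
        person_id = id[excl_multi],
        dispense_day = index[excl_multi],
        drug_code = unname(all_codes_first[other]),
        units = 1L
      )
    } else {
      NULL
    }

    persons[[d]] <- tibble(
      person_id = id, sex = "F", birth_day = birth, death_day = death,
      data_start_day = data_start, data_end_day = data_end
    )
    dispensings[[d]] <- bind_rows(
      tibble(person_id = id[row], dispense_day = ddate, drug_code = drug_code, units = 1L),
      extra_disp
    )
    stays[[d]] <- st
    ground_truth[[d]] <- tibble(
      person_id = id, drug_name = d,
      index_day = index,
      exposure_end_day = exp_end_excl,
      disc_day = as.integer(ifelse(
        !is.na(cov_end_raw) & cov_end_raw < obs_end_excl,
        cov_end_raw - 1L, NA_integer_
      )),
      death_day = death,
      planned_duration_days = dur,
      excl_cancer = excl_cancer, excl_age_lt_55 = excl_age,
      excl_multi_drug = excl_multi
    )
    true_events[[d]] <- ev
  }

  stays_all <- bind_rows(stays)
  if (nrow(stays_all)) {
    stays_all <- stays_all %>%
      arrange(.data$person_id, .data$admission_day, .data$code) %>%
      mutate(stay_id = seq_len(n()), .before = 1L)
  } else {
    stays_all <- tibble(
      stay_id = integer(), person_id = character(),
      admission_day = integer(), discharge_day = integer(),
      code = character(), code_type = character(), code_position = character()
    )
  }

  list(
    persons = bind_rows(persons),
    dispensings = bind_rows(dispensings) %>%
      arrange(.data$person_id, .data$dispense_day, .data$drug_code),
    stays = stays_all,
    ground_truth = bind_rows(ground_truth),
    true_events = bind_rows(true_events),
    config = config
  )
}

#' Write / read a simulation configuration as JSON or YAML
#'
#' The on-disk document mirrors the [sim_config()] fields, with ISO-8601
#' dates and the drug profiles as a record list. The format is chosen by
#' file extension (`.json`, or `.yaml`/`.yml` which requires the yaml
#' package).
#'
#' @param config a `sim_config`.
#' @param path file path ending in .json, .yaml or .yml.
#' @return `write_sim_config()` returns `path` invisibly;
#'   `read_sim_config()` returns a validated `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  doc <- list(
    n_women_per_drug = config$n_women_per_drug,
    drug_profiles = config$drug_profiles,
    inclusion_start = format(day_to_date(config$inclusion_start)),
    inclusion_end = format(day_to_date(config$inclusion_end)),
    study_end = format(day_to_date(config$study_end)),
    baseline_hazards = as.list(config$baseline_hazards),
    on_treatment_irr = normalise_irr(config$on_treatment_irr, default_drug_specs()$drug_name),
    post_disc_irr = normalise_irr(config$post_disc_irr, default_drug_specs()$drug_name),
    death_rate_per_1000py = config$death_rate_per_1000py,
    death_start_day = config$death_start_day,
    assoc_dx_fraction = config$assoc_dx_fraction,
    exclusion_fractions = config$exclusion_fractions,
    grace_days = config$grace_days,
    seed = config$seed
  )
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) stop("the yaml package is required for YAML output")
    doc$drug_profiles <- as.data.frame(doc$drug_profiles)
    doc$on_treatment_irr <- as.data.frame(doc$on_treatment_irr)
    doc$post_disc_irr <- as.data.frame(doc$post_disc_irr)
    yaml::write_yaml(doc, path)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) stop("the yaml package is required for YAML input")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  as_named <- function(x) if (is.list(x)) unlist(x) else x
  nw <- as_named(doc$n_women_per_drug)
  sim_config(
    n_women_per_drug = nw,
    drug_profiles = as_tibble(as.data.frame(doc$drug_profiles)),
    inclusion_start = doc$inclusion_start,
    inclusion_end = doc$inclusion_end,
    study_end = doc$study_end,
    baseline_hazards = as_named(doc$baseline_hazards),
    on_treatment_irr = as_tibble(as.data.frame(doc$on_treatment_irr)),
    post_disc_irr = as_tibble(as.data.frame(doc$post_disc_irr)),
    death_rate_per_1000py = doc$death_rate_per_1000py,
    death_start_day = doc$death_start_day,
    assoc_dx_fraction = doc$assoc_dx_fraction,
    exclusion_fractions = doc$exclusion_fractions,
    grace_days = doc$grace_days,
    seed = doc$seed
  )
}
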
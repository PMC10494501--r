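# Treatment-episode construction from dispensing claims.
#
# Conventions: all intervals are half-open [start, end) in integer days.
# An episode's exposure interval is [index_day, end_day); the "last day
# covered by the last delivery" — the reported discontinuation date — is
# end_day - 1.

#' Find new-user index dates per (person, drug)
#'
#' The candidate index for a drug is the earliest dispensing inside the
#' inclusion window with no dispensing of the same drug — same *class* for
#' oral bisphosphonates, since the three molecules share a class — in the
#' preceding 365 days. A delivery whose washout is violated does not
#' index; a later delivery may, once it re-satisfies the 12-month washout.
#'
#' @param dispensings dispensing table with `person_id`, `dispense_day`,
#'   `drug_code`.
#' @param specs drug specification table, see [default_drug_specs()].
#' @param inclusion_start,inclusion_end inclusion window (days or dates),
#'   both inclusive.
#' @param washout_days washout lookback (default 365).
#' @return tibble `person_id`, `drug_name`, `index_day`.
#' @export
find_index_dates <- function(dispensings, specs,
                             inclusion_start, inclusion_end,
                             washout_days = DAYS_1Y) {
  inclusion_start <- as_day(inclusion_start)
  inclusion_end <- as_day(inclusion_end)
  stopifnot(inclusion_start <= inclusion_end)

  disp <- dispensings %>%
    inner_join(specs_code_table(specs), by = "drug_code") %>%
    select("person_id", "dispense_day", "drug_name")

  if (nrow(disp) == 0L) {
    return(tibble(person_id = character(), drug_name = character(), index_day = integer()))
  }

  first_new_user <- function(days) {
    days <- sort(unique(days))
    in_win <- days[days >= inclusion_start & days <= inclusion_end]
    for (d in in_win) {
      if (!any(days >= d - washout_days & days < d)) return(d)
    }
    NA_integer_
  }

  disp %>%
    group_by(.data$person_id, .data$drug_name) %>%
    summarise(index_day = first_new_user(.data$dispense_day), .groups = "drop") %>%
    filter(!is.na(.data$index_day)) %>%
    arrange(.data$person_id, .data$drug_name)
}

# Chain deliveries into continuous coverage. dates/units sorted by date,
# first row is the index delivery. Coverage of a delivery starts at
# max(delivery date, previous coverage end) — stockpiled supply carries
# forward — and the chain continues while the next delivery falls no more
# than grace_days after the current coverage end.
chain_coverage <- function(dates, units, coverage_days, grace_days) {
  cov_end <- dates[1L] + units[1L] * coverage_days
  n <- 1L
  nd <- length(dates)
  while (n < nd) {
    i <- n + 1L
    if (dates[i] > cov_end + grace_days) break
    start <- max(dates[i], cov_end)
    cov_end <- start + units[i] * coverage_days
    n <- i
  }
  list(cov_end = cov_end, n_dispensings = n)
}

#' Build treatment episodes from index dates
#'
#' Starting at each (person, drug) index delivery, deliveries are chained
#' into a continuous-coverage episode with a refill grace period: the
#' episode persists while the next delivery occurs within `grace_days`
#' after the end of current coverage. The untruncated end of coverage is
#' then censored by death and by the end of the person's data, yielding
#' the end reason (switch annotation is a separate pass,
#' [detect_switches()]).
#'
#' `end_day` is the exclusive bound of the exposure interval; for a
#' discontinuation the reported discontinuation date (`disc_day`) is
#' `end_day - 1`, the last day covered by the last delivery.
#'
#' @param dispensings dispensing table (`person_id`, `dispense_day`,
#'   `drug_code`, `units`).
#' @param index_dates output of [find_index_dates()].
#' @param specs drug specification table.
#' @param persons person table with `death_day`, `data_end_day`.
#' @param grace_days refill grace period (default 30).
#' @return tibble of episodes: `person_id`, `drug_name`, `index_day`,
#'   `end_day` (exclusive), `disc_day`, `end_reason`, `n_dispensings`,
#'   `duration_days`.
#' @export
build_episodes <- function(dispensings, index_dates, specs, persons,
                           grace_days = GRACE_DAYS) {
  if (nrow(index_dates) == 0L) {
    return(tibble(
      person_id = character(), drug_name = character(), index_day = integer(),
      end_day = integer(), disc_day = integer(), end_reason = character(),
      n_dispensings = integer(), duration_days = integer()
    ))
  }
  disp <- dispensings %>%
    inner_join(specs_code_table(specs), by = "drug_code") %>%
    select("person_id", "dispense_day", "units", "drug_name",
      coverage = "coverage_days_per_unit"
    ) %>%
    inner_join(index_dates, by = c("person_id", "drug_name")) %>%
    filter(.data$dispense_day >= .data$index_day) %>%
    arrange(.data$person_id, .data$drug_name, .data$dispense_day)

  if (nrow(disp) == 0L) stop("no dispensings found at or after the index dates")

  key <- paste(disp$person_id, disp$drug_name, sep = "\r")
  groups <- split(seq_len(nrow(disp)), factor(key, levels = unique(key)))
  first <- vapply(groups, `[`, integer(1), 1L)
  days <- disp$dispense_day
  units <- disp$units
  cov <- disp$coverage
  raw_cov_end <- integer(length(groups))
  n_disp <- integer(length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    ch <- chain_coverage(days[idx], units[idx], cov[idx[1L]], grace_days)
    raw_cov_end[g] <- as.integer(ch$cov_end)
    n_disp[g] <- ch$n_dispensings
  }
  episodes <- tibble(
    person_id = disp$person_id[first],
    drug_name = disp$drug_name[first],
    index_day = disp$index_day[first],
    raw_cov_end = raw_cov_end,
    n_dispensings = n_disp
  ) %>%
    left_join(
      persons %>% select("person_id", "death_day", "data_end_day"),
      by = "person_id"
    )

  death_bound <- ifelse(is.na(episodes$death_day), Inf, episodes$death_day + 1)
  fup_bound <- episodes$data_end_day + 1L
  end_day <- pmin(episodes$raw_cov_end, death_bound, fup_bound)
  reason <- ifelse(
    death_bound <= end_day, "death",
    ifelse(fup_bound <= episodes$raw_cov_end, "end_of_followup", "discontinuation")
  )
  episodes %>%
    mutate(
      end_day = as.integer(end_day),
      end_reason = reason,
      disc_day = ifelse(.data$end_reason == "discontinuation", .data$end_day - 1L, NA_integer_),
      duration_days = .data$end_day - .data$index_day
    ) %>%
    select(
      "person_id", "drug_name", "index_day", "end_day", "disc_day",
      "end_reason", "n_dispensings", "duration_days", "raw_cov_end"
    )
}

#' Annotate episodes that end by switching to another study drug
#'
#' If another study medication is initiated (its new-user index date
#' falls) strictly after the current episode's index and before the
#' episode's current end, the episode is truncated the day before the new
#' drug's first delivery and its end reason becomes "switch".
#'
#' @param episodes episodes from [build_episodes()].
#' @param index_dates all candidate index dates (all drugs).
#' @return episodes with `end_day`, `disc_day`, `end_reason`,
#'   `duration_days` updated.
#' @export
detect_switches <- function(episodes, index_dates) {
  if (nrow(episodes) == 0L) return(episodes)
  other <- index_dates %>%
    rename(other_drug = "drug_name", other_index = "index_day")
  sw <- episodes %>%
    select("person_id", "drug_name", "index_day", "end_day") %>%
    inner_join(other, by = "person_id", relationship = "many-to-many") %>%
    filter(
      .data$other_drug != .data$drug_name,
      .data$other_index > .data$index_day,
      .data$other_index < .data$end_day
    )
  sw <- if (nrow(sw)) {
    sw %>%
      group_by(.data$person_id, .data$drug_name) %>%
      summarise(switch_day = min(.data$other_index), .groups = "drop")
  } else {
    tibble(person_id = character(), drug_name = character(), switch_day = integer())
  }

  episodes %>%
    left_join(sw, by = c("person_id", "drug_name")) %>%
    mutate(
      switched = !is.na(.data$switch_day),
      end_day = ifelse(.data$switched, .data$switch_day, .data$end_day),
      end_reason = ifelse(.data$switched, "switch", .data$end_reason),
      disc_day = ifelse(.data$switched, NA_integer_, .data$disc_day),
      duration_days = as.integer(.data$end_day - .data$index_day)
    ) %>%
    select(-"switch_day", -"switched") %>%
    mutate(end_day = as.integer(.data$end_day), disc_day = as.integer(.data$disc_day))
}
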
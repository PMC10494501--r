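# Incidence rates and incidence rate ratios with exact confidence
# intervals.
#
# Rates use the exact Poisson (Garwood) interval on the event count:
# lower = qchisq(a/2, 2x)/2, upper = qchisq(1 - a/2, 2(x+1))/2, scaled to
# events per 1000 person-years. IRRs use the exact conditional method:
# given the total count x1 + x2, x1 is binomial with success probability
# p = PY1*IRR / (PY1*IRR + PY2); the Clopper-Pearson interval for p is
# inverted to an interval for the IRR. A log-normal approximation
# (log IRR +/- z*sqrt(1/x1 + 1/x2)) is available as an option; the method
# used is recorded in the output.

#' Incidence rate with exact Poisson confidence interval
#'
#' @param events event count (vectorised).
#' @param person_years person-years at risk (vectorised).
#' @param level confidence level (default 0.95).
#' @param per rate multiplier (default 1000, i.e. events per 1000 PY).
#' @return tibble: `events`, `person_years`, `rate`, `ci_low`, `ci_high`,
#'   `method`, `defined`. Zero events give a lower bound of 0; zero
#'   person-years give an undefined (all-NA) row.
#' @export
rate_ci <- function(events, person_years, level = 0.95, per = 1000) {
  stopifnot(all(events >= 0, na.rm = TRUE), all(person_years >= 0, na.rm = TRUE))
  n <- max(length(events), length(person_years))
  events <- rep_len(as.numeric(events), n)
  person_years <- rep_len(as.numeric(person_years), n)
  a <- 1 - level
  lo_count <- ifelse(events == 0, 0, qchisq(a / 2, 2 * events) / 2)
  hi_count <- qchisq(1 - a / 2, 2 * (events + 1)) / 2
  defined <- person_years > 0
  tibble(
    events = events, person_years = person_years,
    rate = ifelse(defined, per * events / person_years, NA_real_),
    ci_low = ifelse(defined, per * lo_count / person_years, NA_real_),
    ci_high = ifelse(defined, per * hi_count / person_years, NA_real_),
    method = "exact_poisson",
    defined = defined
  )
}

#' Incidence rate ratio with exact conditional confidence interval
#'
#' The point estimate is the ratio of the two rates. The default interval
#' conditions on the total event count and inverts the exact
#' Clopper-Pearson binomial interval; with zero events in one cell the
#' corresponding bound is 0 (numerator) or infinite (denominator), and
#' with both counts zero the result is flagged undefined.
#'
#' @param events_num,py_num events and person-years in the comparison
#'   (risk) window.
#' @param events_den,py_den events and person-years in the reference
#'   (baseline) window.
#' @param level confidence level.
#' @param method "exact" (conditional binomial) or "lognormal".
#' @return tibble: counts, `irr`, `ci_low`, `ci_high`, `method`,
#'   `defined`.
#' @export
irr_ci <- function(events_num, py_num, events_den, py_den,
                   level = 0.95, method = c("exact", "lognormal")) {
  method <- match.arg(method)
  n <- max(length(events_num), length(py_num), length(events_den), length(py_den))
  x1 <- rep_len(as.numeric(events_num), n)
  t1 <- rep_len(as.numeric(py_num), n)
  x2 <- rep_len(as.numeric(events_den), n)
  t2 <- rep_len(as.numeric(py_den), n)
  a <- 1 - level

  defined <- t1 > 0 & t2 > 0 & (x1 + x2) > 0
  irr <- ifelse(t1 > 0 & t2 > 0 & (x2 > 0 | x1 == 0),
    (x1 / t1) / ifelse(x2 > 0, x2 / t2, NA_real_), Inf
  )
  irr[!defined] <- NA_real_
  irr[defined & x1 == 0 & x2 > 0] <- 0

  if (method == "exact") {
    # Clopper-Pearson on p = x1 / (x1 + x2), then IRR = odds(p) * t2/t1
    p_lo <- ifelse(x1 == 0, 0, qbeta(a / 2, x1, x2 + 1))
    p_hi <- ifelse(x2 == 0, 1, qbeta(1 - a / 2, x1 + 1, x2))
    ci_low <- ifelse(p_lo == 0, 0, p_lo / (1 - p_lo) * t2 / t1)
    ci_high <- ifelse(p_hi == 1, Inf, p_hi / (1 - p_hi) * t2 / t1)
  } else {
    se <- sqrt(1 / x1 + 1 / x2)
    z <- qnorm(1 - a / 2)
    ci_low <- exp(log(irr) - z * se)
    ci_high <- exp(log(irr) + z * se)
    ci_low[x1 == 0 | x2 == 0] <- NA_real_
    ci_high[x1 == 0 | x2 == 0] <- NA_real_
  }
  ci_low[!defined] <- NA_real_
  ci_high[!defined] <- NA_real_

  tibble(
    events_num = x1, py_num = t1, events_den = x2, py_den = t2,
    irr = irr, ci_low = ci_low, ci_high = ci_high,
    method = if (method == "exact") "exact_conditional" else "lognormal",
    defined = defined
  )
}

#' Compute all IRRs from an accumulated cell table
#'
#' For every (cohort, site group, mode, stratum) the risk windows are
#' compared to baseline; when post-discontinuation cells are present they
#' are additionally compared to baseline and to the last on-treatment
#' window (3-24 months). Log-transformed columns are included for forest
#' plotting.
#'
#' @param cells cell table from [accumulate_persontime()] (optionally with
#'   post-discontinuation and stratum rows bound on).
#' @param level confidence level.
#' @param method interval method, see [irr_ci()].
#' @return tibble with one row per comparison: `comparison`
#'   ("<window>_vs_baseline" or "post_disc_vs_m3_24"), counts,
#'   person-years, rates, `irr`, `ci_low`, `ci_high`, `log_irr`,
#'   `log_ci_low`, `log_ci_high`, `defined`.
#' @export
run_irr <- function(cells, level = 0.95, method = "exact") {
  keys <- intersect(c("cohort", "site_group", "mode", "stratum_var", "stratum"), names(cells))
  slim <- cells %>% select(all_of(keys), "window", "events", "person_years")

  pick <- function(win, prefix) {
    df <- slim %>%
      filter(.data$window == win) %>%
      select(all_of(keys), "events", "person_years")
    names(df)[names(df) == "events"] <- paste0(prefix, "_events")
    names(df)[names(df) == "person_years"] <- paste0(prefix, "_py")
    df
  }

  one_comparison <- function(win, ref, label) {
    num <- pick(win, "num")
    den <- pick(ref, "den")
    joined <- inner_join(num, den, by = keys)
    if (nrow(joined) == 0L) return(NULL)
    res <- irr_ci(joined$num_events, joined$num_py,
      joined$den_events, joined$den_py,
      level = level, method = method
    )
    bind_cols(
      joined %>% select(all_of(keys)),
      tibble(comparison = label, window = win, reference = ref),
      res
    )
  }

  wins <- setdiff(unique(slim$window), c("baseline", "post_disc"))
  out <- bind_rows(
    lapply(wins, function(w) one_comparison(w, "baseline", paste0(w, "_vs_baseline")))
  )
  if ("post_disc" %in% slim$window) {
    out <- bind_rows(
      out,
      one_comparison("post_disc", "baseline", "post_disc_vs_baseline"),
      if ("m3_24" %in% slim$window) one_comparison("post_disc", "m3_24", "post_disc_vs_m3_24")
    )
  }
  out %>%
    mutate(
      rate_num = 1000 * .data$events_num / .data$py_num,
      rate_den = 1000 * .data$events_den / .data$py_den,
      log_irr = ifelse(.data$defined & .data$irr > 0 & is.finite(.data$irr),
        log(.data$irr), NA_real_
      ),
      log_ci_low = ifelse(!is.na(.data$ci_low) & .data$ci_low > 0, log(.data$ci_low), NA_real_),
      log_ci_high = ifelse(!is.na(.data$ci_high) & is.finite(.data$ci_high),
        log(.data$ci_high), NA_real_
      )
    )
}

#' Round a rate ratio for display
#'
#' Display convention: rates to two decimals, rate ratios to one decimal
#' (full precision is always retained in the machine-readable output).
#'
#' @param x numeric vector.
#' @param digits decimals (default 1).
#' @return rounded numeric vector.
#' @export
round_display <- function(x, digits = 1) round(x, digits)
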
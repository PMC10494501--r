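# Independent brute-force oracles. These deliberately use a different
# algorithmic route (day-by-day simulation, numerical inversion of tail
# probabilities) from the package implementations they check.

# Day-by-day supply-queue simulation of continuous coverage: a delivery
# adds units*coverage days of supply, one day of supply is consumed per
# covered day, and the episode survives an uncovered run only if a new
# delivery arrives within grace_days of the day coverage ran out.
oracle_coverage <- function(dates, units, coverage_days, grace_days = 30L) {
  o <- order(dates)
  dates <- dates[o]; units <- units[o]
  horizon <- max(dates) + sum(units) * coverage_days + grace_days + 2L
  supply <- 0L
  n_disp <- 0L
  cov_end <- dates[1L]
  uncovered <- 0L
  for (t in dates[1L]:horizon) {
    hit <- which(dates == t)
    if (length(hit)) {
      supply <- supply + sum(units[hit]) * coverage_days
      n_disp <- n_disp + length(hit)
    }
    if (supply > 0L) {
      supply <- supply - 1L
      cov_end <- t + 1L
      uncovered <- 0L
    } else {
      uncovered <- uncovered + 1L
      if (uncovered > grace_days) break
    }
  }
  list(cov_end = cov_end, n_dispensings = n_disp)
}

# day loop over a woman's timeline: person-days and events per window
oracle_window <- function(index, censor, win_start, win_end, event_days = integer()) {
  pd <- 0L
  ev <- 0L
  lo <- index + win_start
  hi <- index + win_end
  if (censor > lo) {
    for (t in lo:(min(hi, censor) - 1L)) {
      if (t >= lo && t < hi && t >= index && t < censor) {
        pd <- pd + 1L
        }
    }
  }
  for (e in event_days) {
    if (e >= lo && e < hi && e < censor) ev <- ev + 1L
  }
  list(person_days = pd, events = ev)
}

# exact Poisson interval by numerical inversion of the tail probabilities
oracle_poisson_ci <- function(x, level = 0.95) {
  a <- 1 - level
  up <- uniroot(function(mu) ppois(x, mu) - a / 2, c(1e-9, 10 * x + 50), tol = 1e-10)$root
  lo <- if (x == 0) 0 else {
    uniroot(function(mu) 1 - ppois(x - 1, mu) - a / 2, c(1e-12, 10 * x + 50), tol = 1e-10)$root
  }
  c(lo, up)
}

# exact conditional IRR interval by numerical inversion of the binomial
# tails for p = t1*irr / (t1*irr + t2), given n = x1 + x2 successes x1
oracle_irr_ci <- function(x1, t1, x2, t2, level = 0.95) {
  a <- 1 - level
  n <- x1 + x2
  p_of <- function(irr) t1 * irr / (t1 * irr + t2)
  up <- if (x2 == 0) Inf else {
    uniroot(
      function(irr) pbinom(x1, n, p_of(irr)) - a / 2,
      c(1e-9, 1e9), tol = 1e-10
    )$root
  }
  lo <- if (x1 == 0) 0 else {
    uniroot(
      function(irr) 1 - pbinom(x1 - 1, n, p_of(irr)) - a / 2,
      c(1e-12, 1e9), tol = 1e-10
    )$root
  }
  c(lo, up)
}
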
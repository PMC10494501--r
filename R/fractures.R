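#' Default fracture code map (synthetic stand-in list)
#'
#' Maps ICD-10-style diagnosis code prefixes and procedure-code
#' placeholders to anatomical fracture sites. Matching is by longest
#' prefix, so e.g. "S7210" matches the "S72" hip entry while "S220"
#' (vertebral) wins over a hypothetical "S22" entry. This default list is
#' an editable configuration, not a validated national code list: real
#' studies must substitute their own audited mapping.
#'
#' Sites: hip, vertebral, wrist_forearm, humerus, clavicle, ribs, pelvis,
#' leg. Diagnosis codes count in principal, related or associated position
#' by default; procedure codes count regardless of position.
#'
#' @return tibble with columns `code` (prefix), `site`, `code_type`.
#' @export
default_fracture_codes <- function() {
  tribble(
    ~code,   ~site,           ~code_type,
    "S72",   "hip",           "diagnosis",
    "S220",  "vertebral",     "diagnosis",
    "S320",  "vertebral",     "diagnosis",
    "T08",   "vertebral",     "diagnosis",
    "VERTP", "vertebral",     "procedure",   # vertebroplasty-like placeholder
    "S52",   "wrist_forearm", "diagnosis",
    "S422",  "humerus",       "diagnosis",
    "S423",  "humerus",       "diagnosis",
    "S420",  "clavicle",      "diagnosis",
    "S222",  "ribs",          "diagnosis",
    "S321",  "pelvis",        "diagnosis",
    "S322",  "pelvis",        "diagnosis",
    "S323",  "pelvis",        "diagnosis",
    "S324",  "pelvis",        "diagnosis",
    "S325",  "pelvis",        "diagnosis",
    "S328",  "pelvis",        "diagnosis",
    "S82",   "leg",           "diagnosis"
  )
}

# longest-prefix match of observed codes against a map; returns the mapped
# site (NA when unmapped)
match_code_site <- function(codes, code_map) {
  out <- rep(NA_character_, length(codes))
  len <- rep(0L, length(codes))
  for (i in seq_len(nrow(code_map))) {
    pre <- code_map$code[i]
    hit <- startsWith(codes, pre) & nchar(pre) > len
    out[hit] <- code_map$site[i]
    len[hit] <- nchar(pre)
  }
  out
}

#' Identify raw hospitalized fracture events from stays
#'
#' One raw event per (stay, site): several codes of the same site within
#' one stay collapse into a single event dated at admission. Diagnosis
#' codes are accepted in the configured positions (default: principal,
#' related, associated); procedure codes are accepted in any position.
#'
#' @param stays long stay table: one row per code, columns `stay_id`,
#'   `person_id`, `admission_day`, `code`, `code_type`
#'   ("diagnosis"/"procedure") and `code_position`.
#' @param code_map fracture code map, see [default_fracture_codes()].
#' @param accepted_positions diagnosis positions that qualify.
#' @return tibble `person_id`, `stay_id`, `event_day`, `site`.
#' @export
identify_raw_events <- function(stays, code_map = default_fracture_codes(),
                                accepted_positions = c("principal", "related", "associated")) {
  if (nrow(stays) == 0L) {
    return(tibble(
      person_id = character(), stay_id = integer(),
      event_day = integer(), site = character()
    ))
  }
  hits <- stays %>%
    mutate(site = match_code_site(.data$code, code_map)) %>%
    filter(
      !is.na(.data$site),
      .data$code_type == "procedure" | .data$code_position %in% accepted_positions
    )
  hits %>%
    distinct(.data$person_id, .data$stay_id, .data$site, .keep_all = TRUE) %>%
    transmute(
      person_id = .data$person_id,
      stay_id = .data$stay_id,
      event_day = as.integer(.data$admission_day),
      site = .data$site
    ) %>%
    arrange(.data$person_id, .data$event_day, .data$site)
}

#' Flag independent fracture events (90-day same-site rule)
#'
#' A same-site recurrence is independent only if it falls at least 90 days
#' after the previous *independent* event of that site and no fracture of
#' any other site occurred strictly between the two dates. The first event
#' of each site is always independent. Non-independent events are retained
#' with `independent = FALSE` for audit; only independent events enter the
#' incidence computation.
#'
#' @param events raw events from [identify_raw_events()].
#' @param min_gap_days minimum separation; the inclusive reading is used
#'   (a gap of exactly 90 days qualifies).
#' @return `events` with a logical `independent` column, sorted by person
#'   and date.
#' @export
deduplicate_events <- function(events, min_gap_days = 90L) {
  if (nrow(events) == 0L) {
    return(mutate(events, independent = logical(0)))
  }
  events <- arrange(events, .data$person_id, .data$event_day, .data$site)
  flag_person <- function(day, site) {
    n <- length(day)
    indep <- logical(n)
    last_indep <- setNames(rep(NA_integer_, length(FRACTURE_SITES)), FRACTURE_SITES)
    for (i in seq_len(n)) {
      prev <- last_indep[[site[i]]]
      if (is.na(prev)) {
        indep[i] <- TRUE
      } else {
        gap_ok <- (day[i] - prev) >= min_gap_days
        between <- day > prev & day < day[i] & site != site[i]
        indep[i] <- gap_ok && !any(between)
      }
      if (indep[i]) last_indep[[site[i]]] <- day[i]
    }
    indep
  }
  events %>%
    group_by(.data$person_id) %>%
    mutate(independent = flag_person(.data$event_day, .data$site)) %>%
    ungroup()
}

#' Assign overlapping site-group memberships
#'
#' The four analysis groups are not mutually exclusive: hip and vertebral
#' events form their own groups; wrist/forearm, humerus, clavicle, ribs,
#' pelvis and leg events form the non-hip/nonvertebral group, with
#' wrist/forearm events additionally counted in their own group.
#'
#' @param events event table with a `site` column.
#' @return the events expanded to one row per (event, site_group), column
#'   `site_group` added.
#' @export
assign_site_groups <- function(events) {
  bad <- setdiff(unique(events$site), FRACTURE_SITES)
  if (length(bad)) stop("unmapped fracture site(s): ", paste(bad, collapse = ", "))
  membership <- site_group_membership()
  events %>%
    inner_join(membership, by = "site", relationship = "many-to-many")
}

site_group_membership <- function() {
  nhnv <- c("wrist_forearm", "humerus", "clavicle", "ribs", "pelvis", "leg")
  bind_rows(
    tibble(site = "hip", site_group = "hip"),
    tibble(site = "vertebral", site_group = "vertebral"),
    tibble(site = "wrist_forearm", site_group = "wrist_forearm"),
    tibble(site = nhnv, site_group = "nonhip_nonvertebral")
  )
}
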
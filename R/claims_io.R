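# Reading and writing the three claims tables (plus generator ground
# truth). Plain CSV with ISO-8601 dates; *_day columns are the internal
# integer representation and *_date columns the calendar rendering.

person_cols <- c("person_id", "sex", "birth_date", "death_date", "data_start", "data_end")
dispensing_cols <- c("person_id", "dispense_date", "drug_code", "units")
stay_cols <- c(
  "stay_id", "person_id", "admission_date", "discharge_date",
  "code", "code_type", "code_position"
)

parse_date_col <- function(x, col, file) {
  x <- as.character(x)
  blank <- is.na(x) | x == ""
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(!blank & is.na(d))
  if (length(bad)) {
    stop(
      file, ": unparseable date in column '", col, "' at row(s) ",
      paste(head(bad, 10L), collapse = ", "),
      call. = FALSE
    )
  }
  as.integer(d)
}

require_cols <- function(df, cols, file) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(file, ": missing column(s) ", paste(miss, collapse = ", "), call. = FALSE)
  }
}

#' Read the three claims tables from a directory
#'
#' Expects `persons.csv`, `dispensings.csv` and `stays.csv` as written by
#' [write_claims()]. Dates are validated row by row; a malformed date is
#' rejected with its row number. An empty `stays.csv` (headers only) is
#' valid and yields an empty table, so a zero-event pipeline still runs.
#'
#' @param directory path containing the claims files.
#' @return list of tibbles `persons`, `dispensings`, `stays` with internal
#'   integer `*_day` columns.
#' @export
read_claims <- function(directory) {
  rd <- function(name) {
    path <- file.path(directory, name)
    if (!file.exists(path)) stop("claims file not found: ", path, call. = FALSE)
    as_tibble(read.csv(path, colClasses = "character"))
  }

  persons <- rd("persons.csv")
  require_cols(persons, person_cols, "persons.csv")
  persons <- persons %>% mutate(
    birth_day = parse_date_col(.data$birth_date, "birth_date", "persons.csv"),
    death_day = parse_date_col(.data$death_date, "death_date", "persons.csv"),
    data_start_day = parse_date_col(.data$data_start, "data_start", "persons.csv"),
    data_end_day = parse_date_col(.data$data_end, "data_end", "persons.csv")
  )

  dispensings <- rd("dispensings.csv")
  require_cols(dispensings, dispensing_cols, "dispensings.csv")
  dispensings <- dispensings %>% mutate(
    dispense_day = parse_date_col(.data$dispense_date, "dispense_date", "dispensings.csv"),
    units = as.integer(.data$units)
  )
  if (any(is.na(dispensings$units) | dispensings$units < 1L)) {
    stop("dispensings.csv: units must be integers >= 1", call. = FALSE)
  }

  stays <- rd("stays.csv")
  require_cols(stays, stay_cols, "stays.csv")
  stays <- stays %>% mutate(
    stay_id = as.integer(.data$stay_id),
    admission_day = parse_date_col(.data$admission_date, "admission_date", "stays.csv"),
    discharge_day = parse_date_col(.data$discharge_date, "discharge_date", "stays.csv")
  )
  if (nrow(stays) && any(stays$admission_day > stays$discharge_day, na.rm = TRUE)) {
    stop("stays.csv: admission_date after discharge_date", call. = FALSE)
  }

  list(persons = persons, dispensings = dispensings, stays = stays)
}

#' Write a claims dataset (and its ground truth) to a directory
#'
#' Emits `persons.csv`, `dispensings.csv`, `stays.csv` and, when the
#' dataset carries them, `ground_truth.csv` and `true_events.csv`, all
#' with ISO-8601 dates. Round-trips losslessly through [read_claims()].
#'
#' @param dataset list as returned by [simulate_claims()] (or at least the
#'   three claims tibbles).
#' @param directory output directory, created if absent.
#' @return invisibly, the paths written.
#' @export
write_claims <- function(dataset, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  iso <- function(day) {
    ifelse(is.na(day), "", format(day_to_date(day), "%Y-%m-%d"))
  }
  wr <- function(df, name) {
    path <- file.path(directory, name)
    write.csv(df, path, row.names = FALSE, na = "")
    path
  }

  paths <- c(
    wr(
      dataset$persons %>% transmute(
        person_id = .data$person_id, sex = .data$sex,
        birth_date = iso(.data$birth_day),
        death_date = iso(.data$death_day),
        data_start = iso(.data$data_start_day),
        data_end = iso(.data$data_end_day)
      ),
      "persons.csv"
    ),
    wr(
      dataset$dispensings %>% transmute(
        person_id = .data$person_id,
        dispense_date = iso(.data$dispense_day),
        drug_code = .data$drug_code, units = .data$units
      ),
      "dispensings.csv"
    ),
    wr(
      dataset$stays %>% transmute(
        stay_id = .data$stay_id, person_id = .data$person_id,
        admission_date = iso(.data$admission_day),
        discharge_date = iso(.data$discharge_day),
        code = .data$code, code_type = .data$code_type,
        code_position = .data$code_position
      ),
      "stays.csv"
    )
  )
  if (!is.null(dataset$ground_truth)) {
    gt <- dataset$ground_truth %>% mutate(
      index_date = iso(.data$index_day),
      disc_date = iso(.data$disc_day),
      death_date = iso(.data$death_day)
    )
    paths <- c(paths, wr(gt, "ground_truth.csv"))
  }
  if (!is.null(dataset$true_events)) {
    te <- dataset$true_events %>% mutate(event_date = iso(.data$event_day))
    paths <- c(paths, wr(te, "true_events.csv"))
  }
  invisible(paths)
}
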
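#' Read a narrative rating log
#'
#' Parses a delimited rating log in which each row is one timestamped feedback
#' submission: a compulsory hopefulness answer on the -1..2 scale and, when the
#' participant chose to answer the optional questions, all four optional
#' answers on the 0..3 scale. Optional answers are all-or-none: a row with a
#' partially filled optional block is rejected.
#'
#' @param path Path to a CSV file with columns `participant_id`,
#'   `narrative_id`, `timestamp` (ISO-8601, UTC), `hopefulness`,
#'   `sim_narrator`, `sim_narrative`, `learning`, `empathy` (optional cells
#'   empty) and an optional `source` label column.
#' @return A tibble of rating events sorted by timestamp, one row per event.
#' @export
read_rating_log <- function(path) {
  if (!file.exists(path)) abort(paste0("rating log not found: ", path))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      narrative_id = readr::col_character(),
      timestamp = readr::col_datetime(format = ""),
      hopefulness = readr::col_integer(),
      sim_narrator = readr::col_integer(),
      sim_narrative = readr::col_integer(),
      learning = readr::col_integer(),
      empathy = readr::col_integer(),
      .default = readr::col_character()
    ),
    progress = FALSE
  )
  required <- c("participant_id", "narrative_id", "timestamp", "hopefulness",
                "sim_narrator", "sim_narrative", "learning", "empathy")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("rating log is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"source" %in% names(raw)) raw$source <- NA_character_
  validate_rating_events(raw)
  dplyr::arrange(raw, .data$timestamp)
}

#' Validate a table of rating events
#'
#' Checks the schema invariants of a rating log: hopefulness present and in
#' -1..2, optional answers in 0..3 and present all-together or absent
#' all-together, ids and timestamps non-missing. Errors name the offending
#' row numbers.
#'
#' @param events A data frame of rating events.
#' @return The input, invisibly, if valid.
#' @export
validate_rating_events <- function(events) {
  bad_row <- function(cond, what) {
    idx <- which(cond)
    if (length(idx) > 0) {
      abort(paste0("invalid rating log: ", what, " at row",
                   if (length(idx) > 1) "s" else "", " ",
                   paste(head(idx, 5), collapse = ", "),
                   if (length(idx) > 5) " ..." else ""))
    }
  }
  bad_row(is.na(events$participant_id) | events$participant_id == "",
          "missing participant_id")
  bad_row(is.na(events$narrative_id) | events$narrative_id == "",
          "missing narrative_id")
  bad_row(is.na(events$timestamp), "missing or unparseable timestamp")
  bad_row(is.na(events$hopefulness), "missing hopefulness (compulsory)")
  bad_row(!events$hopefulness %in% (-1:2), "hopefulness outside -1..2")
  opt <- as.matrix(events[, c("sim_narrator", "sim_narrative",
                              "learning", "empathy")])
  n_answered <- rowSums(!is.na(opt))
  bad_row(n_answered > 0 & n_answered < 4,
          "partial optional block (answers are all-or-none)")
  bad_row(n_answered == 4 & (apply(opt, 1, min) < 0 | apply(opt, 1, max) > 3),
          "optional answer outside 0..3")
  invisible(events)
}

#' Write a rating log
#'
#' Inverse of [read_rating_log()]: writes events as CSV with ISO-8601 UTC
#' timestamps so that a read/write round trip reproduces the table.
#'
#' @param events A validated tibble of rating events.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rating_log <- function(events, path) {
  out <- events
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a narrative characteristic catalog
#'
#' Each row describes one narrative: an id, the date from which it was
#' available for recommendation, and a fixed-width vector of categorical
#' characteristic codes `c1..cd` (emulating an INCRESE-style inventory).
#' All narratives in one catalog must share the same characteristic width.
#'
#' @param path Path to a CSV file with columns `narrative_id`,
#'   `available_from`, `c1` .. `cd`.
#' @return A tibble, one row per narrative.
#' @export
read_narrative_catalog <- function(path) {
  if (!file.exists(path)) abort(paste0("narrative catalog not found: ", path))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      narrative_id = readr::col_character(),
      available_from = readr::col_date(format = ""),
      .default = readr::col_character()
    ),
    progress = FALSE
  )
  if (!all(c("narrative_id", "available_from") %in% names(raw))) {
    abort("narrative catalog must have narrative_id and available_from columns")
  }
  feat <- characteristic_columns(raw)
  if (length(feat) < 2) abort("narrative catalog needs at least 2 characteristic columns (c1..cd)")
  if (anyNA(raw$narrative_id) || anyDuplicated(raw$narrative_id) > 0) {
    abort("narrative_id must be unique and non-missing")
  }
  raw
}

characteristic_columns <- function(catalog) {
  cols <- grep("^c[0-9]+$", names(catalog), value = TRUE)
  cols[order(as.integer(sub("^c", "", cols)))]
}

#' Read a participant profile table
#'
#' @param path Path to a CSV file with columns `participant_id`, `gender`,
#'   `ethnicity`, `enrolled_on`.
#' @param gender_map,ethnicity_map Optional named character vectors (or paths
#'   to two-column CSV files `from,to`) remapping source codes onto the
#'   canonical categories `female`/`male`/`other` and
#'   `white_british`/`other_ethnicity`. Codes not covered by the canonical set
#'   or the mapping are rejected.
#' @return A tibble with the canonical demographic categories plus the derived
#'   binary disadvantaged-group flags used by the unfairness metric:
#'   `gender_disadvantaged` (female or other) and `ethnicity_disadvantaged`
#'   (other ethnicity).
#' @export
read_participant_profiles <- function(path, gender_map = NULL,
                                      ethnicity_map = NULL) {
  if (!file.exists(path)) abort(paste0("participant table not found: ", path))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      gender = readr::col_character(),
      ethnicity = readr::col_character(),
      enrolled_on = readr::col_date(format = "")
    ),
    progress = FALSE
  )
  raw$gender <- apply_code_map(raw$gender, GENDER_LEVELS, gender_map, "gender")
  raw$ethnicity <- apply_code_map(raw$ethnicity, ETHNICITY_LEVELS,
                                  ethnicity_map, "ethnicity")
  if (anyDuplicated(raw$participant_id) > 0) {
    abort("participant_id must be unique")
  }
  add_group_flags(raw)
}

apply_code_map <- function(x, levels, map, what) {
  if (is.character(map) && length(map) == 1 && file.exists(map)) {
    m <- readr::read_csv(map, col_types = "cc", progress = FALSE)
    map <- setNames(m[[2]], m[[1]])
  }
  if (!is.null(map)) {
    hit <- x %in% names(map)
    x[hit] <- unname(map[x[hit]])
  }
  bad <- unique(x[!x %in% levels])
  if (length(bad) > 0) {
    abort(paste0("unknown ", what, " code(s): ", paste(bad, collapse = ", "),
                 " (provide a mapping onto ",
                 paste(levels, collapse = "/"), ")"))
  }
  x
}

#' Derive disadvantaged-group flags from demographic categories
#'
#' The gender-disadvantaged group is participants recorded as female or other;
#' the ethnicity-disadvantaged group is participants of any ethnicity other
#' than White British.
#'
#' @param participants A tibble with `gender` and `ethnicity` columns.
#' @return The tibble with logical `gender_disadvantaged` and
#'   `ethnicity_disadvantaged` columns.
#' @export
add_group_flags <- function(participants) {
  dplyr::mutate(
    participants,
    gender_disadvantaged = .data$gender %in% c("female", "other"),
    ethnicity_disadvantaged = .data$ethnicity == "other_ethnicity"
  )
}
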
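#' Percentage of a count within a total
#'
#' The rounding convention used throughout the descriptive tables: one
#' decimal place by default, and trailing zeros are a display matter (40 is
#' printed for 40.0).
#'
#' @param n Numerator count(s).
#' @param total Denominator count.
#' @param digits Decimal places (default 1).
#' @return Numeric percentage(s).
#' @export
share_pct <- function(n, total, digits = 1) {
  round(100 * n / total, digits)
}

#' Distribution of rating values per question
#'
#' Counts and percentage shares of each answer value for every question in a
#' rating log, on each question's native scale (hopefulness -1..2, optional
#' questions 0..3). Optional-question shares are out of the optional ratings
#' only.
#'
#' @param events A validated rating-event tibble.
#' @param digits Decimal places for percentages; the hopefulness row uses
#'   `hop_digits` (default 2, matching the finer precision those shares are
#'   conventionally reported at).
#' @param hop_digits Decimal places for the hopefulness shares.
#' @return A tibble (question, value, n, pct).
#' @export
rating_value_distribution <- function(events, digits = 1, hop_digits = 2) {
  count_vals <- function(x, levels) {
    tibble::tibble(value = levels,
                   n = vapply(levels, function(v) sum(x == v, na.rm = TRUE),
                              integer(1)))
  }
  hop <- count_vals(events$hopefulness, -1:2) |>
    dplyr::mutate(question = "hopefulness",
                  pct = share_pct(.data$n, sum(.data$n), hop_digits))
  opts <- purrr::map(c("sim_narrator", "sim_narrative", "learning", "empathy"),
                     function(q) {
    count_vals(events[[q]], 0:3) |>
      dplyr::mutate(question = q,
                    pct = share_pct(.data$n, sum(.data$n), digits))
  })
  dplyr::bind_rows(hop, opts) |>
    dplyr::select("question", "value", "n", "pct")
}

#' Descriptive summary of a trial's request and feedback log
#'
#' Recomputes the standard per-trial summary statistics from a rating log, a
#' participant table, and a narrative catalog: participant counts, catalog
#' size at the start and end of the window, narratives given at least one
#' rating, rating and optional-rating counts, and the median (IQR) number of
#' ratings per narrative and per rated narrative. Counts are paired with
#' percentage shares of their natural denominator.
#'
#' @param events A validated rating-event tibble (live ratings; exclude any
#'   seed batch first for trial-style figures).
#' @param participants Participant profile tibble.
#' @param catalog Narrative catalog tibble.
#' @param window_start,window_end Dates bounding the observation window;
#'   default to the catalog availability range and the last event.
#' @return A list of class `trial_descriptives` with `$summary` (tibble:
#'   statistic, n, pct, median, q1, q3) and `$distribution`
#'   ([rating_value_distribution()] of the log).
#' @export
descriptive_summary <- function(events, participants, catalog,
                                window_start = NULL, window_end = NULL) {
  if (is.null(window_start)) window_start <- min(catalog$available_from)
  if (is.null(window_end)) {
    window_end <- max(as.Date(max(events$timestamp)),
                      max(catalog$available_from))
  }
  raters <- unique(events$participant_id)
  rated <- unique(events$narrative_id)
  n_start <- sum(catalog$available_from <= window_start)
  n_end <- sum(catalog$available_from <= window_end)
  n_ratings <- nrow(events)
  n_optional <- sum(!is.na(events$sim_narrator))
  per_narrative <- events |>
    dplyr::count(.data$narrative_id) |>
    dplyr::right_join(tibble::tibble(narrative_id = catalog$narrative_id),
                      by = "narrative_id") |>
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L))
  per_rated <- per_narrative$n[per_narrative$n > 0]
  med_row <- function(x) {
    c(median = median(x), q1 = quantile(x, 0.25, names = FALSE),
      q3 = quantile(x, 0.75, names = FALSE))
  }
  all_q <- med_row(per_narrative$n)
  rated_q <- med_row(per_rated)
  summary <- tibble::tribble(
    ~statistic, ~n, ~pct, ~median, ~q1, ~q3,
    "participants", nrow(participants), 100, NA, NA, NA,
    "participants_rated", length(raters),
      share_pct(length(raters), nrow(participants)), NA, NA, NA,
    "narratives_start", n_start, 100, NA, NA, NA,
    "narratives_end", n_end, 100, NA, NA, NA,
    "narratives_rated", length(rated), share_pct(length(rated), n_end),
      NA, NA, NA,
    "ratings", n_ratings, 100, NA, NA, NA,
    "optional_ratings", n_optional, share_pct(n_optional, n_ratings),
      NA, NA, NA,
    "ratings_per_narrative", NA, NA, all_q[["median"]], all_q[["q1"]],
      all_q[["q3"]],
    "ratings_per_rated_narrative", NA, NA, rated_q[["median"]],
      rated_q[["q1"]], rated_q[["q3"]]
  )
  structure(list(summary = summary,
                 distribution = rating_value_distribution(events),
                 window = c(start = window_start, end = window_end)),
            class = "trial_descriptives")
}

#' @export
print.trial_descriptives <- function(x, ...) {
  cat("Trial descriptives (window ", format(x$window[["start"]]), " to ",
      format(x$window[["end"]]), ")\n", sep = "")
  print(x$summary, n = Inf)
  cat("\nRating value distribution:\n")
  print(x$distribution, n = Inf)
  invisible(x)
}
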
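#' Build per-question rating streams from an event log
#'
#' Collapses the raw event log into the three rating streams used for
#' recommendation and evaluation: hopefulness (shifted from its native -1..2
#' scale onto 0..3 so all streams share one scale), similarity to the
#' narrator, and similarity to the narrative. Rerating overrides: where a
#' participant rated the same narrative more than once, only the latest event
#' contributes (ties on timestamp are broken by file order, last row wins).
#' Events without an optional block contribute to the hopefulness stream only.
#' Learning and empathy answers are retained in the log but deliberately
#' excluded from streams.
#'
#' @param events A validated tibble of rating events.
#' @return A tibble with columns `question`, `participant_id`, `narrative_id`,
#'   `value` (0..3), `timestamp`; one row per (question, participant,
#'   narrative).
#' @export
build_streams <- function(events) {
  if (nrow(events) == 0) {
    return(tibble::tibble(question = character(), participant_id = character(),
                          narrative_id = character(), value = integer(),
                          timestamp = as.POSIXct(character(), tz = "UTC")))
  }
  latest <- events |>
    dplyr::mutate(.file_order = dplyr::row_number()) |>
    dplyr::arrange(.data$participant_id, .data$narrative_id,
                   .data$timestamp, .data$.file_order) |>
    dplyr::group_by(.data$participant_id, .data$narrative_id) |>
    dplyr::slice_tail(n = 1) |>
    dplyr::ungroup()
  hop <- latest |>
    dplyr::transmute(question = "hopefulness",
                     .data$participant_id, .data$narrative_id,
                     value = .data$hopefulness + 1L, .data$timestamp)
  opt <- latest |>
    dplyr::filter(!is.na(.data$sim_narrator)) |>
    dplyr::select("participant_id", "narrative_id", "timestamp",
                  "sim_narrator", "sim_narrative") |>
    tidyr::pivot_longer(c("sim_narrator", "sim_narrative"),
                        names_to = "question", values_to = "value") |>
    dplyr::select("question", "participant_id", "narrative_id",
                  "value", "timestamp")
  dplyr::bind_rows(hop, opt) |>
    dplyr::arrange(match(.data$question, STREAM_QUESTIONS),
                   .data$participant_id, .data$narrative_id)
}

#' Keep only participants and narratives with at least one rating
#'
#' Mirrors the cold-start inclusion rule: within each stream, a participant or
#' narrative is usable only if it carries at least one rating there. Because a
#' stream's rows *are* ratings, every id present already satisfies the rule,
#' so the filter is the identity on well-formed streams; it exists so that
#' callers can assert the invariant and to drop rows against a reference
#' population when `participants` / `narratives` are supplied.
#'
#' @param stream A stream tibble (possibly several questions).
#' @param participants,narratives Optional character vectors restricting the
#'   stream to known ids.
#' @return The filtered stream; warns if a stream becomes empty.
#' @export
apply_inclusion_filter <- function(stream, participants = NULL,
                                   narratives = NULL) {
  out <- stream
  if (!is.null(participants)) {
    out <- dplyr::filter(out, .data$participant_id %in% participants)
  }
  if (!is.null(narratives)) {
    out <- dplyr::filter(out, .data$narrative_id %in% narratives)
  }
  if (nrow(out) == 0 && nrow(stream) >= 0) {
    warn("inclusion filter produced an empty stream")
  }
  out
}

#' Drop a labeled seed batch of ratings from a log
#'
#' Pre-trial ratings (for instance a feasibility-study batch used to soften
#' the cold-start problem) carry a `source` label; the evaluation removes
#' them so the system is judged only on ratings collected live.
#'
#' @param events A rating-event tibble with a `source` column.
#' @param batch_label The label to remove (default `"feasibility"`).
#' @return The events without the labeled batch; warns (and returns the input
#'   unchanged) if no event carries the label.
#' @export
exclude_seed_batch <- function(events, batch_label = "feasibility") {
  if (!"source" %in% names(events)) {
    warn("events carry no source column; nothing to exclude")
    return(events)
  }
  hit <- !is.na(events$source) & events$source == batch_label
  if (!any(hit)) {
    warn(paste0("no events labeled '", batch_label, "'; returning input unchanged"))
    return(events)
  }
  events[!hit, , drop = FALSE]
}

#' One-hot encode narrative characteristics
#'
#' Expands the categorical characteristic codes `c1..cd` of a catalog into a
#' binary matrix, one column per (characteristic, category) pair observed in
#' the catalog. Cosine similarity between narratives is computed on these
#' vectors. A missing code activates no column for that characteristic.
#'
#' @param catalog A narrative catalog tibble.
#' @return A binary matrix with one row per narrative (rownames are
#'   `narrative_id`).
#' @export
one_hot_characteristics <- function(catalog) {
  feat <- characteristic_columns(catalog)
  if (length(feat) == 0) abort("catalog has no characteristic columns (c1..cd)")
  blocks <- lapply(feat, function(cl) {
    v <- factor(catalog[[cl]])
    m <- matrix(0L, nrow = nrow(catalog), ncol = nlevels(v))
    ok <- !is.na(v)
    m[cbind(which(ok), as.integer(v)[ok])] <- 1L
    colnames(m) <- paste0(cl, "=", levels(v))
    m
  })
  out <- do.call(cbind, blocks)
  rownames(out) <- catalog$narrative_id
  out
}

# Row-normalised cosine similarity between the rows of a binary (or numeric)
# matrix; all-zero rows get similarity 0 to everything (with a warning) except
# sim(i,i) which is kept at 1 by convention.
cosine_similarity <- function(m) {
  norms <- sqrt(rowSums(m^2))
  zero <- norms == 0
  if (any(zero)) {
    warn(paste0(sum(zero), " narrative(s) have all-zero characteristic vectors; ",
                "their similarities are set to 0"))
    norms[zero] <- 1
  }
  s <- (m / norms) %*% t(m / norms)
  if (any(zero)) {
    s[zero, ] <- 0
    s[, zero] <- 0
  }
  diag(s) <- 1
  s
}
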
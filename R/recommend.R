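#' Build one algorithm's internal top-n recommendation list
#'
#' Scores every candidate narrative for one participant with a fitted model
#' and keeps the n highest predictions (default 10, the internal list
#' length). Candidates the participant has already requested, or whose id or
#' characteristics the participant has blocked, must be excluded before or
#' via the `exclude` / `blocked_codes` arguments. Ties are broken by
#' ascending narrative id so runs are reproducible; unpredictable candidates
#' are dropped.
#'
#' @param model A fitted `knn_model`, `factor_model`, or `global_mean_model`.
#' @param participant_id One participant id.
#' @param candidates Character vector of candidate narrative ids.
#' @param n List length (default 10).
#' @param exclude Narrative ids to remove (previously requested or
#'   individually blocked narratives).
#' @param blocked_codes Optionally, a character vector of blocked
#'   characteristic codes (`"c3=2"` style) with `catalog` supplied: any
#'   candidate whose one-hot vector activates a blocked code is removed,
#'   implementing type-level blocking.
#' @param catalog Narrative catalog; required when `blocked_codes` is given.
#' @return A tibble (`narrative_id`, `predicted`) of up to n rows, descending
#'   by prediction; empty when no candidate is predictable.
#' @export
top_n <- function(model, participant_id, candidates, n = 10,
                  exclude = character(), blocked_codes = character(),
                  catalog = NULL) {
  cand <- setdiff(unique(candidates), exclude)
  if (length(blocked_codes) > 0) {
    if (is.null(catalog)) abort("blocked_codes requires a catalog")
    oh <- one_hot_characteristics(catalog)
    codes <- intersect(blocked_codes, colnames(oh))
    if (length(codes) > 0) {
      banned <- rownames(oh)[rowSums(oh[, codes, drop = FALSE]) > 0]
      cand <- setdiff(cand, banned)
    }
  }
  if (length(cand) == 0) {
    return(tibble::tibble(narrative_id = character(), predicted = numeric()))
  }
  cand <- sort(cand)
  pred <- predict(model, tibble::tibble(participant_id = participant_id,
                                        narrative_id = cand))
  keep <- !is.na(pred)
  out <- tibble::tibble(narrative_id = cand[keep], predicted = pred[keep])
  # sort is stable, and candidates are already in ascending id order, so
  # equal predictions keep the lower narrative id first
  out <- out[order(-out$predicted), , drop = FALSE]
  head(out, n)
}

#' Select the single served recommendation from the three internal lists
#'
#' The hybrid step: the three algorithms each contribute an internal top-10
#' list (30 entries at most) and the narrative with the highest predicted
#' rating across the union is served, labeled with the subsystem that
#' produced it. Exact ties prefer a collaborative list (svd, then svdpp)
#' over the content list, then the lower narrative id.
#'
#' @param lists A named list of top-n tibbles, names among
#'   `"knn"`, `"svd"`, `"svdpp"`.
#' @return A one-row tibble (`narrative_id`, `predicted`, `algorithm`), or a
#'   zero-row tibble when every list is empty (no recommendation).
#' @export
hybrid_select <- function(lists) {
  prec <- c(svd = 1L, svdpp = 2L, knn = 3L)
  pool <- purrr::imap(lists, function(d, nm) {
    if (nrow(d) == 0) return(NULL)
    dplyr::mutate(d, algorithm = nm)
  })
  pool <- dplyr::bind_rows(pool)
  if (is.null(pool) || nrow(pool) == 0) {
    return(tibble::tibble(narrative_id = character(), predicted = numeric(),
                          algorithm = character()))
  }
  pool <- pool[order(-pool$predicted, prec[pool$algorithm],
                     pool$narrative_id), , drop = FALSE]
  tibble::as_tibble(pool[1, c("narrative_id", "predicted", "algorithm")])
}

#' Serve one hybrid recommendation for a participant
#'
#' End-to-end serving path: builds per-question streams from the event log,
#' combines each participant-narrative pair's latest answers into a single
#' serving score (hopefulness weighted double), fits the three algorithms on
#' the combined scores, generates the three internal top-n lists over the
#' candidate narratives the participant has not yet requested, and returns
#' the hybrid selection.
#'
#' @param events A validated rating-event tibble.
#' @param catalog Narrative catalog tibble.
#' @param participant_id Participant to serve.
#' @param n Internal list length (default 10).
#' @param at Only narratives with `available_from <= at` are candidates
#'   (default: all).
#' @param blocked Narrative ids the participant has blocked.
#' @param blocked_codes Blocked characteristic codes (see [top_n()]).
#' @param seed Seed for factor-model initialization.
#' @param show_internal Return the three internal lists as an attribute
#'   `"internal_lists"`.
#' @return As [hybrid_select()]; zero rows when the participant has no
#'   ratings or no candidate remains.
#' @export
recommend_narrative <- function(events, catalog, participant_id, n = 10,
                                at = NULL, blocked = character(),
                                blocked_codes = character(), seed = 1L,
                                show_internal = FALSE) {
  streams <- build_streams(events)
  combined <- combine_ratings(events) |>
    build_serving_stream()
  if (!participant_id %in% combined$participant_id) {
    empty <- tibble::tibble(narrative_id = character(), predicted = numeric(),
                            algorithm = character())
    return(empty)
  }
  cand_catalog <- catalog
  if (!is.null(at)) {
    cand_catalog <- dplyr::filter(catalog, .data$available_from <= at)
  }
  seen <- unique(events$narrative_id[events$participant_id == participant_id])
  models <- list(
    knn = fit_knn(combined, catalog),
    svd = fit_svd(combined, seed = seed),
    svdpp = fit_svdpp(combined, seed = seed + 1L)
  )
  lists <- purrr::map(models, top_n, participant_id = participant_id,
                      candidates = cand_catalog$narrative_id, n = n,
                      exclude = c(seen, blocked),
                      blocked_codes = blocked_codes, catalog = catalog)
  out <- hybrid_select(lists)
  if (show_internal) attr(out, "internal_lists") <- lists
  out
}

# Latest-event combined score per (participant, narrative), shaped like a
# stream so the fit_* functions accept it.
build_serving_stream <- function(events_with_combined) {
  events_with_combined |>
    dplyr::mutate(.file_order = dplyr::row_number()) |>
    dplyr::arrange(.data$participant_id, .data$narrative_id,
                   .data$timestamp, .data$.file_order) |>
    dplyr::group_by(.data$participant_id, .data$narrative_id) |>
    dplyr::slice_tail(n = 1) |>
    dplyr::ungroup() |>
    dplyr::transmute(question = "combined", .data$participant_id,
                     .data$narrative_id, value = .data$combined,
                     .data$timestamp)
}
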
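#' Normalized mean absolute error
#'
#' Plain mean absolute error between predicted and true ratings after all
#' streams have been normalized onto the shared 0..3 scale and predictions
#' clipped to it; no square root is taken. Lower is better; 0 is a perfect
#' predictor and 3 the largest attainable error on the clipped scale.
#'
#' @param predicted,actual Paired numeric vectors on the 0..3 scale.
#' @return A single non-negative number.
#' @export
nmae <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual))
  keep <- !is.na(predicted) & !is.na(actual)
  if (!any(keep)) abort("nmae needs at least one predictable pair")
  mean(abs(predicted[keep] - actual[keep]))
}

#' Mean average precision per participant
#'
#' Treats each participant's internal top-n list as the recommendation set
#' and their held-out test ratings as ground truth. A listed narrative is
#' relevant iff it carries a test rating at or above `threshold` (on the
#' normalized 0..3 scale, 1 = "a bit" / "no change"); listed narratives
#' without a test rating count as nonrelevant. Average precision for one list
#' is sum over ranks i of P@i * rel(i), divided by min(R, n) where R is the
#' participant's total number of relevant test narratives. Participants with
#' no test entry are excluded; participants with test entries but no relevant
#' one score 0 by default (`no_relevant = "exclude"` drops them instead).
#'
#' @param lists A named list of top-n tibbles, one per participant
#'   (names are participant ids).
#' @param test_stream A single-question stream tibble of held-out ratings.
#' @param threshold Relevance threshold on the normalized scale (default 1).
#' @param n Nominal list length used in the denominator cap (default 10).
#' @param no_relevant How to score participants with test entries but no
#'   relevant one: `"zero"` (default) or `"exclude"`.
#' @return MAP in [0, 1].
#' @export
map_per_participant <- function(lists, test_stream, threshold = 1, n = 10,
                                no_relevant = c("zero", "exclude")) {
  no_relevant <- match.arg(no_relevant)
  eligible <- intersect(names(lists), unique(test_stream$participant_id))
  if (length(eligible) == 0) abort("no participant owns a test entry")
  aps <- vapply(eligible, function(uid) {
    test_u <- test_stream[test_stream$participant_id == uid, ]
    relevant_items <- test_u$narrative_id[test_u$value >= threshold]
    R <- length(relevant_items)
    if (R == 0) return(if (no_relevant == "zero") 0 else NA_real_)
    lst <- lists[[uid]]
    if (nrow(lst) == 0) return(0)
    rel <- as.integer(lst$narrative_id %in% relevant_items)
    prec_at <- cumsum(rel) / seq_along(rel)
    sum(prec_at * rel) / min(R, n)
  }, numeric(1))
  mean(aps, na.rm = TRUE)
}

#' Intra-list diversity
#'
#' Mean pairwise cosine similarity of the characteristic vectors of the
#' narratives in each list, averaged over lists; permutation-insensitive.
#' Lower values mean more diverse lists; identical items give 1 and pairwise
#' orthogonal items give 0. Lists shorter than 2 carry no pair and are
#' skipped with a warning.
#'
#' @param lists A list of top-n tibbles (only `narrative_id` is used).
#' @param catalog Narrative catalog supplying characteristic vectors.
#' @return Overall ILD in [-1, 1].
#' @export
ild <- function(lists, catalog) {
  sim <- cosine_similarity(one_hot_characteristics(catalog))
  per_list <- vapply(lists, function(lst) {
    ids <- lst$narrative_id
    m <- length(ids)
    if (m < 2) return(NA_real_)
    s <- sim[ids, ids, drop = FALSE]
    sum(s[upper.tri(s)]) / (m * (m - 1) / 2)
  }, numeric(1))
  if (all(is.na(per_list))) abort("every list is shorter than 2; ILD undefined")
  if (anyNA(per_list)) {
    warn(paste0(sum(is.na(per_list)), " list(s) shorter than 2 skipped"))
  }
  mean(per_list, na.rm = TRUE)
}

#' Item space coverage
#'
#' The share of rated narratives that are recommendable: a narrative counts
#' as recommendable if it appears in at least one participant's internal
#' top-n list.
#'
#' @param lists A list of top-n tibbles.
#' @param rated_ids Character vector of narratives with at least one training
#'   rating.
#' @return Coverage in [0, 1].
#' @export
isc <- function(lists, rated_ids) {
  rated_ids <- unique(rated_ids)
  if (length(rated_ids) == 0) abort("rated catalog is empty; ISC undefined")
  listed <- unique(unlist(lapply(lists, function(l) l$narrative_id)))
  length(intersect(listed, rated_ids)) / length(rated_ids)
}

#' Overestimation of unfairness between participant groups
#'
#' For each narrative rated in the test set by both the disadvantaged group g
#' and its complement, the per-group mean overestimation is
#' max(0, mean(predicted) - mean(actual)); the metric is the mean over those
#' narratives of the absolute difference between the two group
#' overestimations. 0 means both groups are overestimated equally (harm from
#' over-promising narratives falls evenly); purely underestimated groups also
#' give 0 because underestimation is clipped away.
#'
#' @param scored A tibble with columns `participant_id`, `narrative_id`,
#'   `predicted`, `actual` over the test entries.
#' @param disadvantaged A tibble with columns `participant_id` and a logical
#'   `disadvantaged` flag covering every scored participant.
#' @return A non-negative number, or `NA` (with a warning) when no narrative
#'   is rated by both groups.
#' @export
overestimation_unfairness <- function(scored, disadvantaged) {
  d <- dplyr::inner_join(scored, disadvantaged, by = "participant_id")
  if (nrow(d) < nrow(scored)) {
    abort("some scored participants have no disadvantaged flag")
  }
  d <- dplyr::filter(d, !is.na(.data$predicted))
  per_item <- d |>
    dplyr::group_by(.data$narrative_id, .data$disadvantaged) |>
    dplyr::summarise(over = max(0, mean(.data$predicted) - mean(.data$actual)),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "disadvantaged", values_from = "over",
                       names_prefix = "g")
  if (all(c("gTRUE", "gFALSE") %in% names(per_item))) {
    per_item <- dplyr::filter(per_item, !is.na(.data$gTRUE),
                              !is.na(.data$gFALSE))
  } else {
    per_item <- per_item[0, , drop = FALSE]
  }
  if (nrow(per_item) == 0) {
    warn("no narrative is rated by both groups; unfairness not computable")
    return(NA_real_)
  }
  mean(abs(per_item$gTRUE - per_item$gFALSE))
}
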
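#' Combine a rating event's answers into one serving score
#'
#' When serving recommendations, the answers of one event are weighted and
#' combined with hopefulness twice as influential as each similarity answer:
#' with normalized hopefulness h and similarity answers s1, s2, the combined
#' value is (2h + s1 + s2) / 4, which stays on the 0..3 scale. Events without
#' an optional block contribute h alone. Evaluation never uses the combined
#' value: each stream is evaluated on its own raw ratings.
#'
#' @param events A validated tibble of rating events (raw -1..2 hopefulness).
#' @return The tibble with a `combined` column on the 0..3 scale.
#' @export
combine_ratings <- function(events) {
  h <- events$hopefulness + 1
  comb <- ifelse(is.na(events$sim_narrator), h,
                 (2 * h + events$sim_narrator + events$sim_narrative) / 4)
  dplyr::mutate(events, combined = comb)
}

#' Fit the content-based item k-nearest-neighbour model
#'
#' An adapted item-based kNN: instead of deriving item-item similarity from
#' co-ratings, similarity is the cosine between the narratives' one-hot
#' encoded characteristic vectors, so narratives cluster into content
#' neighbourhoods. Predictions average the participant's own ratings of the
#' target's nearest rated neighbours.
#'
#' @param stream A single-question stream tibble (`participant_id`,
#'   `narrative_id`, `value`).
#' @param catalog The narrative catalog supplying characteristic vectors.
#' @param k Neighbourhood size (default 40).
#' @return An object of class `knn_model`.
#' @export
fit_knn <- function(stream, catalog, k = 40) {
  stopifnot(nrow(stream) > 0)
  unknown <- setdiff(unique(stream$narrative_id), catalog$narrative_id)
  if (length(unknown) > 0) {
    abort(paste0("stream rates narratives absent from the catalog: ",
                 paste(head(unknown, 3), collapse = ", ")))
  }
  sim <- cosine_similarity(one_hot_characteristics(catalog))
  by_user <- split(stream[c("narrative_id", "value")], stream$participant_id)
  structure(list(
    sim = sim,
    k = k,
    ratings = by_user,
    user_means = vapply(by_user, function(d) mean(d$value), numeric(1)),
    global_mean = mean(stream$value),
    item_ids = rownames(sim)
  ), class = "knn_model")
}

#' Predict ratings with a fitted kNN model
#'
#' For each (participant, narrative) pair the prediction is the
#' similarity-weighted mean of the participant's ratings of the up-to-k most
#' similar rated narratives with strictly positive similarity. With no such
#' neighbour the prediction falls back to the participant's mean rating, then
#' to the global mean. Pairs whose participant has no ratings, or whose
#' narrative is not in the catalog, are unpredictable and yield `NA`.
#' Predictions are clipped to [0, 3].
#'
#' @param object A `knn_model`.
#' @param newdata A tibble with `participant_id` and `narrative_id`.
#' @param ... Unused.
#' @return A numeric vector of predictions (NA where unpredictable).
#' @export
predict.knn_model <- function(object, newdata, ...) {
  out <- rep(NA_real_, nrow(newdata))
  known_item <- newdata$narrative_id %in% object$item_ids
  for (uid in unique(newdata$participant_id)) {
    rated <- object$ratings[[uid]]
    rows <- which(newdata$participant_id == uid & known_item)
    if (length(rows) == 0 || is.null(rated)) next
    items <- newdata$narrative_id[rows]
    s <- object$sim[items, rated$narrative_id, drop = FALSE]
    s[s <= 0] <- 0
    if (ncol(s) > object$k) {
      # keep only the k largest similarities per target item
      s <- t(apply(s, 1, function(row) {
        thresh <- sort(row, decreasing = TRUE)[object$k]
        row[rank(-row, ties.method = "first") > object$k] <- 0
        row
      }))
    }
    wsum <- as.numeric(s %*% rated$value)
    denom <- rowSums(s)
    pred <- ifelse(denom > 0, wsum / denom, object$user_means[[uid]])
    out[rows] <- pred
  }
  # participants unseen in training stay NA; items outside catalog stay NA
  pmin(pmax(out, 0), 3)
}

#' Fit the global-mean baseline
#'
#' Predicts the training-set mean rating for every pair; the reference point
#' the factor models must beat.
#'
#' @param stream A single-question stream tibble.
#' @return An object of class `global_mean_model`.
#' @export
fit_global_mean <- function(stream) {
  stopifnot(nrow(stream) > 0)
  structure(list(global_mean = mean(stream$value),
                 users = unique(stream$participant_id),
                 items = unique(stream$narrative_id)),
            class = "global_mean_model")
}

#' @export
predict.global_mean_model <- function(object, newdata, ...) {
  ok <- newdata$participant_id %in% object$users &
    newdata$narrative_id %in% object$items
  ifelse(ok, pmin(pmax(object$global_mean, 0), 3), NA_real_)
}
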
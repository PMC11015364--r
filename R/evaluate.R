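#' Assign stream entries to cross-validation folds
#'
#' Randomly partitions the (participant, narrative) entries of one stream
#' into `folds` disjoint folds of near-equal size; each fold serves once as
#' the 25% test set while the other three form the 75% training set.
#'
#' @param stream A single-question stream tibble.
#' @param folds Number of folds (default 4).
#' @param seed Integer seed for the shuffle.
#' @return The stream with an integer `fold` column.
#' @export
make_folds <- function(stream, folds = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(stream)
  stream$fold <- sample(rep_len(seq_len(folds), n))
  stream
}

default_hyper <- function() {
  list(
    knn = list(k = 40),
    svd = list(factors = 100, epochs = 20, lr = 0.005, reg = 0.02,
               init_sd = 0.1),
    svdpp = list(factors = 20, epochs = 20, lr = 0.005, reg = 0.02,
                 init_sd = 0.1)
  )
}

fit_algorithm <- function(algorithm, stream, catalog, hyper, seed) {
  h <- hyper[[algorithm]]
  switch(algorithm,
    knn = fit_knn(stream, catalog, k = h$k),
    svd = fit_svd(stream, factors = h$factors, epochs = h$epochs, lr = h$lr,
                  reg = h$reg, init_sd = h$init_sd, seed = seed),
    svdpp = fit_svdpp(stream, factors = h$factors, epochs = h$epochs,
                      lr = h$lr, reg = h$reg, init_sd = h$init_sd,
                      seed = seed),
    global_mean = fit_global_mean(stream),
    abort(paste0("unknown algorithm: ", algorithm))
  )
}

# Internal top-n lists for every training participant over the narratives
# rated in the training stream (seen/blocked narratives are deliberately NOT
# excluded during offline evaluation, mirroring an evaluation that scores the
# prediction stage itself).
internal_lists <- function(model, train_stream, n = 10) {
  users <- unique(train_stream$participant_id)
  cand <- unique(train_stream$narrative_id)
  out <- lapply(users, function(uid) top_n(model, uid, cand, n = n))
  names(out) <- users
  out
}

#' Cross-validated evaluation of the three algorithms
#'
#' Runs the full offline evaluation: per rating stream, the entries are split
#' into `folds` folds; per fold, each algorithm is (re)initialized and fitted
#' on the training 75% (with the cold-start inclusion rule applied: only
#' training participants and narratives are predictable) and scored on the
#' held-out 25% with the prediction-based metrics — NMAE, mean average
#' precision per participant, and overestimation unfairness for the gender
#' and ethnicity partitions. The feature-based metrics (ILD, ISC) use the
#' entire stream as the training set and are computed once per algorithm.
#' Medians and IQRs over folds are reported.
#'
#' @param events A validated rating-event tibble (seed-batch ratings should
#'   already be excluded).
#' @param catalog Narrative catalog tibble.
#' @param participants Participant profile tibble with disadvantaged flags.
#' @param algorithms Algorithms to evaluate (subset of `knn`, `svd`, `svdpp`,
#'   `global_mean`).
#' @param questions Streams to evaluate (subset of `hopefulness`,
#'   `sim_narrator`, `sim_narrative`).
#' @param folds Number of folds (default 4).
#' @param n List length for the feature-based metrics and MAP (default 10).
#' @param seed Integer seed governing fold assignment and model
#'   initialization; the same seed reproduces the report exactly.
#' @param hyper Hyperparameter list as [default_hyper()]; partial overrides
#'   are merged over the defaults.
#' @param metrics Which metrics to compute (default all five; restricting to
#'   `"nmae"` skips list construction and is much faster).
#' @return A `rec_evaluation` object: a list with `$summary` (tibble:
#'   algorithm, question, metric, median, q1, q3, n_folds), `$per_fold`
#'   (tibble of fold-level values) and `$meta`. Supports [tidy()],
#'   [glance()], [autoplot()].
#' @export
cross_validate <- function(events, catalog, participants,
                           algorithms = c("knn", "svd", "svdpp"),
                           questions = STREAM_QUESTIONS,
                           folds = 4, n = 10, seed = 1L, hyper = list(),
                           metrics = c("nmae", "map", "ild", "isc",
                                       "unfairness_gender",
                                       "unfairness_ethnicity")) {
  hyper <- utils::modifyList(default_hyper(), hyper)
  streams <- build_streams(events)
  partitions <- list(
    unfairness_gender = dplyr::select(participants, "participant_id",
                                      disadvantaged = "gender_disadvantaged"),
    unfairness_ethnicity = dplyr::select(participants, "participant_id",
                                         disadvantaged = "ethnicity_disadvantaged")
  )
  per_fold <- list()
  feature_rows <- list()
  for (q in questions) {
    stream <- apply_inclusion_filter(streams[streams$question == q, ])
    if (nrow(stream) == 0) next
    stream <- make_folds(stream, folds = folds, seed = seed)
    for (alg in algorithms) {
      # feature-based metrics: full data as training set, computed once
      if (any(c("ild", "isc") %in% metrics)) {
        full_model <- fit_algorithm(alg, stream, catalog, hyper,
                                    seed = seed * 1000L + 1L)
        lists <- internal_lists(full_model, stream, n = n)
        if ("ild" %in% metrics) {
          feature_rows[[length(feature_rows) + 1]] <- tibble::tibble(
            algorithm = alg, question = q, metric = "ild",
            value = suppressWarnings(ild(lists, catalog)))
        }
        if ("isc" %in% metrics) {
          feature_rows[[length(feature_rows) + 1]] <- tibble::tibble(
            algorithm = alg, question = q, metric = "isc",
            value = isc(lists, unique(stream$narrative_id)))
        }
      }
      pred_metrics <- intersect(c("nmae", "map", "unfairness_gender",
                                  "unfairness_ethnicity"), metrics)
      if (length(pred_metrics) == 0) next
      for (fd in seq_len(folds)) {
        train <- stream[stream$fold != fd, , drop = FALSE]
        test <- stream[stream$fold == fd, , drop = FALSE]
        # cold-start inclusion: only training participants/narratives predictable
        test <- apply_inclusion_filter(test,
                                       participants = unique(train$participant_id),
                                       narratives = unique(train$narrative_id))
        if (nrow(test) == 0 || nrow(train) == 0) {
          warn(paste0("fold ", fd, " of ", q, " has no testable entries; skipped"))
          next
        }
        model <- fit_algorithm(alg, train, catalog, hyper,
                               seed = seed * 1000L + fd)
        pred <- predict(model, test)
        rows <- list()
        if ("nmae" %in% metrics) {
          rows$nmae <- nmae(pred, test$value)
        }
        if ("map" %in% metrics) {
          lists_tr <- internal_lists(model, train, n = n)
          rows$map <- map_per_participant(lists_tr, test, n = n)
        }
        for (um in intersect(c("unfairness_gender", "unfairness_ethnicity"),
                             metrics)) {
          scored <- tibble::tibble(participant_id = test$participant_id,
                                   narrative_id = test$narrative_id,
                                   predicted = pred, actual = test$value)
          rows[[um]] <- suppressWarnings(
            overestimation_unfairness(scored, partitions[[um]]))
        }
        per_fold[[length(per_fold) + 1]] <- tibble::tibble(
          algorithm = alg, question = q, fold = fd,
          metric = names(rows), value = unlist(rows))
      }
    }
  }
  per_fold <- dplyr::bind_rows(per_fold)
  if (nrow(per_fold) == 0) {
    per_fold <- tibble::tibble(algorithm = character(), question = character(),
                               fold = integer(), metric = character(),
                               value = numeric())
  }
  summary <- per_fold |>
    dplyr::group_by(.data$algorithm, .data$question, .data$metric) |>
    dplyr::summarise(median = median(.data$value, na.rm = TRUE),
                     q1 = quantile(.data$value, 0.25, na.rm = TRUE,
                                   names = FALSE),
                     q3 = quantile(.data$value, 0.75, na.rm = TRUE,
                                   names = FALSE),
                     n_folds = sum(!is.na(.data$value)), .groups = "drop")
  if (length(feature_rows) > 0) {
    feats <- dplyr::bind_rows(feature_rows) |>
      dplyr::transmute(.data$algorithm, .data$question, .data$metric,
                       median = .data$value, q1 = .data$value,
                       q3 = .data$value, n_folds = 1L)
    summary <- dplyr::bind_rows(summary, feats)
  }
  summary <- dplyr::arrange(summary,
                            match(.data$algorithm, c("knn", "svd", "svdpp",
                                                     "global_mean")),
                            match(.data$question, STREAM_QUESTIONS),
                            .data$metric)
  structure(list(
    summary = summary,
    per_fold = per_fold,
    meta = list(seed = seed, folds = folds, split = (folds - 1) / folds,
                n_events = nrow(events), n_list = n,
                algorithms = algorithms, questions = questions,
                fingerprint = dataset_fingerprint(events))
  ), class = "rec_evaluation")
}

dataset_fingerprint <- function(events) {
  paste0("n", nrow(events), "-p", length(unique(events$participant_id)),
         "-i", length(unique(events$narrative_id)))
}

#' @export
print.rec_evaluation <- function(x, ...) {
  cat("Cross-validated recommender evaluation (", x$meta$folds, " folds, seed ",
      x$meta$seed, ", ", x$meta$n_events, " events)\n", sep = "")
  print(x$summary, n = Inf)
  invisible(x)
}

#' @describeIn cross_validate Fold-level metric values as a tidy tibble.
#' @param x A `rec_evaluation` object.
#' @param ... Unused.
#' @export
tidy.rec_evaluation <- function(x, ...) x$per_fold

#' @describeIn cross_validate One-row run summary (seed, folds, sizes).
#' @export
glance.rec_evaluation <- function(x, ...) {
  tibble::tibble(seed = x$meta$seed, folds = x$meta$folds,
                 split = x$meta$split, n_events = x$meta$n_events,
                 n_algorithms = length(x$meta$algorithms),
                 n_questions = length(x$meta$questions),
                 fingerprint = x$meta$fingerprint)
}

#' @describeIn cross_validate Dot-and-whisker plot of medians and IQRs per
#'   algorithm, faceted by metric and stream.
#' @param object A `rec_evaluation` object.
#' @export
autoplot.rec_evaluation <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$algorithm, y = .data$median,
                               colour = .data$algorithm)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q1, ymax = .data$q3)) +
    ggplot2::facet_grid(metric ~ question, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "median (IQR over folds)") +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "none")
}

#' Write an evaluation report to JSON and CSV
#'
#' @param report A `rec_evaluation` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_evaluation_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$summary, file.path(dir, "evaluation_summary.csv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(meta = report$meta, summary = report$summary,
         per_fold = report$per_fold),
    file.path(dir, "evaluation_report.json"),
    digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Prediction accuracy over time
#'
#' Re-runs the cross-validated NMAE on growing prefixes of the event log: for
#' each month in the grid, events strictly before the first day of that month
#' form the dataset. Months whose hopeful stream has fewer than `min_ratings`
#' entries are skipped with a warning. The default grid spans June 2020 to
#' July 2022, the observation window of the trials the package emulates.
#'
#' @param events A validated rating-event tibble.
#' @param catalog,participants As in [cross_validate()].
#' @param month_grid A `Date` vector of month starts (default
#'   `timeline_month_grid()`).
#' @param algorithms Algorithms to track (default `"svd"`).
#' @param question Stream to track (default hopefulness).
#' @param folds,seed,hyper As in [cross_validate()].
#' @param min_ratings Minimum stream size for a month to be evaluated
#'   (default 20).
#' @return A tibble (month, algorithm, nmae_median, q1, q3, n_ratings).
#' @export
accuracy_timeline <- function(events, catalog, participants,
                              month_grid = timeline_month_grid(),
                              algorithms = "svd",
                              question = "hopefulness",
                              folds = 4, seed = 1L, hyper = list(),
                              min_ratings = 20) {
  if (length(month_grid) == 0) abort("month grid is empty")
  month_grid <- sort(as.Date(month_grid))
  out <- list()
  for (m in seq_along(month_grid)) {
    cutoff <- as.POSIXct(month_grid[m], tz = "UTC")
    prefix <- events[events$timestamp < cutoff, , drop = FALSE]
    stream_n <- nrow(build_streams(prefix) |>
                       dplyr::filter(.data$question == .env$question))
    if (stream_n < min_ratings) {
      warn(paste0("month ", format(month_grid[m]), ": only ", stream_n,
                  " ratings; skipped"))
      next
    }
    # a constant seed means two months with identical prefixes report
    # identical values: the series stabilizes once the log stops growing
    cv <- cross_validate(prefix, catalog, participants,
                         algorithms = algorithms, questions = question,
                         folds = folds, seed = seed, hyper = hyper,
                         metrics = "nmae")
    out[[length(out) + 1]] <- cv$summary |>
      dplyr::transmute(month = month_grid[m], .data$algorithm,
                       nmae_median = .data$median, .data$q1, .data$q3,
                       n_ratings = stream_n)
  }
  dplyr::bind_rows(out)
}

#' Month grid spanning the emulated observation window
#'
#' @param from,to First and last month starts (defaults June 2020 and
#'   July 2022).
#' @return A `Date` vector of month starts.
#' @export
timeline_month_grid <- function(from = as.Date("2020-06-01"),
                                to = as.Date("2022-07-01")) {
  seq(from, to, by = "month")
}
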
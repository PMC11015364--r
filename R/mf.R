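#' Fit a biased matrix-factorization model (SVD) by SGD
#'
#' Learns the rating model r_hat(u,i) = mu + b_u + b_i + q_i' p_u by
#' per-observation stochastic gradient descent with L2 shrinkage on all
#' learned terms. Factors and biases are initialized from a normal
#' distribution (biases at zero), so two fits with the same seed produce
#' identical models.
#'
#' @param stream A single-question stream tibble (`participant_id`,
#'   `narrative_id`, `value` on 0..3).
#' @param factors Latent dimension f (default 100).
#' @param epochs Training epochs (default 20).
#' @param lr SGD learning rate gamma (default 0.005).
#' @param reg L2 regularization lambda (default 0.02).
#' @param init_sd Standard deviation of the normal initialization (default 0.1).
#' @param seed Optional integer seed consumed just before initialization.
#' @return An object of class `factor_model`.
#' @export
fit_svd <- function(stream, factors = 100, epochs = 20, lr = 0.005,
                    reg = 0.02, init_sd = 0.1, seed = NULL) {
  dat <- prepare_mf_data(stream, seed)
  P <- matrix(rnorm(dat$n_users * factors, 0, init_sd), dat$n_users, factors)
  Q <- matrix(rnorm(dat$n_items * factors, 0, init_sd), dat$n_items, factors)
  fit <- sgd_svd_cpp(dat$u, dat$i, dat$r, dat$mu,
                     numeric(dat$n_users), numeric(dat$n_items),
                     P, Q, epochs, lr, reg)
  new_factor_model("svd", dat, fit,
                   list(factors = factors, epochs = epochs, lr = lr,
                        reg = reg, init_sd = init_sd, seed = seed))
}

#' Fit an SVD++ model by SGD
#'
#' Extends [fit_svd()] with an implicit-feedback term: the user factor is
#' augmented by the normalized sum of item factors y_j over the set I_u of
#' items the user rated in training, r_hat = mu + b_u + b_i +
#' q_i'(p_u + |I_u|^(-1/2) sum y_j). Which items a user chose to rate is
#' itself a signal, independent of the rating values.
#'
#' @inheritParams fit_svd
#' @param factors Latent dimension f (default 20).
#' @return An object of class `factor_model`.
#' @export
fit_svdpp <- function(stream, factors = 20, epochs = 20, lr = 0.005,
                      reg = 0.02, init_sd = 0.1, seed = NULL) {
  dat <- prepare_mf_data(stream, seed)
  P <- matrix(rnorm(dat$n_users * factors, 0, init_sd), dat$n_users, factors)
  Q <- matrix(rnorm(dat$n_items * factors, 0, init_sd), dat$n_items, factors)
  Y <- matrix(rnorm(dat$n_items * factors, 0, init_sd), dat$n_items, factors)
  Iu <- lapply(split(dat$i, factor(dat$u, levels = 0:(dat$n_users - 1))),
               as.integer)
  fit <- sgd_svdpp_cpp(dat$u, dat$i, dat$r, dat$mu,
                       numeric(dat$n_users), numeric(dat$n_items),
                       P, Q, Y, unname(Iu), epochs, lr, reg)
  model <- new_factor_model("svdpp", dat, fit,
                            list(factors = factors, epochs = epochs, lr = lr,
                                 reg = reg, init_sd = init_sd, seed = seed))
  model$Y <- fit$Y
  model$Iu <- unname(Iu)
  model
}

prepare_mf_data <- function(stream, seed) {
  if (nrow(stream) == 0) abort("cannot fit a factor model on an empty stream")
  if (!is.null(seed)) set.seed(seed)
  users <- sort(unique(stream$participant_id))
  items <- sort(unique(stream$narrative_id))
  list(
    u = match(stream$participant_id, users) - 1L,
    i = match(stream$narrative_id, items) - 1L,
    r = as.numeric(stream$value),
    mu = mean(stream$value),
    users = users, items = items,
    n_users = length(users), n_items = length(items)
  )
}

new_factor_model <- function(algorithm, dat, fit, hyper) {
  structure(list(
    algorithm = algorithm,
    mu = dat$mu,
    bu = fit$bu, bi = fit$bi,
    P = fit$P, Q = fit$Q,
    users = dat$users, items = dat$items,
    hyper = hyper
  ), class = "factor_model")
}

#' Predict ratings with a fitted factor model
#'
#' Pairs whose participant or narrative was unseen in training are
#' unpredictable and yield `NA`; predictions are clipped to [0, 3].
#'
#' @param object A `factor_model` from [fit_svd()] or [fit_svdpp()].
#' @param newdata A tibble with `participant_id` and `narrative_id`.
#' @param ... Unused.
#' @return A numeric vector of predictions (NA where unpredictable).
#' @export
predict.factor_model <- function(object, newdata, ...) {
  u <- match(newdata$participant_id, object$users)
  i <- match(newdata$narrative_id, object$items)
  ok <- !is.na(u) & !is.na(i)
  out <- rep(NA_real_, nrow(newdata))
  if (any(ok)) {
    uu <- u[ok]; ii <- i[ok]
    user_vec <- object$P[uu, , drop = FALSE]
    if (object$algorithm == "svdpp") {
      impl <- t(vapply(uu, function(x) {
        idx <- object$Iu[[x]] + 1L
        colSums(object$Y[idx, , drop = FALSE]) / sqrt(length(idx))
      }, numeric(ncol(object$P))))
      user_vec <- user_vec + impl
    }
    dots <- rowSums(user_vec * object$Q[ii, , drop = FALSE])
    out[ok] <- object$mu + object$bu[uu] + object$bi[ii] + dots
  }
  pmin(pmax(out, 0), 3)
}

#' Serialize a fitted model to JSON
#'
#' Writes the learned parameters (biases, factors, similarity values) so a
#' fitted model can be archived alongside an evaluation report.
#'
#' @param model A `factor_model`, `knn_model`, or `global_mean_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  payload <- unclass(model)
  payload$class <- class(model)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}
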
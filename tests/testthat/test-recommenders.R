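test_that("rating combination weights hopefulness double and keeps the scale", {
  ev <- make_events("p1", c("n1", "n2", "n3"), c(2, -1, 1),
                    sim_narrator = c(NA, 0, 1),
                    sim_narrative = c(NA, 0, 3),
                    learning = c(NA, 0, 0), empathy = c(NA, 0, 0))
  got <- combine_ratings(ev)$combined
  expect_equal(got[1], 3)            # no optional block -> normalized h
  expect_equal(got[2], 0)            # all-zero answers
  expect_equal(got[3], (2 * 2 + 1 + 3) / 4)  # 2:1:1 weighting
  expect_true(all(got >= 0 & got <= 3))
})

test_that("content kNN similarity equals brute-force cosine of one-hot vectors", {
  cat3 <- make_catalog(matrix(c(1, 1, 2,
                                1, 1, 2,
                                2, 2, 1), nrow = 3, ncol = 3))
  s <- make_stream("p1", "n01", 2)
  m <- fit_knn(s, cat3)
  oh <- oracle_onehot(cat3)
  for (a in 1:3) for (b in 1:3) {
    expect_equal(m$sim[a, b], oracle_cosine(oh[a, ], oh[b, ]),
                 tolerance = 1e-12)
  }
  expect_equal(m$sim[1, 2], 1)  # identical characteristics
  expect_equal(m$sim[1, 3], 0)  # disjoint categories
})

test_that("kNN predictions follow the weighted-mean contract with fallbacks", {
  # single identical neighbour -> the rating itself
  cat2 <- make_catalog(matrix(c(1, 1, 2, 2), nrow = 2))
  m <- fit_knn(make_stream("p1", "n01", 2), cat2)
  p <- predict(m, tibble::tibble(participant_id = "p1", narrative_id = "n02"))
  expect_equal(p, 2)

  # two neighbours with sims (1, 0.5) and ratings (3, 0) -> 3/1.5 = 2
  cat4 <- make_catalog(matrix(c(1, 1, 1, 1,
                                1, 1, 1, 1,
                                1, 1, 2, 2), nrow = 3, byrow = TRUE,
                              ncol = 4))
  oh <- oracle_onehot(cat4)
  expect_equal(oracle_cosine(oh[1, ], oh[3, ]), 0.5)
  m <- fit_knn(make_stream("p1", c("n02", "n03"), c(3, 0)), cat4)
  p <- predict(m, tibble::tibble(participant_id = "p1", narrative_id = "n01"))
  expect_equal(p, 2)

  # no positively similar rated neighbour -> participant mean
  cat_disjoint <- make_catalog(matrix(c(1, 1,
                                        2, 2), nrow = 2, ncol = 2))
  m <- fit_knn(make_stream("p1", "n01", c(1)), cat_disjoint)
  p <- predict(m, tibble::tibble(participant_id = "p1", narrative_id = "n02"))
  expect_equal(p, 1)

  # unknown participant -> unpredictable
  p <- predict(m, tibble::tibble(participant_id = "p9", narrative_id = "n02"))
  expect_true(is.na(p))
})

test_that("kNN agrees with the brute-force oracle on random small instances", {
  set.seed(99)
  for (rep in 1:10) {
    cat5 <- random_catalog(5)
    n_r <- sample(3:8, 1)
    stream <- make_stream(sample(sprintf("u%d", 1:5), n_r, replace = TRUE),
                          sample(cat5$narrative_id, n_r, replace = TRUE),
                          sample(0:3, n_r, replace = TRUE))
    stream <- dplyr::distinct(stream, participant_id, narrative_id,
                              .keep_all = TRUE)
    m <- fit_knn(stream, cat5, k = 3)
    for (uid in unique(stream$participant_id)) {
      for (iid in cat5$narrative_id) {
        got <- predict(m, tibble::tibble(participant_id = uid,
                                         narrative_id = iid))
        want <- oracle_knn_predict(stream, cat5, uid, iid, k = 3)
        expect_equal(got, want, tolerance = 1e-9)
      }
    }
  }
})

test_that("factor-model SGD matches the recurrence replayed in plain R", {
  set.seed(5)
  stream <- make_stream(c("a", "a", "b", "b", "c"),
                        c("x", "y", "x", "z", "y"),
                        c(3, 1, 2, 0, 2))
  for (fitter in list(
    list(fit = fit_svd, f = 3, oracle = "svd"),
    list(fit = fit_svdpp, f = 3, oracle = "svdpp"))) {
    m <- fitter$fit(stream, factors = fitter$f, epochs = 4, lr = 0.01,
                    reg = 0.05, init_sd = 0.1, seed = 21)
    # replay initialization with the same seed and run the plain-R recurrence
    set.seed(21)
    n_u <- 3; n_i <- 3
    P <- matrix(rnorm(n_u * fitter$f, 0, 0.1), n_u, fitter$f)
    Q <- matrix(rnorm(n_i * fitter$f, 0, 0.1), n_i, fitter$f)
    u <- match(stream$participant_id, sort(unique(stream$participant_id)))
    i <- match(stream$narrative_id, sort(unique(stream$narrative_id)))
    mu <- mean(stream$value)
    if (fitter$oracle == "svd") {
      ref <- oracle_sgd_svd(u, i, stream$value, mu, P, Q, 4, 0.01, 0.05)
    } else {
      Y <- matrix(rnorm(n_i * fitter$f, 0, 0.1), n_i, fitter$f)
      Iu <- split(i, u)
      ref <- oracle_sgd_svdpp(u, i, stream$value, mu, P, Q, Y, Iu,
                              4, 0.01, 0.05)
    }
    expect_equal(m$bu, ref$bu, tolerance = 1e-12)
    expect_equal(m$bi, ref$bi, tolerance = 1e-12)
    expect_equal(m$P, ref$P, tolerance = 1e-12)
    expect_equal(m$Q, ref$Q, tolerance = 1e-12)
  }
})

test_that("factor models fit constant and single-observation data sensibly", {
  const <- make_stream(sprintf("u%d", 1:4), rep("n1", 4), rep(2, 4))
  m <- fit_svd(const, factors = 5, seed = 1)
  p <- predict(m, tibble::tibble(participant_id = "u1", narrative_id = "n1"))
  expect_equal(p, 2, tolerance = 0.05)

  one <- make_stream("u1", "n1", 3)
  for (f in list(fit_svd, fit_svdpp)) {
    m <- f(one, seed = 2)
    p <- predict(m, tibble::tibble(participant_id = "u1",
                                   narrative_id = "n1"))
    expect_equal(p, 3, tolerance = 0.1)
  }
  expect_error(fit_svd(one[0, ]), "empty")
})

test_that("identical seeds reproduce identical factor models", {
  set.seed(7)
  stream <- make_stream(sample(sprintf("u%d", 1:10), 40, replace = TRUE),
                        sample(sprintf("n%d", 1:12), 40, replace = TRUE),
                        sample(0:3, 40, replace = TRUE)) |>
    dplyr::distinct(participant_id, narrative_id, .keep_all = TRUE)
  pairs <- tibble::tibble(participant_id = stream$participant_id,
                          narrative_id = stream$narrative_id)
  for (f in list(fit_svd, fit_svdpp)) {
    m1 <- f(stream, factors = 8, seed = 33)
    m2 <- f(stream, factors = 8, seed = 33)
    expect_identical(predict(m1, pairs), predict(m2, pairs))
  }
})

test_that("SVD recovers a noiseless rank-1 rating matrix", {
  set.seed(11)
  n_u <- 20; n_i <- 15
  pu <- runif(n_u, 0.5, 1.5); qi <- runif(n_i, 0.5, 1.5)
  full <- outer(pu, qi)
  full <- 3 * (full - min(full)) / diff(range(full))  # onto 0..3
  obs <- which(matrix(runif(n_u * n_i), n_u, n_i) < 0.8)
  idx <- arrayInd(obs, c(n_u, n_i))
  stream <- make_stream(sprintf("u%02d", idx[, 1]), sprintf("n%02d", idx[, 2]),
                        full[obs])
  held <- setdiff(seq_len(n_u * n_i), obs)
  hidx <- arrayInd(held, c(n_u, n_i))
  m <- fit_svd(stream, factors = 20, epochs = 60, lr = 0.01, seed = 3)
  pred <- predict(m, tibble::tibble(participant_id = sprintf("u%02d", hidx[, 1]),
                                    narrative_id = sprintf("n%02d", hidx[, 2])))
  keep <- !is.na(pred)
  expect_lt(mean(abs(pred[keep] - full[held][keep])), 0.3)
})

test_that("predictions always land in [0, 3]", {
  set.seed(13)
  stream <- make_stream(sample(sprintf("u%d", 1:6), 30, replace = TRUE),
                        sample(sprintf("n%d", 1:8), 30, replace = TRUE),
                        sample(c(0, 3), 30, replace = TRUE)) |>
    dplyr::distinct(participant_id, narrative_id, .keep_all = TRUE)
  cat8 <- random_catalog(8)
  names(cat8)[1] <- "narrative_id"
  cat8$narrative_id <- sprintf("n%d", 1:8)
  pairs <- expand.grid(participant_id = sprintf("u%d", 1:6),
                       narrative_id = sprintf("n%d", 1:8),
                       stringsAsFactors = FALSE)
  for (m in list(fit_svd(stream, seed = 4), fit_svdpp(stream, seed = 4),
                 fit_knn(stream, cat8), fit_global_mean(stream))) {
    p <- predict(m, pairs)
    expect_true(all(is.na(p) | (p >= 0 & p <= 3)))
  }
})

test_that("top-n ranks, breaks ties by id, and respects exclusions", {
  stream <- make_stream("u1", c("n1", "n2", "n3"), c(3, 1, 2))
  m <- fit_global_mean(stream)
  # global-mean model ties every candidate -> pure id ordering
  got <- top_n(m, "u1", c("n3", "n1", "n2"), n = 2)
  expect_equal(got$narrative_id, c("n1", "n2"))

  # distinct predictions sort descending (kNN toy)
  cat3 <- make_catalog(matrix(c(1, 1, 2,
                                1, 2, 2,
                                1, 1, 2), nrow = 3, ncol = 3))
  mk <- fit_knn(make_stream("u1", c("n01", "n02"), c(3, 0)), cat3)
  got <- top_n(mk, "u1", cat3$narrative_id, exclude = c("n01", "n02"))
  expect_equal(got$narrative_id, "n03")

  # everything already requested -> empty list
  got <- top_n(m, "u1", c("n1", "n2"), exclude = c("n1", "n2"))
  expect_equal(nrow(got), 0)
})

test_that("hybrid selection takes the argmax of 30 with deterministic ties", {
  lst <- function(ids, preds) tibble::tibble(narrative_id = ids,
                                             predicted = preds)
  pick <- hybrid_select(list(knn = lst("n5", 2.5),
                             svd = lst(c("n1", "n2"), c(2.9, 2.0)),
                             svdpp = lst("n3", 2.7)))
  expect_equal(pick$narrative_id, "n1")
  expect_equal(pick$algorithm, "svd")

  pick <- hybrid_select(list(knn = lst("n5", 2.95),
                             svd = lst("n1", 2.9)))
  expect_equal(pick$algorithm, "knn")  # content holds the strict max

  pick <- hybrid_select(list(knn = lst("n5", 2.9), svd = lst("n1", 2.9)))
  expect_equal(pick$algorithm, "svd")  # exact tie -> collaborative first

  none <- hybrid_select(list(knn = lst(character(), numeric())))
  expect_equal(nrow(none), 0)
})

test_that("the served recommendation is drawn from the lists and never seen", {
  set.seed(17)
  cat10 <- random_catalog(10)
  ev <- make_events(rep(sprintf("p%d", 1:5), each = 4),
                    sample(cat10$narrative_id, 20, replace = TRUE),
                    sample(-1:2, 20, replace = TRUE))
  ev <- dplyr::distinct(ev, participant_id, narrative_id, .keep_all = TRUE)
  rec <- recommend_narrative(ev, cat10, "p1", seed = 5, show_internal = TRUE)
  seen <- ev$narrative_id[ev$participant_id == "p1"]
  if (nrow(rec) > 0) {
    expect_false(rec$narrative_id %in% seen)
    pool <- dplyr::bind_rows(attr(rec, "internal_lists"))
    expect_true(rec$narrative_id %in% pool$narrative_id)
  }
  # participant with no ratings -> no recommendation
  none <- recommend_narrative(ev, cat10, "p99", seed = 5)
  expect_equal(nrow(none), 0)
})
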
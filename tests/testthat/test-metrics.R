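test_that("nmae is the plain mean absolute error on the shared scale", {
  expect_equal(nmae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(nmae(c(3, 0), c(0, 3)), 3)
  expect_equal(nmae(c(1, 2, 2), c(0, 2, 3)), 2 / 3)
  expect_error(nmae(NA_real_, 1), "predictable")
})

test_that("mean average precision follows the capped-denominator contract", {
  lst <- function(ids) tibble::tibble(narrative_id = ids,
                                      predicted = rev(seq_along(ids)))
  test_s <- make_stream("u1", c("a", "b", "c"), c(2, 0, 3))
  # all listed items relevant
  expect_equal(map_per_participant(list(u1 = lst(c("a", "c"))), test_s), 1)
  # no listed item relevant
  expect_equal(map_per_participant(list(u1 = lst(c("b"))), test_s), 0)
  # relevance pattern (1,0,1) with 2 relevant test items
  got <- map_per_participant(list(u1 = lst(c("a", "b", "c"))), test_s)
  expect_equal(got, (1 / 1 + 2 / 3) / 2)
  # unrated listed items are nonrelevant
  got <- map_per_participant(list(u1 = lst(c("z", "a"))), test_s)
  expect_equal(got, (1 / 2) / 2)
  # participants lacking any relevant test item: zero-scored vs excluded
  test2 <- dplyr::bind_rows(test_s, make_stream("u2", "a", 0))
  lists2 <- list(u1 = lst(c("a", "c")), u2 = lst("a"))
  expect_equal(map_per_participant(lists2, test2), 0.5)
  expect_equal(map_per_participant(lists2, test2, no_relevant = "exclude"), 1)
})

test_that("intra-list diversity hits its analytic limits", {
  same <- make_catalog(matrix(1, nrow = 3, ncol = 3))
  l3 <- list(tibble::tibble(narrative_id = c("n01", "n02", "n03"),
                            predicted = 1:3))
  expect_equal(ild(l3, same), 1)

  # pairwise-orthogonal one-hots: distinct categories everywhere
  ortho <- make_catalog(matrix(c(1, 2, 3,
                                 1, 2, 3,
                                 1, 2, 3), nrow = 3, ncol = 3))
  expect_equal(ild(l3, ortho), 0)

  # pairwise cosines (1, 0, 0) -> 1/3
  mixed <- make_catalog(matrix(c(1, 1, 2,
                                 1, 1, 2,
                                 1, 1, 2), nrow = 3, ncol = 3))
  expect_equal(ild(l3, mixed), 1 / 3)
  expect_error(ild(list(l3[[1]][1, ]), same), "shorter than 2")
})

test_that("item space coverage counts listed rated narratives", {
  lists <- list(tibble::tibble(narrative_id = c("a", "b"), predicted = 1:2),
                tibble::tibble(narrative_id = "c", predicted = 3))
  expect_equal(isc(lists, c("a", "b", "c", "d")), 0.75)
  expect_equal(isc(lists, c("a", "b", "c")), 1)
  expect_equal(isc(list(), c("a", "b")), 0)
  expect_error(isc(lists, character()), "empty")
})

test_that("overestimation unfairness clips underestimation and balances groups", {
  flags <- tibble::tibble(participant_id = c("g1", "g2", "h1", "h2"),
                          disadvantaged = c(TRUE, TRUE, FALSE, FALSE))
  base <- tidyr::expand_grid(participant_id = flags$participant_id,
                             narrative_id = c("a", "b"))
  # identical predictions and truths -> 0
  s <- dplyr::mutate(base, predicted = 2, actual = 2)
  expect_equal(overestimation_unfairness(s, flags), 0)
  # disadvantaged overestimated by exactly 1, complement exact -> 1
  s <- dplyr::mutate(base, actual = 1,
                     predicted = ifelse(participant_id %in% c("g1", "g2"),
                                        2, 1))
  expect_equal(overestimation_unfairness(s, flags), 1)
  # both groups only underestimated -> 0
  s <- dplyr::mutate(base, actual = 3,
                     predicted = ifelse(participant_id %in% c("g1", "g2"),
                                        1, 2))
  expect_equal(overestimation_unfairness(s, flags), 0)
  # no item rated by both groups -> NA with warning
  s <- dplyr::mutate(base[base$participant_id %in% c("g1", "g2"), ],
                     predicted = 2, actual = 1)
  expect_warning(got <- overestimation_unfairness(s, flags), "not computable")
  expect_true(is.na(got))
})

test_that("unfairness is symmetric in the partition and ignores one-group items", {
  set.seed(31)
  for (rep in 1:10) {
    inst <- random_metric_instance()
    u1 <- suppressWarnings(
      overestimation_unfairness(inst$scored, inst$disadvantaged))
    flipped <- dplyr::mutate(inst$disadvantaged,
                             disadvantaged = !disadvantaged)
    u2 <- suppressWarnings(overestimation_unfairness(inst$scored, flipped))
    expect_equal(u1, u2)
    # add an item rated by a single group only: metric unchanged
    if (!is.na(u1) && any(inst$disadvantaged$disadvantaged)) {
      uid <- inst$disadvantaged$participant_id[
        inst$disadvantaged$disadvantaged][1]
      extra <- tibble::tibble(participant_id = uid, narrative_id = "zz_solo",
                              predicted = 3, actual = 0)
      u3 <- suppressWarnings(overestimation_unfairness(
        dplyr::bind_rows(inst$scored, extra), inst$disadvantaged))
      expect_equal(u1, u3)
    }
  }
})

test_that("all five metrics match brute-force oracles on random instances", {
  set.seed(202)
  for (rep in 1:15) {
    inst <- random_metric_instance()
    expect_equal(nmae(inst$scored$predicted, inst$scored$actual),
                 oracle_nmae(inst$scored$predicted, inst$scored$actual),
                 tolerance = 1e-9)
    if (length(intersect(names(inst$lists),
                         unique(inst$test$participant_id))) > 0) {
      expect_equal(map_per_participant(inst$lists, inst$test),
                   oracle_map(inst$lists, inst$test), tolerance = 1e-9)
    }
    expect_equal(suppressWarnings(ild(inst$lists, inst$catalog)),
                 oracle_ild(inst$lists, inst$catalog), tolerance = 1e-9)
    expect_equal(isc(inst$lists, inst$items),
                 oracle_isc(inst$lists, inst$items), tolerance = 1e-9)
    expect_equal(
      suppressWarnings(overestimation_unfairness(inst$scored,
                                                 inst$disadvantaged)),
      oracle_uover(inst$scored, inst$disadvantaged), tolerance = 1e-9)
  }
})

test_that("metric values stay inside their documented scales", {
  set.seed(303)
  for (rep in 1:10) {
    inst <- random_metric_instance()
    expect_gte(nmae(inst$scored$predicted, inst$scored$actual), 0)
    m <- map_per_participant(inst$lists, inst$test)
    expect_true(m >= 0 && m <= 1)
    d <- suppressWarnings(ild(inst$lists, inst$catalog))
    expect_true(d >= -1 && d <= 1)
    cov <- isc(inst$lists, inst$items)
    expect_true(cov >= 0 && cov <= 1)
    u <- suppressWarnings(overestimation_unfairness(inst$scored,
                                                    inst$disadvantaged))
    expect_true(is.na(u) || u >= 0)
  }
})

test_that("coverage is monotone nondecreasing in the list length", {
  set.seed(404)
  stream <- make_stream(sample(sprintf("u%d", 1:8), 40, replace = TRUE),
                        sample(sprintf("n%02d", 1:12), 40, replace = TRUE),
                        sample(0:3, 40, replace = TRUE)) |>
    dplyr::distinct(participant_id, narrative_id, .keep_all = TRUE)
  cat12 <- random_catalog(12)
  m <- fit_knn(stream, cat12)
  prev <- 0
  for (n in c(1, 3, 5, 10)) {
    lists <- lapply(unique(stream$participant_id), function(u)
      top_n(m, u, cat12$narrative_id, n = n))
    cov <- isc(lists, unique(stream$narrative_id))
    expect_gte(cov, prev)
    prev <- cov
  }
})
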
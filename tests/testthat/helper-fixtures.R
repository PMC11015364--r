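# In-code fixture builders shared across the suite.

make_events <- function(participant_id, narrative_id, hopefulness,
                        sim_narrator = NA_integer_,
                        sim_narrative = NA_integer_,
                        learning = NA_integer_, empathy = NA_integer_,
                        timestamp = NULL, source = NA_character_) {
  n <- length(hopefulness)
  if (is.null(timestamp)) {
    timestamp <- as.POSIXct("2021-01-01", tz = "UTC") + 3600 * seq_len(n)
  }
  tibble::tibble(
    participant_id = rep_len(participant_id, n),
    narrative_id = rep_len(narrative_id, n),
    timestamp = timestamp,
    hopefulness = as.integer(hopefulness),
    sim_narrator = as.integer(rep_len(sim_narrator, n)),
    sim_narrative = as.integer(rep_len(sim_narrative, n)),
    learning = as.integer(rep_len(learning, n)),
    empathy = as.integer(rep_len(empathy, n)),
    source = rep_len(source, n)
  )
}

# toy catalog with explicit characteristic codes; rows = narratives
make_catalog <- function(codes, available_from = as.Date("2020-01-01")) {
  d <- ncol(codes)
  out <- tibble::tibble(
    narrative_id = rownames(codes) %||% sprintf("n%02d", seq_len(nrow(codes))),
    available_from = rep_len(available_from, nrow(codes))
  )
  for (j in seq_len(d)) out[[paste0("c", j)]] <- as.character(codes[, j])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_participants <- function(ids, gender = "female",
                              ethnicity = "white_british") {
  narrarec::add_group_flags(tibble::tibble(
    participant_id = ids,
    gender = rep_len(gender, length(ids)),
    ethnicity = rep_len(ethnicity, length(ids)),
    enrolled_on = as.Date("2020-03-01")
  ))
}

make_stream <- function(participant_id, narrative_id, value,
                        question = "hopefulness") {
  tibble::tibble(
    question = question,
    participant_id = participant_id,
    narrative_id = narrative_id,
    value = value,
    timestamp = as.POSIXct("2021-01-01", tz = "UTC") + seq_along(value)
  )
}

# a small random catalog of n items with d characteristics, 2..3 categories
random_catalog <- function(n, d = 4) {
  codes <- matrix(sample(1:3, n * d, replace = TRUE), n, d)
  rownames(codes) <- sprintf("n%02d", seq_len(n))
  make_catalog(codes)
}

# a random metric-test instance: <=10 participants x 10 items with top lists,
# predictions and truths
random_metric_instance <- function() {
  n_u <- sample(2:10, 1)
  n_i <- sample(4:10, 1)
  users <- sprintf("u%02d", seq_len(n_u))
  items <- sprintf("n%02d", seq_len(n_i))
  lists <- lapply(users, function(u) {
    len <- sample(2:min(10, n_i), 1)
    tibble::tibble(narrative_id = sample(items, len),
                   predicted = round(runif(len, 0, 3), 3))
  })
  names(lists) <- users
  pairs <- expand.grid(participant_id = users, narrative_id = items,
                       stringsAsFactors = FALSE)
  keep <- runif(nrow(pairs)) < 0.45
  test <- tibble::tibble(
    question = "hopefulness",
    participant_id = pairs$participant_id[keep],
    narrative_id = pairs$narrative_id[keep],
    value = sample(0:3, sum(keep), replace = TRUE),
    timestamp = as.POSIXct("2021-06-01", tz = "UTC") + seq_len(sum(keep))
  )
  scored <- dplyr::mutate(test, predicted = round(runif(dplyr::n(), 0, 3), 3),
                          actual = value)
  disadvantaged <- tibble::tibble(
    participant_id = users,
    disadvantaged = sample(c(TRUE, FALSE), n_u, replace = TRUE)
  )
  list(users = users, items = items, lists = lists, test = test,
       scored = scored, disadvantaged = disadvantaged,
       catalog = random_catalog(n_i))
}
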
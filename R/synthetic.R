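#' Configuration for the synthetic trial generator
#'
#' Defaults emulate the shape of the trial logs the evaluation was designed
#' for: 739 enrolled participants of whom roughly 38% ever rate, a catalog
#' growing from 348 to 659 narratives over a 30-month window, about 2300
#' ratings with a long-tailed per-participant activity distribution, and an
#' optional-answer rate of 0.25. Rating values arise from a latent-factor
#' model with optional content-driven and group-shock components, then are
#' discretized onto the 4-point scale with cut points calibrated so the
#' marginal hopefulness distribution approximates the published shares.
#'
#' @param n_participants Number of enrolled participants.
#' @param p_rater Share of participants who submit at least one rating.
#' @param activity_mu,activity_size Negative-binomial parameters of the
#'   number of rating events per rater (plus one), giving the long tail.
#' @param n_narratives_start,n_narratives_end Catalog size at the window
#'   start and end; the difference is released in equal monthly batches.
#' @param d Number of categorical characteristics per narrative.
#' @param n_categories Range of category counts per characteristic.
#' @param f_true Latent dimension of the generative factor model.
#' @param bias_sd Standard deviation of the per-participant and
#'   per-narrative bias terms.
#' @param w_latent,w_content,w_group Effect weights: the latent-factor
#'   signal, the content (characteristic-taste) signal, and the probability
#'   of a one-point downward rating shock for gender-disadvantaged
#'   participants (the overestimation-bias knob).
#' @param sigma Rating noise standard deviation before discretization.
#' @param pi_opt Probability that an event carries the optional block.
#' @param opt_sd Noise linking optional answers to the shared event score.
#' @param rerate_prob Probability an event rerates an already-rated narrative.
#' @param window_start,window_end Observation window dates.
#' @param hopeful_marginal Target marginal shares of the four hopefulness
#'   values used to calibrate the discretization cut points.
#' @param seed_batch Number of pre-trial feasibility ratings to emit, labeled
#'   `source = "feasibility"` and timestamped before the window.
#' @param seed Integer seed; the whole simulation is a deterministic function
#'   of the config.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_participants = 739,
                             p_rater = 0.385,
                             activity_mu = 7, activity_size = 0.6,
                             n_narratives_start = 348,
                             n_narratives_end = 659,
                             d = 77, n_categories = c(2, 4),
                             f_true = 5,
                             bias_sd = 0.25,
                             w_latent = 0.3, w_content = 0.25, w_group = 0,
                             sigma = 0.5, pi_opt = 0.25, opt_sd = 0.8,
                             rerate_prob = 0.03,
                             window_start = as.Date("2020-03-09"),
                             window_end = as.Date("2022-09-22"),
                             hopeful_marginal = c(202, 901, 838, 347) / 2288,
                             seed_batch = 465,
                             seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_narratives_end >= cfg$n_narratives_start,
            cfg$pi_opt >= 0, cfg$pi_opt <= 1,
            cfg$p_rater >= 0, cfg$p_rater <= 1,
            cfg$w_group >= 0, cfg$w_group <= 1,
            length(cfg$hopeful_marginal) == 4, all(cfg$hopeful_marginal > 0))
  cfg$hopeful_marginal <- cfg$hopeful_marginal / sum(cfg$hopeful_marginal)
  if (cfg$d < 2) abort("characteristic dimension d must be at least 2")
  structure(cfg, class = "generator_config")
}

#' Generate the participant and narrative tables of a synthetic trial
#'
#' Participants get a gender drawn from a three-category distribution, a
#' binary ethnicity, and an enrollment date early in the window; narratives
#' get categorical characteristic vectors and staggered availability dates
#' (the initial catalog at the window start, the remainder released in equal
#' monthly batches).
#'
#' @param config A [generator_config()].
#' @return A list with `participants`, `catalog`, and `latent` (the hidden
#'   generative parameters, consumed by [generate_ratings()]).
#' @export
generate_world <- function(config) {
  set.seed(config$seed)
  n <- config$n_participants
  participants <- tibble::tibble(
    participant_id = sprintf("p%04d", seq_len(n)),
    gender = sample(GENDER_LEVELS, n, replace = TRUE,
                    prob = c(0.58, 0.37, 0.05)),
    ethnicity = sample(ETHNICITY_LEVELS, n, replace = TRUE,
                       prob = c(0.8, 0.2)),
    enrolled_on = config$window_start +
      sample.int(365, n, replace = TRUE) - 1L
  )
  participants <- add_group_flags(participants)

  n_item <- config$n_narratives_end
  months <- seq(config$window_start, config$window_end, by = "month")
  extra <- n_item - config$n_narratives_start
  n_rel_months <- max(length(months) - 1L, 1L)
  release <- c(rep(config$window_start, config$n_narratives_start),
               rep(months[-1], length.out = 0))
  if (extra > 0) {
    batch <- rep(months[-1][seq_len(n_rel_months)],
                 times = diff(floor(seq(0, extra, length.out = n_rel_months + 1))))
    release <- c(release, batch)
  }
  k_per_item <- sample(seq(config$n_categories[1], config$n_categories[2]),
                       config$d, replace = TRUE)
  chars <- vapply(seq_len(config$d), function(j) {
    sample.int(k_per_item[j], n_item, replace = TRUE)
  }, integer(n_item))
  colnames(chars) <- paste0("c", seq_len(config$d))
  catalog <- dplyr::bind_cols(
    tibble::tibble(narrative_id = sprintf("n%04d", seq_len(n_item)),
                   available_from = sort(release)),
    tibble::as_tibble(chars)
  )

  f <- config$f_true
  onehot <- one_hot_characteristics(catalog)
  latent <- list(
    b_u = rnorm(n, 0, config$bias_sd),
    b_i = rnorm(n_item, 0, config$bias_sd),
    # entries scaled so the rank-f interaction p'q has unit variance before
    # the w_latent weight is applied
    P = matrix(rnorm(n * f, 0, f^(-0.25)), n, f),
    Q = matrix(rnorm(n_item * f, 0, f^(-0.25)), n_item, f),
    taste = matrix(rnorm(n * ncol(onehot), 0, 1), n, ncol(onehot)),
    onehot = onehot,
    # log-normal exposure weights: a few narratives attract most requests,
    # giving the long-tailed ratings-per-narrative distribution of real logs
    popularity = exp(rnorm(n_item, 0, 1)),
    # narratives whose ratings can take the disadvantaged-group shock:
    # the group effect is tied to narrative types, not spread evenly, so it
    # cannot be absorbed by per-participant or per-narrative bias terms
    group_sensitive = runif(n_item) < 0.5
  )
  list(participants = participants, catalog = catalog, latent = latent)
}

# continuous true score of participant u (index) for narrative i (index),
# without noise or group shock
latent_score <- function(world, config, u, i) {
  lat <- world$latent
  dot <- rowSums(lat$P[u, , drop = FALSE] * lat$Q[i, , drop = FALSE])
  content <- rowSums(lat$taste[u, , drop = FALSE] *
                       lat$onehot[i, , drop = FALSE]) / sqrt(config$d)
  lat$b_u[u] + lat$b_i[i] + config$w_latent * dot +
    config$w_content * content
}

#' Generate a synthetic rating-event log
#'
#' Each rater submits a long-tailed number of timestamped events within
#' their activity window; each event rates a narrative available at that
#' time (occasionally rerating one already rated). The continuous score —
#' latent-factor plus content plus noise — is discretized onto the 4-point
#' scale at cut points chosen so the marginal hopefulness distribution
#' matches the configured target; hopefulness is emitted on its native
#' -1..2 scale and the optional block is present with probability `pi_opt`,
#' its values correlated with the event score. Gender-disadvantaged
#' participants' ratings take a one-point downward shock with probability
#' `w_group`. A labeled pre-trial feasibility batch is prepended when
#' `seed_batch > 0`.
#'
#' @param world Output of [generate_world()].
#' @param config The same [generator_config()].
#' @return A rating-event tibble with attribute `"ground_truth"`: a list
#'   with the discretization cut points, the per-event oracle prediction
#'   (the noiseless score discretized onto 0..3), and the oracle noise floor
#'   (mean absolute error of the oracle on the live events) — the reference
#'   any fitted model is compared against in recovery tests. Correlation
#'   strengths between questions are modelling assumptions, recorded there.
#' @export
generate_ratings <- function(world, config) {
  set.seed(config$seed + 1L)
  parts <- world$participants
  cat_dates <- world$catalog$available_from
  n_item <- nrow(world$catalog)

  raters <- which(runif(nrow(parts)) < config$p_rater)
  n_events_u <- rnbinom(length(raters), mu = config$activity_mu,
                        size = config$activity_size) + 1L
  rows <- list()
  for (idx in seq_along(raters)) {
    u <- raters[idx]
    t0 <- max(parts$enrolled_on[u], config$window_start)
    if (t0 >= config$window_end) next
    span <- as.numeric(config$window_end - t0)
    times <- sort(t0 + runif(n_events_u[idx]) * span)
    rated <- integer(0)
    ev_i <- integer(0); ev_t <- as.Date(character(0))
    for (tt in seq_along(times)) {
      avail <- which(cat_dates <= times[tt])
      if (length(rated) > 0 && runif(1) < config$rerate_prob) {
        i <- rated[sample.int(length(rated), 1)]
      } else {
        fresh <- setdiff(avail, rated)
        if (length(fresh) == 0) next
        w <- world$latent$popularity[fresh]
        i <- fresh[sample.int(length(fresh), 1, prob = w)]
        rated <- c(rated, i)
      }
      ev_i <- c(ev_i, i); ev_t <- c(ev_t, times[tt])
    }
    if (length(ev_i) > 0) {
      rows[[length(rows) + 1]] <- tibble::tibble(u = u, i = ev_i, date = ev_t)
    }
  }
  live <- dplyr::bind_rows(rows)
  if (is.null(live) || nrow(live) == 0) {
    live <- tibble::tibble(u = integer(), i = integer(),
                           date = as.Date(character()))
  }

  # pre-trial feasibility batch over the initial catalog, separate raters
  n_seed <- config$seed_batch
  if (n_seed > 0 && config$n_narratives_start > 0) {
    seed_events <- tibble::tibble(
      u = NA_integer_,
      i = sample.int(config$n_narratives_start, n_seed, replace = TRUE),
      date = config$window_start - sample.int(60, n_seed, replace = TRUE),
      seed_uid = sprintf("fs%02d", sample.int(25, n_seed, replace = TRUE))
    )
  } else {
    seed_events <- NULL
  }

  score_of <- function(u, i, is_seed) {
    s0 <- numeric(length(i))
    if (any(!is_seed)) {
      s0[!is_seed] <- latent_score(world, config, u[!is_seed], i[!is_seed])
    }
    if (any(is_seed)) {
      # feasibility raters share no latent profile; item effects only
      s0[is_seed] <- world$latent$b_i[i[is_seed]]
    }
    s0
  }
  all_u <- c(live$u, if (!is.null(seed_events)) seed_events$u)
  all_i <- c(live$i, if (!is.null(seed_events)) seed_events$i)
  is_seed <- c(rep(FALSE, nrow(live)),
               rep(TRUE, if (is.null(seed_events)) 0 else nrow(seed_events)))
  if (length(all_i) == 0) {
    events <- tibble::tibble(
      participant_id = character(), narrative_id = character(),
      timestamp = as.POSIXct(character(), tz = "UTC"),
      hopefulness = integer(), sim_narrator = integer(),
      sim_narrative = integer(), learning = integer(), empathy = integer(),
      source = character())
    attr(events, "ground_truth") <- list(
      cutpoints = numeric(3), noise_floor = NA_real_,
      oracle = tibble::tibble(participant_id = character(),
                              narrative_id = character(),
                              oracle = numeric(), value = integer()))
    return(events)
  }
  s0 <- score_of(all_u, all_i, is_seed)
  s <- s0 + rnorm(length(s0), 0, config$sigma)

  cuts <- quantile(s, cumsum(config$hopeful_marginal)[1:3], names = FALSE)
  discretize <- function(x) findInterval(x, cuts)  # 0..3
  value <- discretize(s)
  shock <- rep(FALSE, length(value))
  if (config$w_group > 0 && nrow(live) > 0) {
    dis <- parts$gender_disadvantaged[live$u]
    sens <- world$latent$group_sensitive[live$i]
    shock[seq_len(nrow(live))] <- dis & sens &
      runif(nrow(live)) < config$w_group
  }
  value <- pmax(value - as.integer(shock), 0L)
  oracle <- discretize(s0)

  has_opt <- runif(length(value)) < config$pi_opt
  opt_val <- function() {
    v <- ifelse(has_opt,
                pmin(pmax(round(value + rnorm(length(value), 0,
                                              config$opt_sd)), 0), 3),
                NA_integer_)
    as.integer(v)
  }
  events <- tibble::tibble(
    participant_id = c(if (nrow(live) > 0) parts$participant_id[live$u],
                       if (!is.null(seed_events)) seed_events$seed_uid),
    narrative_id = world$catalog$narrative_id[all_i],
    # fractional days in the generated dates already carry the time of day;
    # truncated to whole seconds so the CSV round trip is exact
    timestamp = as.POSIXct(
      floor(as.numeric(as.POSIXct(
        c(live$date, if (!is.null(seed_events)) seed_events$date),
        tz = "UTC"))),
      origin = "1970-01-01", tz = "UTC"),
    hopefulness = as.integer(value) - 1L,
    sim_narrator = opt_val(),
    sim_narrative = opt_val(),
    learning = opt_val(),
    empathy = opt_val(),
    source = ifelse(is_seed, "feasibility", NA_character_)
  )
  events <- dplyr::arrange(events, .data$timestamp)
  validate_rating_events(events)

  # oracle table for live events: per (participant, narrative) pair keep the
  # last generated event, matching the latest-wins rule of build_streams()
  # (within a participant, events are generated in chronological order)
  oracle_tbl <- tibble::tibble(
    participant_id = c(if (nrow(live) > 0) parts$participant_id[live$u],
                       if (!is.null(seed_events)) seed_events$seed_uid),
    narrative_id = world$catalog$narrative_id[all_i],
    oracle = as.numeric(oracle),
    value = as.integer(value),
    live = !is_seed
  ) |>
    dplyr::filter(.data$live) |>
    dplyr::group_by(.data$participant_id, .data$narrative_id) |>
    dplyr::slice_tail(n = 1) |>
    dplyr::ungroup() |>
    dplyr::select("participant_id", "narrative_id", "oracle", "value")
  gt <- list(
    cutpoints = cuts,
    noise_sd = config$sigma,
    assumptions = paste("optional answers are the event value plus",
                        "N(0,", config$opt_sd, ") noise, clamped to 0..3;",
                        "inter-question correlation is assumed, not",
                        "estimated from any trial"),
    oracle = oracle_tbl,
    noise_floor = if (nrow(oracle_tbl) > 0) {
      mean(abs(oracle_tbl$oracle - oracle_tbl$value))
    } else NA_real_
  )
  attr(events, "ground_truth") <- gt
  events
}

#' Simulate a full synthetic trial and write it to disk
#'
#' Runs [generate_world()] and [generate_ratings()] and writes
#' `ratings.csv`, `narratives.csv`, `participants.csv`, and
#' `ground_truth.json` (latent dimensioning, discretization cut points,
#' noise floor, and per-pair oracle predictions for recovery tests) into a
#' directory.
#'
#' @param config A [generator_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory `events`, `participants`,
#'   `catalog`, and `ground_truth`.
#' @export
simulate_trial <- function(config = generator_config(), dir = NULL) {
  world <- generate_world(config)
  events <- generate_ratings(world, config)
  gt <- attr(events, "ground_truth")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_rating_log(events, file.path(dir, "ratings.csv"))
    readr::write_csv(world$catalog, file.path(dir, "narratives.csv"),
                     progress = FALSE)
    readr::write_csv(
      dplyr::select(world$participants, "participant_id", "gender",
                    "ethnicity", "enrolled_on"),
      file.path(dir, "participants.csv"), progress = FALSE)
    jsonlite::write_json(
      list(config = unclass(config)[setdiff(names(config),
                                            c("window_start", "window_end"))],
           window = c(format(config$window_start),
                      format(config$window_end)),
           cutpoints = gt$cutpoints, noise_floor = gt$noise_floor,
           assumptions = gt$assumptions, oracle = gt$oracle),
      file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
  }
  invisible(list(events = events, participants = world$participants,
                 catalog = world$catalog, ground_truth = gt))
}
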
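# Independent brute-force oracles. These re-derive every metric from its
# definition with plain loops and no shared code with the package internals.

oracle_cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

oracle_onehot <- function(catalog) {
  feat <- grep("^c[0-9]+$", names(catalog), value = TRUE)
  levs <- lapply(feat, function(cl) sort(unique(catalog[[cl]])))
  t(vapply(seq_len(nrow(catalog)), function(r) {
    unlist(lapply(seq_along(feat), function(j) {
      as.numeric(levs[[j]] == catalog[[feat[j]]][r])
    }))
  }, numeric(sum(lengths(levs))))) |>
    (\(m) {rownames(m) <- catalog$narrative_id; m})()
}

oracle_nmae <- function(pred, actual) {
  s <- 0; n <- 0
  for (t in seq_along(pred)) {
    if (!is.na(pred[t]) && !is.na(actual[t])) {
      s <- s + abs(pred[t] - actual[t]); n <- n + 1
    }
  }
  s / n
}

oracle_map <- function(lists, test, threshold = 1, n_cap = 10) {
  aps <- c()
  for (u in names(lists)) {
    tu <- test[test$participant_id == u, ]
    if (nrow(tu) == 0) next
    relevant <- tu$narrative_id[tu$value >= threshold]
    if (length(relevant) == 0) { aps <- c(aps, 0); next }
    ids <- lists[[u]]$narrative_id
    hits <- 0; ap <- 0
    for (i in seq_along(ids)) {
      if (ids[i] %in% relevant) {
        hits <- hits + 1
        ap <- ap + hits / i
      }
    }
    aps <- c(aps, ap / min(length(relevant), n_cap))
  }
  mean(aps)
}

oracle_ild <- function(lists, catalog) {
  oh <- oracle_onehot(catalog)
  vals <- c()
  for (lst in lists) {
    ids <- lst$narrative_id
    if (length(ids) < 2) next
    tot <- 0; m <- 0
    for (a in seq_along(ids)) for (b in seq_along(ids)) {
      if (a < b) {
        tot <- tot + oracle_cosine(oh[ids[a], ], oh[ids[b], ])
        m <- m + 1
      }
    }
    vals <- c(vals, tot / m)
  }
  mean(vals)
}

oracle_isc <- function(lists, rated_ids) {
  rated_ids <- unique(rated_ids)
  hit <- 0
  for (i in rated_ids) {
    found <- FALSE
    for (lst in lists) if (i %in% lst$narrative_id) found <- TRUE
    if (found) hit <- hit + 1
  }
  hit / length(rated_ids)
}

oracle_uover <- function(scored, disadvantaged) {
  flag <- setNames(disadvantaged$disadvantaged, disadvantaged$participant_id)
  items <- unique(scored$narrative_id)
  terms <- c()
  for (j in items) {
    sj <- scored[scored$narrative_id == j & !is.na(scored$predicted), ]
    g <- sj[flag[sj$participant_id], ]
    ng <- sj[!flag[sj$participant_id], ]
    if (nrow(g) == 0 || nrow(ng) == 0) next
    og <- max(0, mean(g$predicted) - mean(g$actual))
    ong <- max(0, mean(ng$predicted) - mean(ng$actual))
    terms <- c(terms, abs(og - ong))
  }
  if (length(terms) == 0) return(NA_real_)
  mean(terms)
}

# brute-force item-kNN prediction straight from the contract
oracle_knn_predict <- function(stream, catalog, uid, iid, k = 40) {
  oh <- oracle_onehot(catalog)
  mine <- stream[stream$participant_id == uid, ]
  if (nrow(mine) == 0 || !iid %in% catalog$narrative_id) return(NA_real_)
  sims <- vapply(mine$narrative_id,
                 function(j) oracle_cosine(oh[iid, ], oh[j, ]), numeric(1))
  keep <- which(sims > 0)
  if (length(keep) > 0) {
    ord <- keep[order(sims[keep], decreasing = TRUE)]
    ord <- ord[seq_len(min(k, length(ord)))]
    p <- sum(sims[ord] * mine$value[ord]) / sum(sims[ord])
  } else {
    p <- mean(mine$value)
  }
  min(max(p, 0), 3)
}

# the SGD recurrences replayed in plain R, observation by observation
oracle_sgd_svd <- function(u, i, r, mu, P, Q, epochs, lr, reg) {
  bu <- numeric(nrow(P)); bi <- numeric(nrow(Q))
  for (ep in seq_len(epochs)) {
    for (t in seq_along(r)) {
      uu <- u[t]; ii <- i[t]
      e <- r[t] - (mu + bu[uu] + bi[ii] + sum(P[uu, ] * Q[ii, ]))
      bu[uu] <- bu[uu] + lr * (e - reg * bu[uu])
      bi[ii] <- bi[ii] + lr * (e - reg * bi[ii])
      pu <- P[uu, ]
      P[uu, ] <- P[uu, ] + lr * (e * Q[ii, ] - reg * P[uu, ])
      Q[ii, ] <- Q[ii, ] + lr * (e * pu - reg * Q[ii, ])
    }
  }
  list(bu = bu, bi = bi, P = P, Q = Q)
}

oracle_sgd_svdpp <- function(u, i, r, mu, P, Q, Y, Iu, epochs, lr, reg) {
  bu <- numeric(nrow(P)); bi <- numeric(nrow(Q))
  for (ep in seq_len(epochs)) {
    for (t in seq_along(r)) {
      uu <- u[t]; ii <- i[t]
      items_u <- Iu[[uu]]
      sq <- 1 / sqrt(length(items_u))
      impl <- sq * colSums(Y[items_u, , drop = FALSE])
      e <- r[t] - (mu + bu[uu] + bi[ii] + sum(Q[ii, ] * (P[uu, ] + impl)))
      bu[uu] <- bu[uu] + lr * (e - reg * bu[uu])
      bi[ii] <- bi[ii] + lr * (e - reg * bi[ii])
      pu <- P[uu, ]; qi <- Q[ii, ]
      P[uu, ] <- P[uu, ] + lr * (e * qi - reg * pu)
      Q[ii, ] <- Q[ii, ] + lr * (e * (pu + impl) - reg * qi)
      for (j in items_u) {
        Y[j, ] <- Y[j, ] + lr * (e * sq * qi - reg * Y[j, ])
      }
    }
  }
  list(bu = bu, bi = bi, P = P, Q = Q, Y = Y)
}
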
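# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: pair counting instead of ranks, exhaustive
# threshold search instead of the ROC-vertex walk, dense grids instead of
# polished optimization.

# Mann-Whitney AUC by explicit pair enumeration (ties count 1/2)
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# best Youden threshold by brute force over all observed score values,
# mirroring the documented tie-breaks (higher specificity, lower threshold)
youden_oracle <- function(scores, labels) {
  labels <- as.logical(labels)
  cand <- sort(unique(scores))
  stats <- t(vapply(cand, function(t) {
    pred <- scores >= t
    sens <- sum(pred & labels) / sum(labels)
    spec <- sum(!pred & !labels) / sum(!labels)
    c(j = sens + spec - 1, spec = spec)
  }, numeric(2)))
  best <- which(stats[, "j"] >= max(stats[, "j"]) - 1e-12)
  best <- best[order(-stats[best, "spec"], cand[best])][1]
  cand[best]
}

# dense-grid maximization of a cp_polysurface over the closed unit square
grid_max_oracle <- function(surface, grid_n = 2001L) {
  g <- seq(0, 1, length.out = grid_n)
  co <- surface$coefficients
  vals <- matrix(0, grid_n, grid_n)
  for (k in seq_len(nrow(co))) {
    vals <- vals + co$coefficient[k] * outer(g^co$i[k], g^co$j[k])
  }
  idx <- which.max(vals)
  list(x = g[(idx - 1L) %% grid_n + 1L], y = g[(idx - 1L) %/% grid_n + 1L],
       value = max(vals))
}

# random polynomial surface of a given total degree
random_surface <- function(order, seed) {
  exps <- expand.grid(i = 0:order, j = 0:order)
  exps <- exps[exps$i + exps$j <= order, ]
  coefs <- withr::with_seed(seed, stats::rnorm(nrow(exps)))
  structure(
    list(order = order,
         coefficients = tibble::tibble(i = exps$i, j = exps$j,
                                       coefficient = coefs),
         r_squared = NA_real_, n = NA_integer_),
    class = "cp_polysurface"
  )
}

# small labelled cohort with a guaranteed event and non-event
tiny_cohort <- function(n = 40, seed = 1, event_rate = 0.3) {
  withr::with_seed(seed, {
    tibble::tibble(
      id = sprintf("T%03d", seq_len(n)),
      age = stats::runif(n, 40, 95),
      heart_rate = stats::runif(n, 55, 130),
      pao2 = stats::runif(n, 35, 100),
      died_30d = c(TRUE, FALSE,
                   stats::runif(n - 2) < event_rate)
    )
  })
}

published_weights <- c(0.5705, 0.2553, 0.1742)
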
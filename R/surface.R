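#' Sample reduced weight pairs uniformly on the unit square
#'
#' The optimizer explores the normalized weight simplex through its 2-D
#' reduced coordinates (see [expand_weights()]); candidate weightings are
#' drawn i.i.d. uniform on (0, 1) in each coordinate. The default design of
#' the derivation procedure uses 5000 pairs.
#'
#' @param n Number of pairs (at least 1).
#' @param seed Integer seed; the sequence is reproducible.
#' @return Tibble with columns `x`, `y`, all values strictly inside (0, 1).
#' @export
sample_weight_pairs <- function(n, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    abort("`n` must be a positive integer.")
  }
  m <- withr::with_seed(as.integer(seed), matrix(runif(2L * n), ncol = 2L))
  tibble::tibble(x = m[, 1L], y = m[, 2L])
}

#' Evaluate the AUC surface over sampled weight pairs
#'
#' For each reduced pair (x, y), expands to a normalized weight triple,
#' scores every patient with the continuous evaluation function, and
#' computes the ROC AUC (`Q`) against the 30-day mortality label. The
#' result is the Monte-Carlo sample of the response surface
#' `Q(x, y)` that the polynomial surrogate is fitted to.
#'
#' @param data Cohort tibble with `age`, `heart_rate`, `pao2`, `died_30d`
#'   (both outcome classes must be present).
#' @param pairs Tibble with columns `x`, `y` in (0, 1), e.g. from
#'   [sample_weight_pairs()].
#' @return Tibble of class `cp_surface_samples` with columns `x`, `y`, `q`
#'   (each `q` in \[0, 1\]), rows aligned with `pairs`.
#' @export
evaluate_surface <- function(data, pairs) {
  data <- check_cohort_frame(data, c("age", "heart_rate", "pao2", "died_30d"))
  if (!is.data.frame(pairs) || !all(c("x", "y") %in% names(pairs))) {
    abort("`pairs` must be a data frame with columns `x` and `y`.")
  }
  if (any(pairs$x <= 0 | pairs$x >= 1 | pairs$y <= 0 | pairs$y >= 1)) {
    abort("All reduced coordinates must lie strictly inside (0, 1).")
  }
  labels <- as.logical(data$died_30d)
  if (!any(labels) || all(labels)) {
    abort("Cohort must contain both an event and a non-event.")
  }
  v <- recycle_covariates(data$age, data$heart_rate, data$pao2)
  X <- cbind(v$age, v$heart_rate, -v$pao2)
  W <- cbind(pairs$x, (1 - pairs$x) * pairs$y, (1 - pairs$x) * (1 - pairs$y))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  q <- numeric(nrow(W))
  # chunked so the score matrix stays modest for large designs
  chunks <- split(seq_len(nrow(W)), ceiling(seq_len(nrow(W)) / 500))
  for (idx in chunks) {
    S <- X %*% t(W[idx, , drop = FALSE])
    q[idx] <- apply(S, 2L, function(s) {
      (sum(rank(s)[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
    })
  }
  out <- tibble::tibble(x = pairs$x, y = pairs$y, q = q)
  class(out) <- c("cp_surface_samples", class(out))
  attr(out, "n_pos") <- n_pos
  attr(out, "n_neg") <- n_neg
  out
}

#' Fit a bivariate polynomial surrogate to sampled AUC values
#'
#' Ordinary least squares on the full monomial basis `x^i * y^j` with
#' `i + j <= order` — `(order + 1)(order + 2) / 2` terms, e.g. 36 at order
#' 7. Monomials are evaluated at the raw (x, y) coordinates on the unit
#' square; design columns are rescaled to unit root-mean-square before the
#' QR solve for conditioning and the coefficients are returned on the raw
#' monomial scale. R-squared is computed in-sample on the fitted points.
#'
#' @param samples Tibble with columns `x`, `y`, `q` (a `cp_surface_samples`
#'   or any data frame of that shape).
#' @param order Total polynomial degree `d >= 1`.
#' @return A `cp_polysurface` object: coefficients (tibble `i`, `j`,
#'   `coefficient`), `order`, `r_squared`, and the sample size `n`.
#'   `predict()` evaluates it on new `(x, y)` data; `tidy()` returns the
#'   coefficient table, `glance()` the fit summary.
#' @export
fit_polynomial_surface <- function(samples, order) {
  if (!is.data.frame(samples) || !all(c("x", "y", "q") %in% names(samples))) {
    abort("`samples` must have columns `x`, `y`, `q`.")
  }
  if (!is.numeric(order) || length(order) != 1L || order < 1 ||
      order != round(order)) {
    abort("`order` must be a positive integer.")
  }
  order <- as.integer(order)
  n_terms <- (order + 1L) * (order + 2L) / 2L
  n <- nrow(samples)
  if (n < n_terms) {
    abort(sprintf(
      "Under-determined fit: order %d needs at least %d sample points, got %d.",
      order, n_terms, n
    ))
  }
  exps <- monomial_exponents(order)
  M <- monomial_matrix(samples$x, samples$y, exps)
  scale <- sqrt(colMeans(M^2))
  scale[scale == 0] <- 1
  fit <- stats::lm.fit(sweep(M, 2L, scale, "/"), samples$q)
  beta <- fit$coefficients / scale
  fitted <- drop(M %*% beta)
  ss_res <- sum((samples$q - fitted)^2)
  ss_tot <- sum((samples$q - mean(samples$q))^2)
  structure(
    list(
      order = order,
      coefficients = tibble::tibble(i = exps$i, j = exps$j,
                                    coefficient = unname(beta)),
      r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
      n = n
    ),
    class = "cp_polysurface"
  )
}

#' @rdname fit_polynomial_surface
#' @param object,x A `cp_polysurface`.
#' @param newdata Data frame with columns `x` and `y`.
#' @param ... Unused.
#' @export
predict.cp_polysurface <- function(object, newdata, ...) {
  if (!all(c("x", "y") %in% names(newdata))) {
    abort("`newdata` must have columns `x` and `y`.")
  }
  exps <- object$coefficients
  drop(monomial_matrix(newdata$x, newdata$y,
                       list(i = exps$i, j = exps$j)) %*% exps$coefficient)
}

#' @rdname fit_polynomial_surface
#' @method tidy cp_polysurface
#' @export
tidy.cp_polysurface <- function(x, ...) x$coefficients

#' @rdname fit_polynomial_surface
#' @method glance cp_polysurface
#' @export
glance.cp_polysurface <- function(x, ...) {
  tibble::tibble(order = x$order, n_terms = nrow(x$coefficients),
                 r_squared = x$r_squared, n = x$n)
}

#' @export
print.cp_polysurface <- function(x, ...) {
  cat(sprintf("<bivariate polynomial surface: order %d, %d terms, R^2 = %.5f, n = %d>\n",
              x$order, nrow(x$coefficients), x$r_squared, x$n))
  invisible(x)
}

#' Maximize a polynomial surface over the closed unit square
#'
#' Global maximization by dense grid scan over the interior, bounded local
#' polish (`optim(method = "L-BFGS-B")`) from the best grid cells, and explicit 1-D maximization along each boundary
#' edge — the interior optimum is compared against the boundary before the
#' overall argmax is returned.
#'
#' @param surface A `cp_polysurface` (or any object with a compatible
#'   `predict()` method accepting `newdata`).
#' @param grid_n Grid resolution per axis for the scan (default 501).
#' @param n_polish Number of top grid points to polish locally (default 10).
#' @return Named list with `x`, `y`, `value`, and `location` ("interior" or
#'   "boundary").
#' @export
maximize_surface <- function(surface, grid_n = 501L, n_polish = 10L) {
  f <- function(x, y) predict(surface, data.frame(x = x, y = y))
  g <- seq(0, 1, length.out = grid_n)
  exps <- surface$coefficients
  # accumulate coef * outer(x^i, y^j) term by term: cheap and exact
  vals <- matrix(0, grid_n, grid_n)
  for (k in seq_len(nrow(exps))) {
    vals <- vals + exps$coefficient[k] * outer(g^exps$i[k], g^exps$j[k])
  }
  top <- order(vals, decreasing = TRUE)[seq_len(min(n_polish, length(vals)))]
  best <- list(x = NA_real_, y = NA_real_, value = -Inf, location = "interior")
  for (cell in top) {
    start <- c(g[(cell - 1L) %% grid_n + 1L], g[(cell - 1L) %/% grid_n + 1L])
    opt <- optim(start, function(p) -f(p[1L], p[2L]), method = "L-BFGS-B",
                 lower = 0, upper = 1)
    if (-opt$value > best$value) {
      best <- list(x = opt$par[1L], y = opt$par[2L], value = -opt$value,
                   location = "interior")
    }
  }
  # boundary edges, each a 1-D polynomial maximization
  edges <- list(
    list(fix = "y", at = 0), list(fix = "y", at = 1),
    list(fix = "x", at = 0), list(fix = "x", at = 1)
  )
  for (e in edges) {
    h <- if (e$fix == "y") function(t) f(t, e$at) else function(t) f(e$at, t)
    cand_t <- g[order(h(g), decreasing = TRUE)[seq_len(min(5L, grid_n))]]
    for (t0 in cand_t) {
      o <- optim(t0, function(t) -h(t), method = "L-BFGS-B", lower = 0, upper = 1)
      val <- -o$value
      if (val > best$value) {
        p <- if (e$fix == "y") c(o$par, e$at) else c(e$at, o$par)
        best <- list(x = p[1L], y = p[2L], value = val, location = "boundary")
      }
    }
  }
  if (best$x %in% c(0, 1) || best$y %in% c(0, 1)) best$location <- "boundary"
  best
}

monomial_exponents <- function(order) {
  grid <- expand.grid(i = 0:order, j = 0:order)
  grid <- grid[grid$i + grid$j <= order, , drop = FALSE]
  grid <- grid[order(grid$i + grid$j, grid$j), , drop = FALSE]
  list(i = grid$i, j = grid$j)
}

monomial_matrix <- function(x, y, exps) {
  M <- matrix(0, length(x), length(exps$i))
  for (k in seq_along(exps$i)) M[, k] <- x^exps$i[k] * y^exps$j[k]
  M
}
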
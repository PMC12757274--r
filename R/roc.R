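#' Area under the ROC curve
#'
#' Computes the AUC as the tie-corrected Mann–Whitney statistic: the fraction
#' of (event, non-event) pairs in which the event scores higher, with tied
#' pairs counted 1/2. This is identical to the trapezoidal area under the
#' tie-collapsed empirical ROC curve, and is the objective (`Q`) that the
#' weight optimizer maximizes.
#'
#' @param scores Numeric risk scores; higher means higher predicted risk.
#' @param labels Binary outcome labels (logical or 0/1); `TRUE`/1 is an
#'   event.
#' @return AUC in \[0, 1\].
#' @examples
#' auc(c(1, 2, 3, 4), c(0, 0, 1, 1)) # 1
#' @export
auc <- function(scores, labels) {
  d <- check_roc_input(scores, labels)
  r <- rank(d$scores)
  (sum(r[d$labels]) - d$n_pos * (d$n_pos + 1) / 2) / (d$n_pos * d$n_neg)
}

#' Empirical ROC curve
#'
#' Builds the empirical ROC curve for the rule "predict an event when
#' `score >= threshold`". One vertex is emitted per distinct score value
#' (ties collapse to a single vertex) plus the terminal (0, 0) point at an
#' infinite threshold; the curve always ends at (1, 1).
#'
#' @inheritParams auc
#' @return An object of class `cp_roc`: a list with `points` (tibble of
#'   `threshold`, `fpr`, `tpr`), `auc` (trapezoidal area), and the class
#'   counts `n_pos`, `n_neg`. `tidy()` returns the points, `glance()` a
#'   one-row summary, and `autoplot()` draws the curve.
#' @export
roc_curve <- function(scores, labels) {
  d <- check_roc_input(scores, labels)
  ord <- order(d$scores, decreasing = TRUE)
  s <- d$scores[ord]
  y <- d$labels[ord]
  last_of_tie <- c(diff(s) != 0, TRUE)
  tp <- cumsum(y)[last_of_tie]
  fp <- cumsum(!y)[last_of_tie]
  points <- tibble::tibble(
    threshold = c(Inf, s[last_of_tie]),
    fpr = c(0, fp / d$n_neg),
    tpr = c(0, tp / d$n_pos)
  )
  area <- sum(diff(points$fpr) * (points$tpr[-1L] + points$tpr[-nrow(points)]) / 2)
  structure(
    list(points = points, auc = area, n_pos = d$n_pos, n_neg = d$n_neg),
    class = "cp_roc"
  )
}

#' Youden-optimal classification threshold
#'
#' The cutoff reported for a risk score is the observed score value
#' maximizing Youden's J = sensitivity + specificity - 1 under the rule
#' "event when `score >= threshold`". Ties in J are broken in favor of
#' higher specificity, then of the lower threshold. When the curve is the
#' diagonal (J = 0 everywhere, e.g. all scores tied) the single observed
#' vertex is returned with a degeneracy warning.
#'
#' @param roc A `cp_roc` object from [roc_curve()].
#' @return The threshold (a finite observed score value).
#' @export
optimal_threshold <- function(roc) {
  if (!inherits(roc, "cp_roc")) abort("`roc` must be a `cp_roc` object.")
  pts <- roc$points[is.finite(roc$points$threshold), , drop = FALSE]
  if (nrow(pts) == 0L) abort("Degenerate ROC curve: no finite thresholds.")
  j <- pts$tpr - pts$fpr
  if (max(j) <= 0 && nrow(pts) >= 1L && all(abs(j) < 1e-12)) {
    warn("ROC curve is the diagonal (no discrimination); threshold is arbitrary.")
  }
  # tolerance absorbs last-ulp differences between equivalent J computations
  best <- which(j >= max(j) - 1e-12)
  if (length(best) > 1L) best <- best[order(pts$fpr[best], pts$threshold[best])][1L]
  pts$threshold[best]
}

#' Confusion-matrix metrics at a threshold
#'
#' @inheritParams auc
#' @param threshold Classification cutoff; an event is predicted when
#'   `score >= threshold`.
#' @return One-row tibble with `accuracy`, `sensitivity`, `specificity`,
#'   and the 2x2 counts `tp`, `fp`, `tn`, `fn`.
#' @export
classification_metrics <- function(scores, labels, threshold) {
  d <- check_roc_input(scores, labels)
  pred <- d$scores >= threshold
  tp <- sum(pred & d$labels)
  fp <- sum(pred & !d$labels)
  fn <- sum(!pred & d$labels)
  tn <- sum(!pred & !d$labels)
  tibble::tibble(
    accuracy = (tp + tn) / length(d$scores),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    tp = tp, fp = fp, tn = tn, fn = fn
  )
}

#' Bootstrap confidence interval for the AUC
#'
#' Stratified percentile bootstrap: events and non-events are resampled
#' separately (so both classes are present in every replicate), the AUC is
#' recomputed per replicate, and the interval is read off the percentile
#' quantiles.
#'
#' @inheritParams auc
#' @param level Confidence level, default 0.95.
#' @param reps Number of bootstrap replicates (at least 100), default 2000.
#' @param seed Integer seed; the interval is reproducible under a fixed
#'   seed.
#' @return Named numeric vector `c(low, high)`.
#' @export
auc_ci <- function(scores, labels, level = 0.95, reps = 2000L, seed = 1L) {
  d <- check_roc_input(scores, labels)
  if (reps < 100L) abort("`reps` must be at least 100.")
  pos <- d$scores[d$labels]
  neg <- d$scores[!d$labels]
  stat <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(reps), function(i) {
      s_pos <- sample(pos, replace = TRUE)
      s_neg <- sample(neg, replace = TRUE)
      auc(c(s_pos, s_neg), rep(c(TRUE, FALSE), c(length(s_pos), length(s_neg))))
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- unname(quantile(stat, c(alpha, 1 - alpha), names = FALSE, type = 7))
  c(low = ci[1L], high = ci[2L])
}

#' Check AUC invariance under positive rescaling of scores
#'
#' Multiplying every score by a positive constant `N` is a strictly
#' increasing transform, so the ROC curve and AUC are unchanged; this is the
#' property that lets the weight triple be normalized onto the unit simplex
#' without loss. Negative `N` reverses the ranking and is rejected.
#'
#' @inheritParams auc
#' @param N Positive scaling constant.
#' @return `TRUE` when the AUCs agree exactly.
#' @export
auc_scale_invariance_check <- function(scores, labels, N) {
  if (!is.numeric(N) || length(N) != 1L || !is.finite(N) || N <= 0) {
    abort("`N` must be a single positive finite number.")
  }
  isTRUE(all.equal(auc(scores, labels), auc(N * scores, labels), tolerance = 0))
}

#' Evaluate CON-PERFORM (or PERFORM) on a labeled cohort
#'
#' Scores a cohort, builds the ROC curve, selects the Youden-optimal
#' threshold, and reports accuracy / sensitivity / specificity at that
#' threshold together with a bootstrap confidence interval for the AUC.
#'
#' @param data Cohort tibble with `age`, `heart_rate`, `pao2`, `died_30d`.
#' @param weights Weight triple for the continuous score, or `NULL` to
#'   evaluate the discrete PERFORM score instead.
#' @param threshold Optional fixed cutoff; by default the Youden-optimal
#'   threshold is derived from this cohort.
#' @param ci Compute the bootstrap AUC interval (default `TRUE`).
#' @param reps,level,seed Passed to [auc_ci()].
#' @return A `cp_eval` object; `glance()` gives the one-row metric summary,
#'   `tidy()` the ROC points, `autoplot()` the ROC curve.
#' @export
evaluate_cohort <- function(data, weights = NULL, threshold = NULL,
                            ci = TRUE, reps = 2000L, level = 0.95, seed = 1L) {
  data <- check_cohort_frame(data, c("age", "heart_rate", "pao2", "died_30d"))
  scores <- if (is.null(weights)) {
    perform_score(data$age, data$heart_rate, data$pao2)
  } else {
    con_perform_score(data$age, data$heart_rate, data$pao2, weights)
  }
  labels <- as.logical(data$died_30d)
  roc <- roc_curve(scores, labels)
  thr <- threshold %||% optimal_threshold(roc)
  metrics <- classification_metrics(scores, labels, thr)
  interval <- if (ci) auc_ci(scores, labels, level = level, reps = reps, seed = seed) else NULL
  structure(
    list(
      score = if (is.null(weights)) "PERFORM" else "CON-PERFORM",
      weights = if (is.null(weights)) NULL else check_weights(weights),
      roc = roc, auc = roc$auc, auc_ci = interval, level = level,
      threshold = thr, threshold_fixed = !is.null(threshold),
      metrics = metrics, n = nrow(data), n_events = sum(labels)
    ),
    class = "cp_eval"
  )
}

#' @export
print.cp_eval <- function(x, ...) {
  cat(sprintf("<%s evaluation: n = %d, events = %d>\n", x$score, x$n, x$n_events))
  cat(sprintf("  AUC %.3f%s\n", x$auc,
              if (!is.null(x$auc_ci)) {
                sprintf(" (%d%% CI %.3f-%.3f)", round(100 * x$level),
                        x$auc_ci[["low"]], x$auc_ci[["high"]])
              } else ""))
  cat(sprintf("  threshold %s%.4g  accuracy %.3f  sensitivity %.3f  specificity %.3f\n",
              if (x$threshold_fixed) "(fixed) " else "(Youden) ",
              x$threshold, x$metrics$accuracy, x$metrics$sensitivity,
              x$metrics$specificity))
  invisible(x)
}

#' @method tidy cp_roc
#' @export
tidy.cp_roc <- function(x, ...) x$points

#' @method glance cp_roc
#' @export
glance.cp_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg,
                 n_points = nrow(x$points))
}

#' @rdname evaluate_cohort
#' @param x A `cp_eval` object.
#' @param ... Unused.
#' @method tidy cp_eval
#' @export
tidy.cp_eval <- function(x, ...) x$roc$points

#' @rdname evaluate_cohort
#' @method glance cp_eval
#' @export
glance.cp_eval <- function(x, ...) {
  tibble::tibble(
    score = x$score,
    auc = x$auc,
    auc_low = if (is.null(x$auc_ci)) NA_real_ else x$auc_ci[["low"]],
    auc_high = if (is.null(x$auc_ci)) NA_real_ else x$auc_ci[["high"]],
    threshold = x$threshold,
    accuracy = x$metrics$accuracy,
    sensitivity = x$metrics$sensitivity,
    specificity = x$metrics$specificity,
    n = x$n, n_events = x$n_events
  )
}

check_roc_input <- function(scores, labels) {
  if (length(scores) != length(labels) || length(scores) == 0L) {
    abort("`scores` and `labels` must be non-empty and of equal length.")
  }
  if (!is.numeric(scores) || anyNA(scores) || any(!is.finite(scores))) {
    abort("`scores` must be finite numeric values.")
  }
  lab <- if (is.logical(labels)) labels else {
    if (!all(labels %in% c(0, 1))) abort("`labels` must be logical or 0/1.")
    labels == 1
  }
  if (anyNA(lab)) abort("`labels` must not contain missing values.")
  n_pos <- sum(lab)
  n_neg <- sum(!lab)
  if (n_pos == 0L || n_neg == 0L) {
    abort("Both an event and a non-event are required for ROC analysis.")
  }
  list(scores = as.numeric(scores), labels = lab, n_pos = n_pos, n_neg = n_neg)
}
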
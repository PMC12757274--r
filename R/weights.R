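#' Weight triples on the normalized simplex
#'
#' CON-PERFORM scores patients with a linear evaluation function
#' `G = k_age * age + k_heartrate * heart_rate - k_pao2 * pao2`.
#' Multiplying all three coefficients by the same positive constant leaves
#' every patient ordering — and therefore the ROC curve and its AUC —
#' unchanged, so weights are only identified up to scale. The package works
#' on the normalized simplex `k_age + k_heartrate + k_pao2 = 1` with every
#' component in (0, 1).
#'
#' @param weights Numeric vector of three strictly positive, finite raw
#'   coefficients, in the order age, heart rate, PaO2 (names are optional and
#'   ignored beyond a sanity check).
#' @return A named numeric vector `c(k_age, k_heartrate, k_pao2)` summing
#'   to 1.
#' @examples
#' normalize_weights(c(2, 2, 4))
#' normalize_weights(c(0.5705, 0.2553, 0.1742))
#' @export
normalize_weights <- function(weights) {
  w <- check_weights(weights, require_positive = TRUE)
  out <- w / sum(w)
  names(out) <- weight_names()
  out
}

#' Expand reduced weight coordinates to a weight triple
#'
#' The normalized simplex has two free coordinates. The package uses
#' `x = k_age` and `y`, the relative weight of heart rate versus PaO2 within
#' the remainder, so that `k_heartrate = (1 - x) * y` and
#' `k_pao2 = (1 - x) * (1 - y)`. Both coordinates live on the open unit
#' interval, which turns the constrained weight search into an unconstrained
#' one over the unit square.
#'
#' @param x Age weight `k_age`, in (0, 1).
#' @param y Relative heart-rate-versus-PaO2 weight, in (0, 1).
#' @return A named numeric weight triple summing to 1 (up to floating error).
#' @seealso [reduce_weights()] for the inverse map.
#' @examples
#' expand_weights(0.5705, 0.5945)
#' @export
expand_weights <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != 1L || length(y) != 1L ||
      !is.finite(x) || !is.finite(y)) {
    abort("`x` and `y` must be single finite numbers.")
  }
  if (x <= 0 || x >= 1 || y <= 0 || y >= 1) {
    abort("Reduced weight coordinates must lie strictly inside (0, 1).")
  }
  out <- c(x, (1 - x) * y, (1 - x) * (1 - y))
  names(out) <- weight_names()
  out
}

#' Reduced coordinates of a weight triple
#'
#' Inverse of [expand_weights()]: renormalizes the triple and returns
#' `x = k_age` and `y = k_heartrate / (k_heartrate + k_pao2)`.
#'
#' @inheritParams normalize_weights
#' @return Named numeric vector `c(x, y)`.
#' @export
reduce_weights <- function(weights) {
  w <- normalize_weights(weights)
  c(x = unname(w[1L]), y = unname(w[2L] / (w[2L] + w[3L])))
}

#' Clinical equivalence ratios of a weight triple
#'
#' Under a linear score, a one-year increase in age moves the score by
#' `k_age`, so it is equivalent to a `k_age / k_heartrate` bpm increase in
#' heart rate, or a `k_age / k_pao2` mmHg decrease in PaO2. These ratios are
#' the interpretable summary of how the optimized score trades the three
#' parameters off against each other.
#'
#' @inheritParams normalize_weights
#' @return Named numeric vector `c(hr_per_age_year, pao2_per_age_year)`.
#' @examples
#' equivalence_ratios(c(0.5705, 0.2553, 0.1742))
#' @export
equivalence_ratios <- function(weights) {
  w <- check_weights(weights, require_positive = TRUE)
  c(hr_per_age_year = unname(w[1L] / w[2L]),
    pao2_per_age_year = unname(w[1L] / w[3L]))
}

weight_names <- function() c("k_age", "k_heartrate", "k_pao2")

# shared validation for 3-vectors of coefficients; raw (unnormalized) weights
# are accepted wherever only the induced patient ordering matters
check_weights <- function(weights, require_positive = FALSE) {
  if (!is.numeric(weights) || length(weights) != 3L) {
    abort("`weights` must be a numeric vector of length 3 (age, heart rate, PaO2).")
  }
  if (anyNA(weights) || any(!is.finite(weights))) {
    abort("`weights` must be finite and non-missing.")
  }
  if (require_positive && any(weights <= 0)) {
    abort("All weights must be strictly positive.")
  }
  unname(as.numeric(weights))
}
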
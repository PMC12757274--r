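#' Discrete PERFORM score
#'
#' The PERFORM score assigns category points to each of the three bedside
#' parameters and sums them. Bins (points 0 / 1 / 2 / 4):
#'
#' * age (years): `< 65`, `[65, 75)`, `[75, 85)`, `>= 85`
#' * heart rate (bpm): `< 75`, `[75, 85)`, `[85, 95)`, `>= 95`
#' * PaO2 (mmHg): `>= 80`, `[60, 80)`, `[40, 60)`, `< 40`
#'
#' The total lies in 0..12. Age and heart rate bins are closed on the left;
#' PaO2 bins are closed on the left of each *descending* interval, so a PaO2
#' of exactly 60 scores 1 and exactly 40 scores 2.
#'
#' @param age,heart_rate,pao2 Numeric vectors (recycled to a common length)
#'   of age in years, heart rate in beats/min, and PaO2 in mmHg. Missing or
#'   non-finite values are an error: incomplete records are excluded at
#'   cohort construction, not silently scored.
#' @return Integer vector of scores.
#' @examples
#' perform_score(75, 85, 59) # 6
#' perform_score(74, 84, 60) # 3
#' @export
perform_score <- function(age, heart_rate, pao2) {
  v <- recycle_covariates(age, heart_rate, pao2)
  age_pts <- c(0L, 1L, 2L, 4L)[findInterval(v$age, c(65, 75, 85)) + 1L]
  hr_pts <- c(0L, 1L, 2L, 4L)[findInterval(v$heart_rate, c(75, 85, 95)) + 1L]
  pao2_pts <- c(4L, 2L, 1L, 0L)[findInterval(v$pao2, c(40, 60, 80)) + 1L]
  age_pts + hr_pts + pao2_pts
}

#' Continuous CON-PERFORM score
#'
#' Evaluates `G = k_age * age + k_heartrate * heart_rate - k_pao2 * pao2` on
#' raw clinical units (no standardization). PaO2 enters negated because lower
#' oxygenation means higher risk. The score is ordinal: only the induced
#' patient ranking matters, and rescaling all weights by a positive constant
#' rescales every score by that constant without changing the ranking.
#'
#' @inheritParams perform_score
#' @param weights Length-3 numeric vector of finite weights in the order
#'   (age, heart rate, PaO2), e.g. from [normalize_weights()] or
#'   [expand_weights()]. Need not be normalized.
#' @return Numeric vector of scores at full precision (round to 2 decimals
#'   for reporting).
#' @examples
#' w <- c(0.5705, 0.2553, 0.1742)
#' con_perform_score(75, 85, 59, w) # 54.21
#' con_perform_score(74, 84, 60, w) # 53.21
#' @export
con_perform_score <- function(age, heart_rate, pao2, weights) {
  v <- recycle_covariates(age, heart_rate, pao2)
  w <- check_weights(weights)
  w[1L] * v$age + w[2L] * v$heart_rate - w[3L] * v$pao2
}

#' Append PERFORM and CON-PERFORM scores to a cohort
#'
#' @param data A data frame with columns `age`, `heart_rate`, `pao2`
#'   (the canonical cohort layout written by [read_cohort()] and
#'   [generate_cohort()]).
#' @inheritParams con_perform_score
#' @return The input as a tibble with columns `perform_score` and
#'   `con_perform_score` appended.
#' @examples
#' cohort <- generate_cohort(simulation_config(n = 20, seed = 1))
#' score_cohort(cohort, c(0.5705, 0.2553, 0.1742))
#' @export
score_cohort <- function(data, weights) {
  data <- check_cohort_frame(data)
  dplyr::mutate(
    data,
    perform_score = perform_score(.data$age, .data$heart_rate, .data$pao2),
    con_perform_score = con_perform_score(
      .data$age, .data$heart_rate, .data$pao2, weights
    )
  )
}

recycle_covariates <- function(age, heart_rate, pao2) {
  n <- max(length(age), length(heart_rate), length(pao2))
  v <- list(
    age = rep_len(as.numeric(age), n),
    heart_rate = rep_len(as.numeric(heart_rate), n),
    pao2 = rep_len(as.numeric(pao2), n)
  )
  bad <- !is.finite(v$age) | !is.finite(v$heart_rate) | !is.finite(v$pao2)
  if (any(bad)) {
    abort(sprintf(
      "Covariates must be complete and finite (%d offending record(s)); exclude incomplete records first.",
      sum(bad)
    ))
  }
  if (any(v$age < 0) || any(v$heart_rate <= 0) || any(v$pao2 <= 0)) {
    abort("age must be non-negative; heart_rate and pao2 must be positive.")
  }
  v
}

check_cohort_frame <- function(data, cols = c("age", "heart_rate", "pao2")) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(sprintf("`data` is missing required column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  tibble::as_tibble(data)
}
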
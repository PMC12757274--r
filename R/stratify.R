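#' Stratify a scored cohort into high- and low-risk groups
#'
#' Dichotomizes at an explicit threshold with the boundary convention
#' "high risk when `score >= threshold`". The threshold is always an
#' argument: published analyses of this score family report slightly
#' different cutoffs on overlapping data (55.6 and 56.2 appear for the same
#' cohort), so no value is privileged here.
#'
#' @param data Scored cohort tibble.
#' @param threshold Risk cutoff.
#' @param score Column holding the risk score (tidy-select, default
#'   `con_perform_score`).
#' @return The input tibble with a `risk_group` factor column
#'   (`"low"` / `"high"`).
#' @export
stratify_cohort <- function(data, threshold, score = con_perform_score) {
  if (!is.data.frame(data) || nrow(data) == 0L) {
    abort("`data` must be a non-empty data frame.")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold)) {
    abort("`threshold` must be a single finite number.")
  }
  scores <- dplyr::pull(data, {{ score }})
  if (anyNA(scores) || any(!is.finite(scores))) {
    abort("Scores must be finite for stratification.")
  }
  dplyr::mutate(
    tibble::as_tibble(data),
    risk_group = factor(ifelse(scores >= threshold, "high", "low"),
                        levels = c("low", "high"))
  )
}

#' 30-day outcome-state distribution at evaluation days
#'
#' Tabulates the three exhaustive clinical states — still hospitalized,
#' discharged, dead — at each evaluation day, per risk group when a
#' `risk_group` column is present. States are absorbing: a patient is dead
#' at day `t` when `day_of_death <= t`, discharged when
#' `day_of_discharge <= t`, and hospitalized otherwise (patients with no
#' recorded event within the 30-day window count as hospitalized at every
#' day). The three proportions sum to 1 at every day; dead and discharged
#' proportions are non-decreasing over days.
#'
#' @param data Cohort tibble with `day_of_death` and `day_of_discharge`
#'   columns (`NA` when the event did not occur), optionally `risk_group`.
#' @param days Evaluation days, default `c(10, 20, 30)`.
#' @return Tibble of class `cp_outcome_table` with columns `risk_group`
#'   (when grouped), `day`, `n`, `hospitalized`, `discharged`, `dead`.
#' @export
outcome_distribution <- function(data, days = c(10, 20, 30)) {
  if (!is.data.frame(data) || nrow(data) == 0L) {
    abort("`data` must be a non-empty data frame.")
  }
  for (col in c("day_of_death", "day_of_discharge")) {
    if (!col %in% names(data)) {
      abort(sprintf("`data` must contain `%s` (NA when the event did not occur).", col))
    }
  }
  both <- !is.na(data$day_of_death) & !is.na(data$day_of_discharge)
  if (any(both)) {
    abort("A record cannot carry both a death day and a discharge day.")
  }
  grouped <- "risk_group" %in% names(data)
  groups <- if (grouped) split(data, data$risk_group) else list(all = data)
  out <- purrr::imap_dfr(groups, function(g, label) {
    purrr::map_dfr(sort(days), function(t) {
      dead <- !is.na(g$day_of_death) & g$day_of_death <= t
      discharged <- !is.na(g$day_of_discharge) & g$day_of_discharge <= t
      tibble::tibble(
        risk_group = label,
        day = t,
        n = nrow(g),
        hospitalized = mean(!dead & !discharged),
        discharged = mean(discharged),
        dead = mean(dead)
      )
    })
  })
  if (!grouped) out$risk_group <- NULL
  class(out) <- c("cp_outcome_table", class(out))
  out
}

#' Cumulative mortality by a given day
#'
#' Fraction of the group with a recorded death on or before `day`; `day 30`
#' is the primary endpoint, `day 15` the secondary one.
#'
#' @param data Cohort tibble with a `day_of_death` column.
#' @param day Evaluation day (e.g. 15 or 30).
#' @return A single proportion.
#' @export
mortality_at <- function(data, day = 30) {
  if (!is.data.frame(data) || nrow(data) == 0L) {
    abort("`data` must be a non-empty data frame.")
  }
  if (!"day_of_death" %in% names(data)) {
    abort("`data` must contain `day_of_death`.")
  }
  mean(!is.na(data$day_of_death) & data$day_of_death <= day)
}
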
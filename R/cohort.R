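#' Read a patient cohort from a delimited file
#'
#' Reads a CSV/TSV export, renames columns to the canonical layout, applies
#' the listwise exclusion rules, and attaches an exclusion log. A record is
#' included only when age, heart rate and PaO2 are all present and finite;
#' no imputation is performed. Exclusion reasons, applied in order per
#' record, are:
#'
#' * `missing_heart_rate` — heart rate absent or non-finite
#' * `missing_blood_gas` — PaO2 absent or non-finite
#' * `left_before_discharge` — flagged as having left hospital before
#'   physician-approved discharge (only when such a column is mapped)
#' * `other_missing` — age or the outcome label unavailable
#'
#' The 30-day mortality label may be given directly (`died_30d`, logical or
#' 0/1) or derived from event days: when only `day_of_death` /
#' `day_of_discharge` are present, a death day of 30 or less marks an event.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Optional named character vector mapping canonical names
#'   to the file's column names, e.g.
#'   `c(age = "Age", heart_rate = "HR", pao2 = "PaO2", died_30d = "dead30")`.
#'   Canonical names: `id`, `age`, `heart_rate`, `pao2`, `died_30d`,
#'   `day_of_death`, `day_of_discharge`, `left_before_discharge`. Unmapped
#'   canonical names are looked up verbatim.
#' @param delim Field delimiter; `","` by default, use `"\t"` for TSV.
#' @return A tibble with columns `id`, `age`, `heart_rate`, `pao2`,
#'   `died_30d`, `day_of_death`, `day_of_discharge`, in file order, with an
#'   `exclusions` attribute (see [exclusion_report()]).
#' @export
read_cohort <- function(path, column_map = NULL, delim = ",") {
  if (!file.exists(path)) abort(sprintf("Cohort file not found: %s", path))
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  canonical <- c("id", "age", "heart_rate", "pao2", "died_30d",
                 "day_of_death", "day_of_discharge", "left_before_discharge")
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), canonical)
    if (length(unknown)) {
      abort(sprintf("Unknown canonical column(s) in `column_map`: %s.",
                    paste(unknown, collapse = ", ")))
    }
    missing_src <- setdiff(unname(column_map), names(raw))
    if (length(missing_src)) {
      abort(sprintf("Mapped column(s) absent from file: %s.",
                    paste(missing_src, collapse = ", ")))
    }
    raw <- dplyr::rename(raw, !!!rlang::set_names(column_map, names(column_map)))
  }
  for (col in c("age", "heart_rate", "pao2")) {
    if (!col %in% names(raw)) {
      abort(sprintf("Mandatory column `%s` not found; supply it via `column_map`.", col))
    }
  }
  build_cohort(raw)
}

# Exclusion + label derivation shared by read_cohort() and as_cohort()
build_cohort <- function(raw) {
  n <- nrow(raw)
  num <- function(col) {
    if (col %in% names(raw)) suppressWarnings(as.numeric(raw[[col]])) else rep(NA_real_, n)
  }
  age <- num("age")
  hr <- num("heart_rate")
  pao2 <- num("pao2")
  death_day <- num("day_of_death")
  discharge_day <- num("day_of_discharge")
  left <- if ("left_before_discharge" %in% names(raw)) {
    isTRUE_vec(raw$left_before_discharge)
  } else {
    rep(FALSE, n)
  }
  died <- if ("died_30d" %in% names(raw)) {
    as_binary_label(raw$died_30d)
  } else {
    # derive from event days: a recorded death day within the window is an event
    dplyr::case_when(
      !is.na(death_day) & death_day <= 30 ~ TRUE,
      !is.na(discharge_day) ~ FALSE,
      .default = NA
    )
  }

  both_days <- !is.na(death_day) & !is.na(discharge_day)
  if (any(both_days)) {
    abort(sprintf("%d record(s) carry both a death day and a discharge day.",
                  sum(both_days)))
  }
  bad_day <- (!is.na(death_day) & (death_day < 1 | death_day > 30)) |
    (!is.na(discharge_day) & (discharge_day < 1 | discharge_day > 30))
  if (any(bad_day)) abort("Event days must be integers in 1..30.")

  reason <- dplyr::case_when(
    !is.finite(hr) ~ "missing_heart_rate",
    !is.finite(pao2) ~ "missing_blood_gas",
    left ~ "left_before_discharge",
    !is.finite(age) | is.na(died) ~ "other_missing",
    .default = NA_character_
  )
  keep <- is.na(reason)
  if (!any(keep)) abort("No includable records after exclusions.")

  id <- if ("id" %in% names(raw)) as.character(raw$id) else sprintf("P%04d", seq_len(n))
  out <- tibble::tibble(
    id = id[keep],
    age = age[keep],
    heart_rate = hr[keep],
    pao2 = pao2[keep],
    died_30d = died[keep],
    day_of_death = as.integer(death_day[keep]),
    day_of_discharge = as.integer(discharge_day[keep])
  )
  reasons <- c("missing_heart_rate", "missing_blood_gas",
               "left_before_discharge", "other_missing")
  counts <- vapply(reasons, function(r) sum(reason == r, na.rm = TRUE), integer(1))
  attr(out, "exclusions") <- tibble::tibble(reason = reasons, n = unname(counts))
  out
}

#' Exclusion log of a cohort
#'
#' @param cohort A cohort tibble from [read_cohort()] or [as_cohort()].
#' @return A tibble with one row per exclusion reason
#'   (`missing_heart_rate`, `missing_blood_gas`, `left_before_discharge`,
#'   `other_missing`) and the count of records dropped for it.
#' @export
exclusion_report <- function(cohort) {
  ex <- attr(cohort, "exclusions")
  if (is.null(ex)) {
    ex <- tibble::tibble(
      reason = c("missing_heart_rate", "missing_blood_gas",
                 "left_before_discharge", "other_missing"),
      n = 0L
    )
  }
  ex
}

#' Coerce an in-memory data frame to a canonical cohort
#'
#' Applies the same exclusion rules and label derivation as [read_cohort()].
#'
#' @param data Data frame with (a subset of) the canonical columns.
#' @return Canonical cohort tibble with an `exclusions` attribute.
#' @export
as_cohort <- function(data) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  build_cohort(tibble::as_tibble(data))
}

#' Write a cohort to the canonical CSV layout
#'
#' @param cohort Cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- check_cohort_frame(cohort)
  cols <- intersect(
    c("id", "age", "heart_rate", "pao2", "died_30d",
      "day_of_death", "day_of_discharge"),
    names(cohort)
  )
  readr::write_csv(cohort[, cols], path, progress = FALSE)
  invisible(path)
}

#' Randomly split a cohort into training and validation sets
#'
#' Simple (optionally outcome-stratified) randomization. The training set
#' receives `round(ratio * n)` records — so 559 records at ratio 2/3 split
#' 373 / 186 — and the validation set the remainder; the partition is
#' disjoint, exhaustive, and reproducible under `seed`.
#'
#' @param cohort Cohort tibble (any data frame; rows are the unit).
#' @param ratio Training fraction, strictly between 0 and 1. Default 2/3.
#' @param seed Integer seed for the randomization list.
#' @param stratify If `TRUE`, split within each outcome class (requires a
#'   `died_30d` column) so the event rate is balanced across sets; per-class
#'   sizes are rounded, so the total training size may differ from
#'   `round(ratio * n)` by at most 1.
#' @return Named list of two tibbles, `training` and `validation`.
#' @export
split_cohort <- function(cohort, ratio = 2 / 3, seed = 1L, stratify = FALSE) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L) {
    abort("`cohort` must be a non-empty data frame.")
  }
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0 || ratio >= 1) {
    abort("`ratio` must lie strictly between 0 and 1.")
  }
  cohort <- tibble::as_tibble(cohort)
  n <- nrow(cohort)
  idx <- withr::with_seed(as.integer(seed), {
    if (stratify) {
      if (!"died_30d" %in% names(cohort)) {
        abort("Stratified splitting needs a `died_30d` column.")
      }
      unlist(lapply(split(seq_len(n), as.logical(cohort$died_30d)), function(rows) {
        sample(rows, round(ratio * length(rows)))
      }), use.names = FALSE)
    } else {
      sample.int(n, round(ratio * n))
    }
  })
  list(
    training = cohort[sort(idx), , drop = FALSE],
    validation = cohort[setdiff(seq_len(n), sort(idx)), , drop = FALSE]
  )
}

as_binary_label <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    out <- rep(NA, length(x))
    out[x %in% c(0, 1)] <- x[x %in% c(0, 1)] == 1
    return(out)
  }
  lx <- tolower(as.character(x))
  dplyr::case_when(
    lx %in% c("1", "true", "t", "yes", "dead", "died") ~ TRUE,
    lx %in% c("0", "false", "f", "no", "alive", "survived") ~ FALSE,
    .default = NA
  )
}

isTRUE_vec <- function(x) {
  out <- as_binary_label(x)
  out[is.na(out)] <- FALSE
  out
}
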
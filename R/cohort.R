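#' Read a patient manifest
#'
#' Loads a cohort manifest mapping tissue cores to patients and survival
#' labels. Each row describes one core; rows belonging to the same patient
#' must agree on the survival label (follow-up time in years and event
#' indicator, 1 = disease-specific death observed, 0 = censored).
#'
#' @param path Path to a CSV file with header
#'   `patient_id,core_id,time_years,event` (UTF-8, `.` decimal separator).
#' @return A cohort tibble with one row per patient: `patient_id`
#'   (character), `core_ids` (list of character vectors), `n_cores`
#'   (integer), `time_years` (double), `event` (integer in \{0, 1\}).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("patient_id,core_id,time_years,event",
#'              "P1,P1-A,4.3,1", "P1,P1-B,4.3,1"), f)
#' read_manifest(f)
#' @export
read_manifest <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  needed <- c("patient_id", "core_id", "time_years", "event")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Manifest is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "milsurv_format_error")
  }
  raw <- tibble::as_tibble(raw)
  raw$time_years <- suppressWarnings(as.numeric(raw$time_years))
  raw$event <- suppressWarnings(as.numeric(raw$event))
  validate_cohort_rows(raw)
  cohort <- raw |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      core_ids = list(unique(.data$core_id)),
      time_years = .data$time_years[1],
      event = as.integer(.data$event[1]),
      .groups = "drop"
    ) |>
    dplyr::mutate(n_cores = lengths(.data$core_ids), .after = "core_ids")
  new_cohort(cohort)
}

#' Build a cohort tibble from per-core records in memory
#'
#' Programmatic counterpart of [read_manifest()]: takes a data frame with
#' the manifest columns and applies the same validation and per-patient
#' aggregation.
#'
#' @param data Data frame with columns `patient_id`, `core_id`,
#'   `time_years`, `event`.
#' @return A cohort tibble (see [read_manifest()]).
#' @export
as_cohort <- function(data) {
  needed <- c("patient_id", "core_id", "time_years", "event")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "milsurv_format_error")
  }
  data <- tibble::as_tibble(data)
  data$patient_id <- as.character(data$patient_id)
  data$core_id <- as.character(data$core_id)
  validate_cohort_rows(data)
  cohort <- data |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      core_ids = list(unique(.data$core_id)),
      time_years = .data$time_years[1],
      event = as.integer(.data$event[1]),
      .groups = "drop"
    ) |>
    dplyr::mutate(n_cores = lengths(.data$core_ids), .after = "core_ids")
  new_cohort(cohort)
}

new_cohort <- function(x) {
  class(x) <- c("milsurv_cohort", class(x))
  x
}

validate_cohort_rows <- function(rows) {
  if (nrow(rows) == 0) return(invisible(rows))
  if (anyNA(rows$time_years) || anyNA(rows$event)) {
    abort("Non-numeric or missing time_years/event values in manifest.",
          class = "milsurv_validation_error")
  }
  if (any(rows$time_years < 0)) {
    abort("Follow-up time must be non-negative.",
          class = "milsurv_validation_error")
  }
  if (!all(rows$event %in% c(0, 1))) {
    abort("Event indicator must be 0 (censored) or 1 (event observed).",
          class = "milsurv_validation_error")
  }
  conflicted <- rows |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      ok = dplyr::n_distinct(.data$time_years) == 1 &&
        dplyr::n_distinct(.data$event) == 1,
      .groups = "drop"
    ) |>
    dplyr::filter(!.data$ok)
  if (nrow(conflicted) > 0) {
    abort(paste0("Conflicting survival labels for patient(s): ",
                 paste(conflicted$patient_id, collapse = ", ")),
          class = "milsurv_validation_error")
  }
  invisible(rows)
}

#' Drop patients with too few tissue cores
#'
#' Cohort-level filter retaining exactly the patients that have at least
#' `min_cores` cores, in their original order. The number of patients
#' removed is attached as attribute `n_removed` and reported via a message.
#'
#' @param cohort A cohort tibble from [read_manifest()] or [as_cohort()].
#' @param min_cores Minimum number of cores a patient must have (>= 1).
#' @param quiet Suppress the removal message.
#' @return The filtered cohort tibble, with attribute `n_removed`.
#' @export
filter_min_cores <- function(cohort, min_cores = 2L, quiet = FALSE) {
  stopifnot(is.numeric(min_cores), min_cores >= 1)
  keep <- cohort$n_cores >= min_cores
  out <- cohort[keep, , drop = FALSE]
  n_removed <- sum(!keep)
  if (!quiet && n_removed > 0) {
    message(n_removed, " patient(s) removed (fewer than ", min_cores,
            " cores); ", nrow(out), " retained.")
  }
  attr(out, "n_removed") <- n_removed
  out
}

#' Plan cross-validation folds with nested train/validation splits
#'
#' Produces a k-fold plan in which each fold holds out one test portion
#' (test-set sizes differ by at most one across folds, and the test sets
#' partition the cohort) and splits the remaining patients 70/30 into
#' training and validation sets. Assignment is a uniform random permutation
#' of patient ids under `seed`; optional stratification keeps the event
#' rate balanced across test folds.
#'
#' @param cohort Cohort tibble, or any data frame with a `patient_id`
#'   column (plus `event` if `stratify = TRUE`).
#' @param n_folds Number of folds (>= 2).
#' @param seed Integer seed making the plan reproducible.
#' @param val_prop Proportion of the non-test portion used for validation
#'   (validation gets the floor of `val_prop * n_nontest`).
#' @param stratify If `TRUE`, permute events and censored patients
#'   separately so each test fold has a near-balanced event count.
#' @return A fold-plan tibble with columns `patient_id`, `fold` (integer),
#'   `role` (`"train"`, `"val"` or `"test"`), one row per patient per fold,
#'   carrying attributes `n_folds` and `seed`.
#' @examples
#' cohort <- tibble::tibble(patient_id = sprintf("P%03d", 1:20))
#' plan <- make_folds(cohort, n_folds = 5, seed = 1)
#' dplyr::count(plan, fold, role)
#' @export
make_folds <- function(cohort, n_folds = 5L, seed = 1L, val_prop = 0.3,
                       stratify = FALSE) {
  ids <- as.character(cohort$patient_id)
  n <- length(ids)
  if (anyDuplicated(ids)) abort("patient_id values must be unique.")
  if (n_folds < 2) abort("n_folds must be at least 2.")
  if (n < n_folds) abort("Cohort smaller than the number of folds.")

  perm <- local_seeded(seed, {
    if (stratify && "event" %in% names(cohort)) {
      # events first, then censored: the round-robin below spreads each
      # stratum near-evenly across test folds
      ev <- as.integer(cohort$event)
      c(sample(which(ev == 1)), sample(which(ev == 0)))
    } else {
      sample.int(n)
    }
  })
  # round-robin test assignment over the permuted order gives sizes
  # differing by <= 1 (larger test sets land in the earlier folds)
  fold_of <- rep(seq_len(n_folds), length.out = n)
  test_fold <- integer(n)
  test_fold[perm] <- fold_of

  plans <- lapply(seq_len(n_folds), function(f) {
    is_test <- test_fold == f
    nontest_idx <- which(!is_test)
    # deterministic sub-split: reuse the global permutation order
    nontest_ord <- nontest_idx[order(match(nontest_idx, perm))]
    n_val <- floor(val_prop * length(nontest_ord))
    val_idx <- tail(nontest_ord, n_val)
    role <- rep("train", n)
    role[is_test] <- "test"
    role[val_idx] <- "val"
    tibble::tibble(patient_id = ids, fold = f, role = role)
  })
  plan <- dplyr::bind_rows(plans)
  attr(plan, "n_folds") <- as.integer(n_folds)
  attr(plan, "seed") <- as.integer(seed)
  class(plan) <- c("milsurv_fold_plan", class(plan))
  plan
}

#' Write / read a fold plan as CSV
#'
#' @param plan Fold-plan tibble from [make_folds()].
#' @param path Output CSV path (`patient_id,fold,role`).
#' @return `write_fold_plan()` returns `path` invisibly; `read_fold_plan()`
#'   returns the fold-plan tibble.
#' @export
write_fold_plan <- function(plan, path) {
  utils::write.csv(as.data.frame(plan[c("patient_id", "fold", "role")]),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fold_plan
#' @export
read_fold_plan <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(df) |>
    dplyr::mutate(patient_id = as.character(.data$patient_id),
                  fold = as.integer(.data$fold))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
local_seeded <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
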
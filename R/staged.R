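#' Three-stage statistical analysis of model predictions
#'
#' Replicates the staged protocol for assessing prognostic significance
#' of a risk model: Stage 1 uses the test split only, Stage 2 the test
#' and validation splits combined, Stage 3 the full cohort. Each stage
#' recomputes its own median cutoff from the patients it includes,
#' dichotomises predictions into high/low groups, runs univariate Cox
#' proportional-hazards regression on the high/low indicator (and, when
#' clinical covariates are supplied, a multivariate model alongside
#' them), and produces Kaplan-Meier curves per group. A stage with fewer
#' than two events is skipped with a warning.
#'
#' @param predictions Tibble `patient_id, risk` covering the full
#'   cohort.
#' @param labels Tibble `patient_id, time, event` (e.g. from
#'   [bag_labels()]; a cohort tibble with `time_years` also works).
#' @param plan Fold plan from [make_folds()].
#' @param fold Fold whose test/validation split defines Stages 1 and 2.
#' @param covariates Optional tibble of pre-dichotomised clinical
#'   indicator columns keyed by `patient_id` (e.g. age > 55, size >
#'   20 mm, nodal positivity, TIL < 30, grade).
#' @return Object of class `milsurv_staged`: `table` (tibble
#'   `stage, parameter, cutoff, n_high, n_low, hr, ci_low, ci_high,
#'   p_value, analysis`), `km` (per-stage KM curves), `stages` (the
#'   per-stage detail), of which `table` is also returned by `tidy()`.
#' @export
staged_analysis <- function(predictions, labels, plan, fold = 1L,
                            covariates = NULL) {
  if ("time_years" %in% names(labels) && !"time" %in% names(labels)) {
    labels <- dplyr::rename(labels, time = "time_years")
  }
  labels <- dplyr::select(tibble::as_tibble(labels),
                          "patient_id", "time", "event")
  data <- dplyr::inner_join(predictions, labels, by = "patient_id")
  roles <- dplyr::filter(plan, .data$fold == !!fold)
  data <- dplyr::left_join(data,
                           dplyr::select(roles, "patient_id", "role"),
                           by = "patient_id")

  stage_sets <- list(
    `1` = dplyr::filter(data, .data$role == "test"),
    `2` = dplyr::filter(data, .data$role %in% c("test", "val")),
    `3` = data
  )

  tables <- list()
  kms <- list()
  details <- list()
  for (stage in names(stage_sets)) {
    sd <- stage_sets[[stage]]
    if (sum(sd$event) < 2) {
      warn(paste0("Stage ", stage,
                  " has fewer than 2 events; skipped."))
      next
    }
    sd <- dichotomize_by_median(sd)
    cutoff <- attr(sd, "cutoff")
    high <- as.integer(sd$risk_group == "high")
    n_high <- sum(high)
    n_low <- sum(1 - high)

    row_uni <- if (n_high == 0 || n_low == 0) {
      tibble::tibble(stage = as.integer(stage), parameter = "risk_group",
                     cutoff = cutoff, n_high = n_high, n_low = n_low,
                     hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                     p_value = NA_real_, analysis = "univariate",
                     flag = "degenerate_grouping")
    } else {
      uni <- cox_fit(matrix(high, dimnames = list(NULL, "risk_group")),
                     sd$time, sd$event, mode = "univariate")
      tu <- tidy(uni)
      tibble::tibble(stage = as.integer(stage), parameter = "risk_group",
                     cutoff = cutoff, n_high = n_high, n_low = n_low,
                     hr = tu$hr, ci_low = tu$ci_low, ci_high = tu$ci_high,
                     p_value = tu$p_value, analysis = "univariate",
                     flag = tu$flag)
    }
    tables[[length(tables) + 1]] <- row_uni

    if (!is.null(covariates) && n_high > 0 && n_low > 0) {
      cov <- dplyr::inner_join(dplyr::select(sd, "patient_id"),
                               covariates, by = "patient_id")
      Xc <- cbind(risk_group = high,
                  as.matrix(cov[setdiff(names(cov), "patient_id")]))
      multi <- cox_fit(Xc, sd$time, sd$event, mode = "multivariate")
      tm <- tidy(multi)
      tables[[length(tables) + 1]] <- tibble::tibble(
        stage = as.integer(stage), parameter = tm$term, cutoff = cutoff,
        n_high = n_high, n_low = n_low, hr = tm$hr, ci_low = tm$ci_low,
        ci_high = tm$ci_high, p_value = tm$p_value,
        analysis = "multivariate", flag = tm$flag
      )
    }

    km <- kaplan_meier(sd$time, sd$event, group = sd$risk_group)
    kms[[length(kms) + 1]] <- dplyr::mutate(tibble::as_tibble(km),
                                            stage = as.integer(stage),
                                            .before = 1)
    details[[stage]] <- sd
  }

  structure(
    list(table = dplyr::bind_rows(tables), km = dplyr::bind_rows(kms),
         stages = details, fold = fold),
    class = "milsurv_staged"
  )
}

#' @export
print.milsurv_staged <- function(x, ...) {
  cat("<milsurv_staged> fold ", x$fold, ", ",
      length(x$stages), " stage(s)\n", sep = "")
  print(x$table, ...)
  invisible(x)
}

#' @describeIn staged_analysis Results table of a staged analysis.
#' @param x A `milsurv_staged` object.
#' @param ... Unused.
#' @method tidy milsurv_staged
#' @export
tidy.milsurv_staged <- function(x, ...) x$table

#' Write the staged results table / KM curves as CSV
#'
#' @param x A `milsurv_staged` object.
#' @param table_path,km_path Output CSV paths (`NULL` skips one).
#' @return `x`, invisibly.
#' @export
write_staged_results <- function(x, table_path = NULL, km_path = NULL) {
  if (!is.null(table_path)) {
    utils::write.csv(as.data.frame(x$table), table_path, row.names = FALSE)
  }
  if (!is.null(km_path)) {
    utils::write.csv(as.data.frame(x$km), km_path, row.names = FALSE)
  }
  invisible(x)
}
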
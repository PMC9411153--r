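#' Concordance index under right-censoring
#'
#' Fraction of permissible patient pairs whose predicted risk ordering
#' agrees with their survival ordering, with half credit for tied risks:
#' \deqn{\hat c = (C + R/2) / (C + D + R).}
#' A pair is permissible when the patient with the shorter observed time
#' experienced the event (so the ordering of the pair's failure times is
#' known); the pair is concordant when that patient has the strictly
#' higher risk, discordant when strictly lower, and a risk tie otherwise.
#' Pairs with equal observed times are not permissible. With
#' `pairs = "all"` censoring is ignored and every pair of distinct
#' observed times is counted — on fully observed data the two modes
#' coincide.
#'
#' @param risk Numeric risk scores (higher = predicted shorter survival).
#' @param time Observed follow-up times.
#' @param event Event indicators (1 = observed, 0 = censored).
#' @param pairs `"permissible"` (default; Harrell's convention) or
#'   `"all"` (censoring-blind).
#' @return A one-row tibble: `c_index`, counts `concordant`, `discordant`,
#'   `tied_risk`, and `n_permissible`.
#' @examples
#' concordance_index(risk = c(2, 1, 3), time = c(1, 2, 3),
#'                   event = c(1, 1, 1))
#' @export
concordance_index <- function(risk, time, event,
                              pairs = c("permissible", "all")) {
  pairs <- match.arg(pairs)
  check_survival_args(risk, time, event)
  if (length(risk) < 2) abort("At least two observations are required.")
  event <- as.integer(event)

  earlier <- outer(time, time, "<")                   # [i, j]: t_i < t_j
  permissible <- if (pairs == "permissible") {
    earlier & (event == 1L)                           # recycles over rows
  } else {
    earlier
  }
  if (!any(permissible)) {
    abort("No permissible pairs (no usable event ordering).",
          class = "milsurv_validation_error")
  }
  higher <- outer(risk, risk, ">")
  lower <- outer(risk, risk, "<")
  C <- sum(permissible & higher)
  D <- sum(permissible & lower)
  R <- sum(permissible) - C - D
  tibble::tibble(
    c_index = (C + R / 2) / (C + D + R),
    concordant = C, discordant = D, tied_risk = R,
    n_permissible = C + D + R
  )
}

#' Split predictions into high/low risk groups at the median
#'
#' The cutoff is the median of the supplied predictions; a patient is
#' `high` when the risk is strictly above the cutoff and `low` otherwise,
#' so with all-equal predictions everyone is `low`.
#'
#' @param data Data frame with a risk column.
#' @param risk Column holding the risk score (tidy-eval; default `risk`).
#' @return The input with an added factor column `risk_group` (levels
#'   `low`, `high`) and the cutoff in attribute `cutoff`.
#' @export
dichotomize_by_median <- function(data, risk = "risk") {
  r <- data[[risk]]
  if (length(r) < 2) abort("At least two predictions are required.")
  cutoff <- median(r)
  out <- dplyr::mutate(
    tibble::as_tibble(data),
    risk_group = factor(ifelse(r > cutoff, "high", "low"),
                        levels = c("low", "high"))
  )
  attr(out, "cutoff") <- cutoff
  out
}

#' Kaplan-Meier survival curves
#'
#' Product-limit estimate of the survival function per group, with
#' censored observations reducing the at-risk count without a step.
#'
#' @inheritParams concordance_index
#' @param group Optional grouping vector (one curve per level); a single
#'   curve when omitted.
#' @return Tibble `group, time, survival, at_risk, events`, beginning at
#'   `time = 0, survival = 1` for each group, of class `milsurv_km`.
#' @examples
#' kaplan_meier(time = c(1, 2, 3), event = c(1, 1, 0))
#' @export
kaplan_meier <- function(time, event, group = NULL) {
  if (is.null(group)) group <- rep("all", length(time))
  group <- as.character(group)  # empty factor levels carry no patients
  if (length(group) != length(time) || length(unique(group)) == 0) {
    abort("Each group must be non-empty.")
  }
  df <- data.frame(time = time, event = as.integer(event),
                   group = as.character(group))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) {
    rep(unique(df$group), length(sm$time))
  } else {
    sub("^group=", "", as.character(sm$strata))
  }
  curves <- tibble::tibble(
    group = grp, time = sm$time, survival = sm$surv,
    at_risk = sm$n.risk, events = sm$n.event
  )
  origin <- tibble::tibble(
    group = unique(curves$group), time = 0, survival = 1,
    at_risk = as.numeric(table(df$group)[unique(curves$group)]), events = 0
  )
  out <- dplyr::arrange(dplyr::bind_rows(origin, curves),
                        .data$group, .data$time)
  class(out) <- c("milsurv_km", class(out))
  out
}

#' Cox proportional-hazards regression via the shared partial likelihood
#'
#' Newton-Raphson maximisation of the Breslow partial likelihood, built on
#' the same loss/gradient code used to train the survival network
#' ([npll_loss()], [npll_gradient()]). Wald confidence intervals use
#' `exp(coef +/- 1.96 * SE)`.
#'
#' @param covariates Numeric matrix or data frame of covariates (one
#'   column per term).
#' @param time,event Survival outcome vectors.
#' @param mode `"multivariate"` fits all columns jointly;
#'   `"univariate"` fits each column in its own model.
#' @param tol Convergence tolerance on the change in partial
#'   log-likelihood.
#' @param max_iter Iteration cap; non-convergence is flagged, not an
#'   error.
#' @return Object of class `milsurv_cox`; see [tidy.milsurv_cox()] for the
#'   per-term table and [glance.milsurv_cox()] for the fit summary.
#' @export
cox_fit <- function(covariates, time, event,
                    mode = c("multivariate", "univariate"),
                    tol = 1e-8, max_iter = 100L) {
  mode <- match.arg(mode)
  X <- as.matrix(covariates)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  storage.mode(X) <- "double"
  if (anyNA(X) || any(!is.finite(X))) abort("Covariates must be finite.")
  if (sum(event) < 1) abort("At least one event is required.")

  if (mode == "univariate") {
    fits <- lapply(seq_len(ncol(X)), function(j) {
      cox_newton(X[, j, drop = FALSE], time, event, tol, max_iter)
    })
    terms <- dplyr::bind_rows(lapply(fits, `[[`, "table"))
    res <- list(
      table = terms, mode = mode,
      loglik = vapply(fits, `[[`, numeric(1), "loglik"),
      converged = all(vapply(fits, `[[`, logical(1), "converged")),
      n = length(time), n_events = sum(event)
    )
  } else {
    fit <- cox_newton(X, time, event, tol, max_iter)
    res <- list(
      table = fit$table, mode = mode, loglik = fit$loglik,
      converged = fit$converged, n = length(time), n_events = sum(event)
    )
  }
  structure(res, class = "milsurv_cox")
}

# One Newton-Raphson run on design matrix X. Minimises the NPLL using the
# shared gradient; the Hessian is the usual weighted covariance of
# covariates over each event's risk set.
cox_newton <- function(X, time, event, tol, max_iter) {
  p <- ncol(X)
  beta <- rep(0, p)
  event <- as.integer(event)
  ev_idx <- which(event == 1L)
  loss <- sum_npll(drop(X %*% beta), time, event)$loss
  converged <- FALSE
  flagged <- NULL
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    g_eta <- sum_npll(eta, time, event)$gradient
    grad <- drop(crossprod(X, g_eta))
    H <- cox_hessian(X, eta, time, ev_idx)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) {
      flagged <- "singular_hessian"
      break
    }
    # step-halving line search on the NPLL
    new_loss <- Inf
    for (h in 0:30) {
      cand <- beta - step / 2^h
      new_loss <- sum_npll(drop(X %*% cand), time, event)$loss
      if (is.finite(new_loss) && new_loss <= loss + 1e-12) break
    }
    delta <- loss - new_loss
    beta <- beta - step / 2^h
    loss <- new_loss
    if (abs(delta) < tol) {
      converged <- TRUE
      break
    }
  }
  if (any(abs(beta) > 15)) flagged <- "possible_separation"
  H <- cox_hessian(X, drop(X %*% beta), time, ev_idx)
  se <- tryCatch(sqrt(diag(solve(H))), error = function(e) rep(NA_real_, p))
  beta <- unname(beta)
  se <- unname(se)
  z <- beta / se
  tab <- tibble::tibble(
    term = colnames(X),
    estimate = beta,
    hr = exp(beta),
    se = se,
    ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se),
    p_value = 2 * pnorm(-abs(z)),
    converged = converged && is.null(flagged),
    flag = if (is.null(flagged)) NA_character_ else flagged
  )
  list(table = tab, loglik = -loss, converged = converged && is.null(flagged))
}

cox_hessian <- function(X, eta, time, ev_idx) {
  p <- ncol(X)
  H <- matrix(0, p, p)
  for (i in ev_idx) {
    rs <- which(time >= time[i])
    w <- exp(eta[rs] - max(eta[rs]))
    w <- w / sum(w)
    Xr <- X[rs, , drop = FALSE]
    mu <- drop(crossprod(Xr, w))
    H <- H + crossprod(Xr * sqrt(w)) - tcrossprod(mu)
  }
  H
}

#' @export
print.milsurv_cox <- function(x, ...) {
  cat("Cox proportional-hazards fit (", x$mode, "), n = ", x$n,
      ", events = ", x$n_events, "\n", sep = "")
  print(x$table, ...)
  invisible(x)
}

#' Tidy a Cox fit
#'
#' @param x A `milsurv_cox` object.
#' @param ... Unused.
#' @return Per-term tibble: `term`, `estimate` (log hazard ratio), `hr`,
#'   `se`, `ci_low`, `ci_high`, `p_value`, `converged`, `flag`.
#' @method tidy milsurv_cox
#' @export
tidy.milsurv_cox <- function(x, ...) x$table

#' One-row summary of a Cox fit
#'
#' @inheritParams tidy.milsurv_cox
#' @return Tibble with `n`, `n_events`, `loglik`, `converged`.
#' @method glance milsurv_cox
#' @export
glance.milsurv_cox <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events,
                 loglik = sum(x$loglik), converged = x$converged)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
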
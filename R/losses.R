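#' Cox negative partial log-likelihood of a risk vector
#'
#' The training loss for the survival network. For patients with observed
#' events it accumulates \eqn{-o_i + \log \sum_{j: t_j \ge t_i} e^{o_j}},
#' where the risk set contains every patient whose observed time is at
#' least \eqn{t_i} (Breslow convention for tied event times). Censored
#' patients contribute only through risk sets. The loss depends only on
#' the relative ordering of the observed times, is non-negative, and is
#' invariant to adding a constant to all risks.
#'
#' @param risk Numeric vector of risk scores (the model's linear output).
#' @param time Numeric vector of observed times, same length as `risk`.
#' @param event Integer/logical vector; 1 where the event was observed.
#' @return A single non-negative number; `0` when there are no events.
#' @examples
#' npll_loss(c(0, 0, 0), time = c(1, 2, 3), event = c(1, 0, 1)) # log(3)
#' @export
npll_loss <- function(risk, time, event) {
  check_survival_args(risk, time, event)
  sum_npll(risk, time, event)$loss
}

#' Gradient of the negative partial log-likelihood
#'
#' Analytic gradient of [npll_loss()] with respect to the risk vector,
#' used by the training loop and the Cox fitter (which share this code
#' path).
#'
#' @inheritParams npll_loss
#' @return Numeric vector of the same length as `risk`.
#' @export
npll_gradient <- function(risk, time, event) {
  check_survival_args(risk, time, event)
  sum_npll(risk, time, event)$gradient
}

check_survival_args <- function(risk, time, event) {
  if (length(risk) != length(time) || length(risk) != length(event)) {
    abort("risk, time and event must have equal length.")
  }
  if (length(risk) < 1) abort("At least one observation is required.")
  if (anyNA(risk) || any(!is.finite(risk))) {
    abort("Non-finite risk score.", class = "milsurv_validation_error")
  }
  invisible(TRUE)
}

# Loss, gradient and (optionally) per-event softmax weights of the
# Breslow partial likelihood, computed with a stable log-sum-exp.
sum_npll <- function(risk, time, event) {
  event <- as.integer(event)
  n <- length(risk)
  loss <- 0
  grad <- -as.numeric(event)
  ev_idx <- which(event == 1L)
  for (i in ev_idx) {
    rs <- which(time >= time[i])
    m <- max(risk[rs])
    w <- exp(risk[rs] - m)
    sw <- sum(w)
    loss <- loss + (-risk[i] + m + log(sw))
    grad[rs] <- grad[rs] + w / sw
  }
  list(loss = loss, gradient = grad)
}

#' Pairwise ranking loss on a pair of risk scores
#'
#' The refinement loss \eqn{-\log \sigma(o_i - o_j)} for an ordered pair
#' in which patient *i* experienced the event before patient *j* was
#' observed, with \eqn{\sigma} the logistic function. Strictly decreasing
#' in the risk margin \eqn{o_i - o_j}.
#'
#' @param risk_i,risk_j Risk scores; patient *i* should out-rank *j*.
#' @return Positive numeric (vectorised over pairs).
#' @examples
#' rank_loss(0, 0)        # log 2
#' rank_loss(1, 0)        # log(1 + exp(-1))
#' @export
rank_loss <- function(risk_i, risk_j) {
  # -log sigma(u) = log(1 + exp(-u)), computed stably
  u <- risk_i - risk_j
  log1p(exp(-abs(u))) + pmax(-u, 0)
}

# d/du of -log sigma(u) = sigma(u) - 1 = -sigma(-u)
rank_loss_grad_margin <- function(risk_i, risk_j) {
  u <- risk_i - risk_j
  -1 / (1 + exp(u))
}

#' Enumerate comparable patient pairs under right-censoring
#'
#' A pair `(i, j)` is comparable when patient *i*'s event was observed and
#' occurred strictly before patient *j*'s observed time: patient *i* is
#' then known to have failed first and should receive the higher risk.
#'
#' @inheritParams npll_loss
#' @return Tibble with integer columns `i`, `j` (indices into the input
#'   vectors); zero rows when no pair is comparable.
#' @examples
#' comparable_pairs(time = c(1, 2, 3), event = c(1, 0, 1))
#' @export
comparable_pairs <- function(time, event) {
  event <- as.integer(event)
  ev <- which(event == 1L)
  if (length(ev) == 0) {
    return(tibble::tibble(i = integer(), j = integer()))
  }
  pairs <- purrr::map(ev, function(i) {
    j <- which(time > time[i])
    if (length(j) == 0) return(NULL)
    tibble::tibble(i = i, j = j)
  })
  out <- dplyr::bind_rows(pairs)
  if (nrow(out) == 0) tibble::tibble(i = integer(), j = integer()) else out
}

#' Risk sets of a cohort
#'
#' For each patient with an observed event, the indices of patients whose
#' observed time is at least that event time (the Breslow risk set used by
#' the partial likelihood).
#'
#' @inheritParams npll_loss
#' @return Tibble with columns `i` (event index) and `risk_set` (list of
#'   integer vectors).
#' @export
risk_sets <- function(time, event) {
  ev <- which(as.integer(event) == 1L)
  tibble::tibble(
    i = ev,
    risk_set = purrr::map(ev, function(i) which(time >= time[i]))
  )
}
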
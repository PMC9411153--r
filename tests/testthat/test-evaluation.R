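test_that("concordance index handles perfect, tied and mixed orderings", {
  # risks perfectly anti-ordered with event times, all events
  r <- concordance_index(risk = c(5, 4, 3, 2), time = 1:4,
                         event = rep(1, 4))
  expect_equal(r$c_index, 1)
  expect_equal(r$discordant, 0)

  # all risks equal: every permissible pair is a risk tie
  r <- concordance_index(risk = rep(2, 5), time = 1:5, event = rep(1, 5))
  expect_equal(r$c_index, 0.5)
  expect_equal(r$tied_risk, r$n_permissible)

  # hand-enumerated 3-patient case
  r <- concordance_index(risk = c(2, 1, 3), time = c(1, 2, 3),
                         event = c(1, 1, 1))
  expect_equal(r$concordant, 1)
  expect_equal(r$discordant, 2)
  expect_equal(r$tied_risk, 0)
  expect_equal(r$c_index, 1 / 3)
})

test_that("concordance matches the brute-force enumerator on random cohorts", {
  set.seed(12)
  for (rep in 1:40) {
    n <- sample(2:200, 1)
    risk <- sample(rnorm(max(2, n %/% 2)), n, replace = TRUE) # force ties
    time <- rexp(n)
    event <- rbinom(n, 1, 0.7)
    if (sum(event) == 0) event[which.min(time)] <- 1L
    fast <- concordance_index(risk, time, event)
    slow <- brute_force_cindex(risk, time, event)
    expect_identical(fast$concordant, slow$C)
    expect_identical(fast$discordant, slow$D)
    expect_identical(fast$tied_risk, slow$R)
    expect_equal(fast$c_index, slow$c_index)
  }
})

test_that("negating risks mirrors the c-index when no risks tie", {
  set.seed(3)
  risk <- rnorm(60)
  time <- rexp(60)
  event <- rbinom(60, 1, 0.6)
  a <- concordance_index(risk, time, event)
  b <- concordance_index(-risk, time, event)
  expect_equal(a$tied_risk, 0)
  expect_equal(a$c_index + b$c_index, 1)
})

test_that("censoring-blind mode coincides with permissible pairs on fully observed data", {
  set.seed(8)
  risk <- rnorm(40)
  time <- rexp(40)
  ev1 <- rep(1, 40)
  expect_equal(concordance_index(risk, time, ev1, pairs = "all"),
               concordance_index(risk, time, ev1))
  expect_error(concordance_index(1:3, c(2, 2, 2), c(1, 1, 1)),
               class = "milsurv_validation_error")
})

test_that("median dichotomisation uses a strict upper cut", {
  d <- tibble::tibble(risk = c(0.1, 0.2, 0.3, 0.4))
  out <- dichotomize_by_median(d)
  expect_equal(attr(out, "cutoff"), 0.25)
  expect_equal(out$risk[out$risk_group == "high"], c(0.3, 0.4))

  allsame <- dichotomize_by_median(tibble::tibble(risk = rep(1, 6)))
  expect_true(all(allsame$risk_group == "low"))

  set.seed(2)
  many <- dichotomize_by_median(tibble::tibble(risk = rnorm(240)))
  counts <- table(many$risk_group)
  expect_equal(sum(counts), 240)
  expect_lte(abs(counts[["high"]] - counts[["low"]]), 1)
})

test_that("Kaplan-Meier curves follow the product-limit computation", {
  km <- kaplan_meier(time = c(1, 2, 3), event = c(1, 1, 0))
  expect_equal(km$survival, c(1, 2 / 3, 1 / 3, 1 / 3))
  expect_equal(km$time, c(0, 1, 2, 3))

  flat <- kaplan_meier(time = c(1, 2, 3), event = c(0, 0, 0))
  expect_true(all(flat$survival == 1))

  one <- kaplan_meier(time = 2, event = 1)
  expect_equal(one$survival, c(1, 0))

  # non-increasing within each group, bounded in [0, 1]
  set.seed(4)
  km2 <- kaplan_meier(rexp(50), rbinom(50, 1, 0.5),
                      group = sample(c("a", "b"), 50, TRUE))
  for (g in c("a", "b")) {
    s <- km2$survival[km2$group == g]
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
  }
})

test_that("Cox fitter finds the partial-likelihood maximiser of a 10-patient toy", {
  set.seed(21)
  x <- rnorm(10)
  time <- rexp(10, exp(0.9 * x) * 0.3)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 1)
  fit <- cox_fit(matrix(x, dimnames = list(NULL, "x")), time, event)
  # grid scan of the partial likelihood
  grid <- seq(-4, 4, by = 1e-4)
  nll <- vapply(grid, function(b) npll_loss(b * x, time, event),
                numeric(1))
  expect_equal(tidy(fit)$estimate, grid[which.min(nll)], tolerance = 1e-4)
  # fitter's loglik equals the negated loss at the maximiser
  expect_equal(glance(fit)$loglik,
               -npll_loss(tidy(fit)$estimate * x, time, event),
               tolerance = 1e-6)
})

test_that("Cox fitter agrees with the survival package under Breslow ties", {
  set.seed(14)
  n <- 250
  X <- cbind(bin = rbinom(n, 1, 0.5), cont = rnorm(n))
  tt <- round(rexp(n, 0.2 * exp(0.7 * X[, 1] - 0.5 * X[, 2])), 1) # ties
  cens <- rexp(n, 0.08)
  time <- pmin(tt, cens)
  event <- as.integer(tt <= cens)
  mine <- tidy(cox_fit(X, time, event))
  ref <- survival::coxph(survival::Surv(time, event) ~ X,
                         ties = "breslow")
  expect_equal(mine$estimate, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(mine$se, unname(sqrt(diag(vcov(ref)))), tolerance = 1e-5)
})

test_that("simulated hazard ratios are recovered and nulls behave", {
  set.seed(33)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  tt <- rexp(n, 0.1 * exp(log(3) * x))
  cens <- rexp(n, 0.055)   # roughly 30% censoring
  time <- pmin(tt, cens)
  event <- as.integer(tt <= cens)
  expect_lt(abs(mean(1 - event) - 0.3), 0.07)
  fit <- tidy(cox_fit(matrix(x, dimnames = list(NULL, "x")), time, event))
  expect_lt(abs(fit$estimate - log(3)), 0.15)

  # independent covariate: HR near 1 and p > 0.05 in >= 90% of replicates
  ok <- vapply(1:100, function(r) {
    xx <- rnorm(500)
    t2 <- rexp(500, 0.2)
    c2 <- rexp(500, 0.08)
    f <- tidy(cox_fit(matrix(xx, dimnames = list(NULL, "x")),
                      pmin(t2, c2), as.integer(t2 <= c2)))
    f$hr > 0.8 && f$hr < 1.25 && f$p_value > 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("staged analysis recomputes cutoffs per stage and flags degeneracy", {
  set.seed(6)
  sim <- simulate_cohort(sim_config(n_patients = 120, d = 8,
                                    instances_range = c(5L, 8L),
                                    seed = 19))
  plan <- make_folds(sim$truth, n_folds = 5, seed = 19)
  preds <- dplyr::transmute(sim$truth, patient_id,
                            risk = true_risk + rnorm(120, sd = 0.2))
  res <- staged_analysis(preds, sim$truth, plan, fold = 1)
  tab <- tidy(res)
  uni <- dplyr::filter(tab, analysis == "univariate")
  expect_equal(sort(uni$stage), 1:3)
  # different patient subsets give different median cutoffs
  expect_gt(length(unique(uni$cutoff)), 1)
  # the true risk drives hazard: stage 3 CI excludes 1
  s3 <- dplyr::filter(uni, stage == 3)
  expect_gt(s3$hr, 1)
  expect_gt(s3$ci_low, 1)
  expect_true(all(res$km$survival >= 0 & res$km$survival <= 1))

  # constant predictions: everyone low, univariate flagged degenerate
  const <- dplyr::mutate(preds, risk = 1)
  res2 <- suppressWarnings(staged_analysis(const, sim$truth, plan,
                                           fold = 1))
  expect_true(all(tidy(res2)$flag == "degenerate_grouping"))
})

test_that("multivariate staged analysis includes supplied covariates", {
  set.seed(40)
  sim <- simulate_cohort(sim_config(n_patients = 100, d = 6,
                                    instances_range = c(4L, 6L),
                                    seed = 23))
  plan <- make_folds(sim$truth, n_folds = 5, seed = 23)
  preds <- dplyr::transmute(sim$truth, patient_id, risk = true_risk)
  covs <- tibble::tibble(patient_id = sim$truth$patient_id,
                         age_gt_55 = rbinom(100, 1, 0.5))
  res <- staged_analysis(preds, sim$truth, plan, fold = 1,
                         covariates = covs)
  multi <- dplyr::filter(tidy(res), analysis == "multivariate")
  expect_setequal(unique(multi$parameter), c("risk_group", "age_gt_55"))
})
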
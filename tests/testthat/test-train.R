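make_training_setup <- function(n = 24, seed = 2) {
  sim <- simulate_cohort(sim_config(n_patients = n, d = 6,
                                    instances_range = c(4L, 7L),
                                    seed = seed))
  plan <- make_folds(sim$truth, n_folds = 3, seed = seed)
  list(sim = sim, plan = plan)
}

test_that("training is reproducible for a fixed seed", {
  su <- make_training_setup()
  cfg <- train_config(learning_rate = 1e-3, epochs = 6,
                      rank_loss_start_epoch = 3, seed = 4)
  f1 <- mil_train(su$sim$bags, su$plan, fold = 1, config = cfg,
                  variant = "instance", M = 4, L = 4, hidden = 3)
  f2 <- mil_train(su$sim$bags, su$plan, fold = 1, config = cfg,
                  variant = "instance", M = 4, L = 4, hidden = 3)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$params, f2$params)
  expect_equal(names(f1$log),
               c("epoch", "train_npll", "train_rank", "val_cindex"))
  # ranking term activates on schedule
  expect_true(all(is.na(f1$log$train_rank[1:2])))
  expect_true(all(!is.na(f1$log$train_rank[3:6])))
})

test_that("training reduces the partial-likelihood loss", {
  su <- make_training_setup(n = 30, seed = 6)
  cfg <- train_config(learning_rate = 1e-3, epochs = 25,
                      rank_loss_weight = 0, seed = 1)
  fit <- mil_train(su$sim$bags, su$plan, fold = 1, config = cfg,
                   variant = "instance", M = 4, L = 4, hidden = 3)
  expect_lt(dplyr::last(fit$log$train_npll), fit$log$train_npll[1])
})

test_that("a training split without events is rejected", {
  bags <- toy_bags(6, n = 4, d = 3)
  for (i in seq_along(bags)) bags[[i]]$event <- 0L
  plan <- make_folds(bag_labels(bags), n_folds = 2, seed = 1)
  expect_error(
    mil_train(bags, plan, fold = 1,
              config = train_config(epochs = 2, rank_loss_start_epoch = 1,
                                    seed = 1),
              variant = "instance", M = 2, L = 2, hidden = 2),
    class = "milsurv_validation_error"
  )
})

test_that("clustered and instance variants both train and predict", {
  su <- make_training_setup(n = 24, seed = 9)
  cfg <- train_config(learning_rate = 1e-3, epochs = 4,
                      rank_loss_start_epoch = 2, seed = 2)
  for (variant in c("instance", "clustered")) {
    fit <- mil_train(su$sim$bags, su$plan, fold = 1, config = cfg,
                     variant = variant, k = 3, M = 4, L = 4, hidden = 3)
    preds <- predict(fit, su$sim$bags)
    expect_equal(nrow(preds), 24)
    expect_true(all(is.finite(preds$risk)))
    att_len <- vapply(preds$attention, length, integer(1))
    if (variant == "instance") {
      expect_equal(att_len,
                   vapply(su$sim$bags, function(b) nrow(b$instances),
                          integer(1)),
                   ignore_attr = TRUE)
    } else {
      expect_true(all(att_len <= 3))
    }
    expect_equal(vapply(preds$attention, sum, numeric(1)),
                 rep(1, 24), tolerance = 1e-6)
    g <- glance(fit)
    expect_equal(g$variant, variant)
  }
})

test_that("dropout perturbs training but not inference", {
  su <- make_training_setup(n = 20, seed = 12)
  cfg <- train_config(learning_rate = 1e-3, epochs = 3, seed = 3,
                      rank_loss_start_epoch = 1)
  fit <- mil_train(su$sim$bags, su$plan, fold = 1, config = cfg,
                   variant = "instance", M = 4, L = 4, hidden = 3,
                   dropout_rate = 0.5)
  p1 <- predict(fit, su$sim$bags[1])
  p2 <- predict(fit, su$sim$bags[1])
  expect_identical(p1$risk, p2$risk)
})

test_that("minibatch scheme forms risk sets within batches and still learns", {
  su <- make_training_setup(n = 30, seed = 21)
  cfg <- train_config(learning_rate = 1e-3, epochs = 8,
                      rank_loss_start_epoch = 4,
                      batch_scheme = "minibatch", batch_size = 8,
                      seed = 5)
  fit <- mil_train(su$sim$bags, su$plan, fold = 1, config = cfg,
                   variant = "instance", M = 4, L = 4, hidden = 3)
  expect_equal(nrow(fit$log), 8)
  expect_true(all(is.finite(fit$log$train_npll)))
})

test_that("with no signal the held-out c-index stays near chance", {
  sim <- simulate_cohort(sim_config(n_patients = 60, d = 8,
                                    instances_range = c(5L, 8L),
                                    signal_fraction = 0, seed = 31))
  plan <- make_folds(sim$truth, n_folds = 3, seed = 31)
  cfg <- train_config(learning_rate = 1e-3, epochs = 30,
                      rank_loss_start_epoch = 15, seed = 7)
  fit <- mil_train(sim$bags, plan, fold = 1, config = cfg,
                   variant = "instance", M = 4, L = 8, hidden = 4)
  roles <- dplyr::filter(plan, fold == 1)
  test_ids <- roles$patient_id[roles$role == "test"]
  preds <- predict(fit, sim$bags[test_ids])
  lab <- bag_labels(sim$bags[test_ids])
  ci <- concordance_index(preds$risk, lab$time, lab$event)$c_index
  expect_gt(ci, 0.2)
  expect_lt(ci, 0.8)
})

test_that("minimising the bag-level NPLL recovers the Cox solution on singleton bags", {
  # bags of one instance whose single feature is the covariate: the
  # network reduces to a monotone transform of x, so the dichotomised
  # ordering must match a linear Cox fit's ordering
  set.seed(55)
  n <- 40
  x <- rnorm(n)
  tt <- rexp(n, 0.3 * exp(1.2 * x))
  bags <- lapply(seq_len(n), function(i) {
    patient_bag(sprintf("S%02d", i), matrix(x[i], 1, 1), time = tt[i],
                event = 1L, d = 1)
  })
  plan <- tibble::tibble(patient_id = rep(sprintf("S%02d", 1:n), 1),
                         fold = 1L,
                         role = rep(c("train", "val"), c(30, 10)))
  cfg <- train_config(learning_rate = 5e-3, epochs = 120,
                      rank_loss_weight = 0, weight_decay = 0,
                      seed = 8)
  fit <- mil_train(bags, plan, fold = 1, config = cfg,
                   variant = "instance", M = 4, L = 4, hidden = 3)
  o <- predict(fit, bags)$risk
  # compare against the linear Cox partial-likelihood estimate: risk
  # ordering should agree with beta_hat * x for nearly all pairs
  cox <- tidy(cox_fit(matrix(x, dimnames = list(NULL, "x")), tt,
                      rep(1L, n)))
  agreement <- concordance_index(o, -cox$estimate * x,
                                 rep(1L, n))$c_index
  expect_gt(agreement, 0.85) # o increases where the Cox risk increases
})
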
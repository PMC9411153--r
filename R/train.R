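#' Training configuration
#'
#' Holds the optimiser settings and loss schedule for [mil_train()]. The
#' model is first trained on the Cox negative partial log-likelihood
#' alone; from `rank_loss_start_epoch` onwards a pairwise ranking term
#' (mean over comparable pairs, weighted by `rank_loss_weight`) is added
#' to refine the ordering.
#'
#' @param learning_rate Adam learning rate. `NULL` resolves per model
#'   variant at training time: 1e-5 for the clustered variant and 2e-5
#'   for the instance-level variant.
#' @param weight_decay L2 weight decay added to the gradients
#'   (default 5e-3).
#' @param epochs Number of epochs.
#' @param rank_loss_start_epoch Epoch (1-based) from which the ranking
#'   term is active; must not exceed `epochs`.
#' @param rank_loss_weight Weight of the ranking term in the total loss.
#' @param batch_scheme `"full"` (entire training split per step, so risk
#'   sets are exact) or `"minibatch"` (risk sets formed within each
#'   batch).
#' @param batch_size Bags per mini-batch when `batch_scheme = "minibatch"`.
#' @param max_pairs Comparable pairs are uniformly subsampled (seeded)
#'   when they exceed this cap.
#' @param seed Seed controlling initialisation, shuffling and dropout.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = NULL, weight_decay = 5e-3,
                         epochs = 100L, rank_loss_start_epoch = 10L,
                         rank_loss_weight = 1.0,
                         batch_scheme = c("full", "minibatch"),
                         batch_size = 32L, max_pairs = 10000L, seed = 1L) {
  batch_scheme <- match.arg(batch_scheme)
  if (!is.null(learning_rate) && learning_rate <= 0) {
    abort("learning_rate must be positive.")
  }
  if (rank_loss_start_epoch < 0 || rank_loss_start_epoch > epochs) {
    abort("rank_loss_start_epoch must lie in [0, epochs].")
  }
  structure(
    list(learning_rate = learning_rate, weight_decay = weight_decay,
         epochs = as.integer(epochs),
         rank_loss_start_epoch = as.integer(rank_loss_start_epoch),
         rank_loss_weight = rank_loss_weight, batch_scheme = batch_scheme,
         batch_size = as.integer(batch_size),
         max_pairs = as.integer(max_pairs), seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Train the attention-MIL survival network
#'
#' Optimises the network with Adam on the negative partial log-likelihood
#' (plus the ranking refinement once scheduled) over the training split,
#' tracking the concordance index on the validation split each epoch; the
#' parameters with the highest validation c-index are kept (ties broken
#' by the earlier epoch). Fully reproducible for a fixed seed.
#'
#' @param bags List of [patient_bag()] objects (the whole cohort).
#' @param plan Fold plan from [make_folds()], or any tibble with columns
#'   `patient_id`, `fold`, `role`.
#' @param fold Which fold of the plan to train on.
#' @param config [train_config()].
#' @param variant `"instance"` (attention per instance; Model 2 style) or
#'   `"clustered"` (attention per k-means phenotype; Model 1 style).
#' @param k Number of phenotype clusters (clustered variant only).
#' @param params Optional pre-built [mil_params()]; by default built from
#'   the bags' dimensions with `M = 64`, `L = 128`.
#' @param ... Passed to [mil_params()] when `params` is `NULL`.
#' @return Object of class `mil_fit`: best `params`, training `log`
#'   (tibble `epoch, train_npll, train_rank, val_cindex`), `best_epoch`,
#'   the configuration, and the split ids.
#' @export
mil_train <- function(bags, plan, fold = 1L, config = train_config(),
                      variant = c("instance", "clustered"), k = 10L,
                      params = NULL, ...) {
  variant <- match.arg(variant)
  roles <- dplyr::filter(plan, .data$fold == !!fold)
  if (nrow(roles) == 0) abort("Fold not present in the plan.")
  ids <- vapply(bags, `[[`, character(1), "patient_id")
  names(bags) <- ids
  train_ids <- roles$patient_id[roles$role == "train"]
  val_ids <- roles$patient_id[roles$role == "val"]
  missing_ids <- setdiff(c(train_ids, val_ids), ids)
  if (length(missing_ids) > 0) {
    abort(paste0("Plan refers to patients without bags: ",
                 paste(head(missing_ids, 5), collapse = ", ")))
  }
  lr <- config$learning_rate %||%
    (if (variant == "clustered") 1e-5 else 2e-5)

  train_bags <- bags[train_ids]
  val_bags <- bags[val_ids]
  lab <- bag_labels(train_bags)
  if (sum(lab$event) == 0) {
    abort("No events in the training split; the partial likelihood is degenerate.",
          class = "milsurv_validation_error")
  }

  if (is.null(params)) {
    bag1 <- train_bags[[1]]
    params <- mil_params(d = bag1$d, grid = bag1$grid,
                         seed = config$seed, ...)
  }

  # fixed per-bag unit grouping: identity for the instance variant,
  # per-patient k-means phenotypes for the clustered variant
  unit_of <- function(b, which_seed) {
    if (variant == "instance") seq_len(nrow(b$instances))
    else cluster_bag(b, k = k, seed = which_seed)$assignment
  }
  train_units <- purrr::imap(train_bags, ~ unit_of(.x, config$seed + 1L))
  val_units <- purrr::imap(val_bags, ~ unit_of(.x, config$seed + 1L))

  pairs <- comparable_pairs(lab$time, lab$event)
  if (nrow(pairs) > config$max_pairs) {
    keep <- local_seeded(config$seed + 2L,
                         sample.int(nrow(pairs), config$max_pairs))
    pairs <- pairs[keep, ]
  }

  opt <- adam_state(params)
  best <- list(cindex = -Inf, epoch = NA_integer_, params = params)
  log <- vector("list", config$epochs)
  n_train <- length(train_bags)

  for (epoch in seq_len(config$epochs)) {
    batches <- if (config$batch_scheme == "full") {
      list(seq_len(n_train))
    } else {
      ord <- local_seeded(config$seed + 100L + epoch, sample.int(n_train))
      split(ord, ceiling(seq_along(ord) / config$batch_size))
    }
    use_rank <- epoch >= config$rank_loss_start_epoch &&
      config$rank_loss_weight > 0 && nrow(pairs) > 0
    epoch_npll <- 0
    epoch_rank <- 0

    for (batch in batches) {
      bb <- train_bags[batch]
      masks <- dropout_masks(bb, train_units[batch], params,
                             config$seed, epoch)
      fwd <- purrr::pmap(list(bb, train_units[batch], masks),
                         function(b, u, m) {
                           mil_forward(b$instances, u, params,
                                       dropout_mask = m)
                         })
      o <- vapply(fwd, `[[`, numeric(1), "o")
      t_b <- lab$time[batch]
      e_b <- lab$event[batch]
      part <- sum_npll(o, t_b, e_b)
      do <- part$gradient
      epoch_npll <- epoch_npll + part$loss

      if (use_rank) {
        pb <- if (config$batch_scheme == "full") {
          pairs
        } else {
          li <- match(pairs$i, batch)
          lj <- match(pairs$j, batch)
          ok <- !is.na(li) & !is.na(lj)
          tibble::tibble(i = li[ok], j = lj[ok])
        }
        if (nrow(pb) > 0) {
          rl <- rank_loss(o[pb$i], o[pb$j])
          gm <- config$rank_loss_weight *
            rank_loss_grad_margin(o[pb$i], o[pb$j]) / nrow(pb)
          epoch_rank <- epoch_rank + mean(rl)
          add_i <- rowsum(gm, pb$i)
          add_j <- rowsum(gm, pb$j)
          do[as.integer(rownames(add_i))] <-
            do[as.integer(rownames(add_i))] + drop(add_i)
          do[as.integer(rownames(add_j))] <-
            do[as.integer(rownames(add_j))] - drop(add_j)
        }
      }

      grads <- zero_grads(params)
      for (bi in seq_along(fwd)) {
        g <- mil_backward(fwd[[bi]]$cache, do[bi], params)
        for (nm in trainable_names) grads[[nm]] <- grads[[nm]] + g[[nm]]
      }
      for (nm in trainable_names) {
        grads[[nm]] <- grads[[nm]] + config$weight_decay * params[[nm]]
      }
      upd <- adam_step(opt, params, grads, lr)
      params <- upd$params
      opt <- upd$state
    }

    val_c <- if (length(val_bags) > 0) {
      vo <- vapply(seq_along(val_bags), function(i) {
        mil_forward(val_bags[[i]]$instances, val_units[[i]], params)$o
      }, numeric(1))
      vlab <- bag_labels(val_bags)
      tryCatch(concordance_index(vo, vlab$time, vlab$event)$c_index,
               error = function(e) NA_real_)
    } else NA_real_

    if (!is.na(val_c) && val_c > best$cindex) {
      best <- list(cindex = val_c, epoch = epoch, params = params)
    }
    log[[epoch]] <- tibble::tibble(
      epoch = epoch, train_npll = epoch_npll,
      train_rank = if (use_rank) epoch_rank else NA_real_,
      val_cindex = val_c
    )
  }

  if (!is.finite(best$cindex)) {
    best <- list(cindex = NA_real_, epoch = config$epochs, params = params)
  }
  structure(
    list(params = best$params, final_params = params,
         best_epoch = best$epoch, best_val_cindex = best$cindex,
         log = dplyr::bind_rows(log), config = config, variant = variant,
         k = if (variant == "clustered") as.integer(k) else NA_integer_,
         learning_rate = lr, fold = fold,
         train_ids = train_ids, val_ids = val_ids),
    class = "mil_fit"
  )
}

dropout_masks <- function(bags, units, params, seed, epoch) {
  if (params$dropout_rate <= 0) {
    return(vector("list", length(bags)))
  }
  rate <- params$dropout_rate
  local_seeded(seed + 1000L + epoch, {
    lapply(seq_along(bags), function(i) {
      C <- length(unique(units[[i]]))
      m <- matrix(rbinom(C * params$M, 1, 1 - rate), C, params$M)
      m / (1 - rate)
    })
  })
}

zero_grads <- function(params) {
  g <- lapply(params[trainable_names], function(p) p * 0)
  g
}

adam_state <- function(params) {
  list(m = zero_grads(params), v = zero_grads(params), t = 0,
       beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(state, params, grads, lr) {
  state$t <- state$t + 1
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  for (nm in trainable_names) {
    state$m[[nm]] <- state$beta1 * state$m[[nm]] +
      (1 - state$beta1) * grads[[nm]]
    state$v[[nm]] <- state$beta2 * state$v[[nm]] +
      (1 - state$beta2) * grads[[nm]]^2
    step <- lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + state$eps)
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, state = state)
}

#' @export
print.mil_fit <- function(x, ...) {
  cat("<mil_fit> variant = ", x$variant,
      if (!is.na(x$k)) paste0(" (k = ", x$k, ")") else "",
      ", fold ", x$fold, "\n", sep = "")
  cat("  epochs: ", nrow(x$log), ", best epoch ", x$best_epoch,
      " (val c-index ", signif(x$best_val_cindex, 4), ")\n", sep = "")
  invisible(x)
}

#' Per-epoch training log of a fitted MIL model
#'
#' @param x A `mil_fit` object.
#' @param ... Unused.
#' @return Tibble `epoch, train_npll, train_rank, val_cindex`.
#' @method tidy mil_fit
#' @export
tidy.mil_fit <- function(x, ...) x$log

#' One-row summary of a fitted MIL model
#'
#' @inheritParams tidy.mil_fit
#' @return Tibble with the variant, learning rate, best epoch and best
#'   validation c-index.
#' @method glance mil_fit
#' @export
glance.mil_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$variant, k = x$k, learning_rate = x$learning_rate,
    epochs = nrow(x$log), best_epoch = x$best_epoch,
    best_val_cindex = x$best_val_cindex
  )
}

#' Predict risk scores (and attention) for bags
#'
#' @param object A `mil_fit` from [mil_train()].
#' @param bags List of [patient_bag()] objects.
#' @param ... Unused.
#' @return Tibble `patient_id, risk, attention` where `attention` is a
#'   list column of per-unit weights (per instance for the instance
#'   variant, per phenotype for the clustered variant).
#' @export
predict.mil_fit <- function(object, bags, ...) {
  preds <- purrr::map(bags, function(b) {
    ph <- if (object$variant == "clustered") {
      cluster_bag(b, k = object$k, seed = object$config$seed + 1L)
    } else NULL
    forward_risk(b, object$params, phenotypes = ph)
  })
  tibble::tibble(
    patient_id = unname(vapply(preds, `[[`, character(1), "patient_id")),
    risk = unname(vapply(preds, `[[`, numeric(1), "risk")),
    attention = unname(purrr::map(preds, "attention"))
  )
}

#' Cross-validated training with pooled test-fold predictions
#'
#' Trains one model per fold of the plan and collects each patient's risk
#' prediction from the fold in which that patient was held out in the
#' test set, so every patient receives exactly one out-of-training
#' prediction and the pooled concordance index summarises held-out
#' performance over the whole cohort.
#'
#' @inheritParams mil_train
#' @param folds Which folds to run (default: all in the plan).
#' @return List of class `mil_cv`: `fits` (per-fold `mil_fit`s),
#'   `predictions` (tibble `patient_id, fold, risk, attention` of pooled
#'   test-fold predictions), `test_cindex` (pooled), and `per_fold`
#'   (tibble of per-fold test c-indexes).
#' @export
mil_crossval <- function(bags, plan, config = train_config(),
                         variant = c("instance", "clustered"), k = 10L,
                         folds = NULL, ...) {
  variant <- match.arg(variant)
  ids <- vapply(bags, `[[`, character(1), "patient_id")
  names(bags) <- ids
  folds <- folds %||% sort(unique(plan$fold))
  fits <- list()
  preds <- list()
  per_fold <- list()
  for (f in folds) {
    fit <- mil_train(bags, plan, fold = f, config = config,
                     variant = variant, k = k, ...)
    roles <- dplyr::filter(plan, .data$fold == !!f)
    test_ids <- roles$patient_id[roles$role == "test"]
    pr <- predict(fit, bags[test_ids])
    lab <- bag_labels(bags[test_ids])
    ci <- tryCatch(
      concordance_index(pr$risk, lab$time, lab$event)$c_index,
      error = function(e) NA_real_
    )
    fits[[as.character(f)]] <- fit
    preds[[as.character(f)]] <- dplyr::mutate(pr, fold = f, .after = 1)
    per_fold[[as.character(f)]] <- tibble::tibble(fold = f,
                                                  test_cindex = ci)
  }
  predictions <- dplyr::bind_rows(preds)
  lab_all <- bag_labels(bags[predictions$patient_id])
  pooled <- concordance_index(predictions$risk, lab_all$time,
                              lab_all$event)$c_index
  structure(
    list(fits = fits, predictions = predictions, test_cindex = pooled,
         per_fold = dplyr::bind_rows(per_fold)),
    class = "mil_cv"
  )
}

#' @export
print.mil_cv <- function(x, ...) {
  cat("<mil_cv> ", length(x$fits), " fold(s); pooled test c-index ",
      signif(x$test_cindex, 4), "\n", sep = "")
  print(x$per_fold, ...)
  invisible(x)
}

#' @method glance mil_cv
#' @export
glance.mil_cv <- function(x, ...) {
  tibble::tibble(n_folds = length(x$fits),
                 test_cindex = x$test_cindex,
                 mean_fold_cindex = mean(x$per_fold$test_cindex,
                                         na.rm = TRUE))
}
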
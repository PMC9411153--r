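#' Simulation configuration for synthetic cohorts
#'
#' Describes a cohort of patient bags in which a minority of instances
#' carry a risk-determining feature motif and survival follows a
#' proportional-hazards model on each patient's signal burden.
#'
#' Each patient draws a signal prevalence \eqn{f_i} from a Beta
#' distribution with mean `signal_fraction`; instances are flagged as
#' signal with probability \eqn{f_i}. Background instances are standard
#' Gaussian d-vectors; signal instances are shifted by `signal_shift`
#' along a fixed unit motif direction (drawn once from the seed). The
#' patient's log relative hazard is `effect_beta` per standard deviation
#' of signal burden, i.e. `effect_beta * (f_i - mean) / sd` with the Beta
#' distribution's own mean and standard deviation, so `effect_beta`
#' controls the discriminability of the cohort irrespective of how rare
#' the motif is. Event times are exponential with hazard
#' `baseline_hazard * exp(risk)`; censoring times are independent
#' exponentials whose rate is solved so the expected censored fraction
#' equals `censor_rate`.
#'
#' @param n_patients Number of patients (>= 2).
#' @param instances_range Integer range (min, max) of instances per bag.
#' @param d Feature dimension.
#' @param signal_fraction Mean share of signal instances per bag, in
#'   (0, 1).
#' @param signal_shift Shift of signal instances along the motif, in
#'   feature SD units.
#' @param effect_beta Log hazard ratio per SD of signal burden.
#' @param baseline_hazard Baseline event rate (1/years).
#' @param censor_rate Expected fraction of censored patients, in [0, 1).
#' @param prevalence_shape First shape parameter of the Beta prevalence
#'   distribution (the second is solved to hit `signal_fraction`).
#' @param seed Integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_patients = 200L, instances_range = c(40L, 60L),
                       d = 128L, signal_fraction = 0.2, signal_shift = 2,
                       effect_beta = 2, baseline_hazard = 0.1,
                       censor_rate = 0.3, prevalence_shape = 2,
                       seed = 1L) {
  stopifnot(n_patients >= 2, signal_fraction >= 0, signal_fraction < 1,
            censor_rate >= 0, censor_rate < 1, baseline_hazard > 0,
            length(instances_range) == 2,
            instances_range[1] >= 1,
            instances_range[2] >= instances_range[1])
  structure(
    list(n_patients = as.integer(n_patients),
         instances_range = as.integer(instances_range), d = as.integer(d),
         signal_fraction = signal_fraction, signal_shift = signal_shift,
         effect_beta = effect_beta, baseline_hazard = baseline_hazard,
         censor_rate = censor_rate, prevalence_shape = prevalence_shape,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a cohort of feature bags with known risk structure
#'
#' Generates patient bags, ground-truth per-instance signal flags and
#' per-patient true log relative hazards, and right-censored survival
#' outcomes from a proportional-hazards model (see [sim_config()] for the
#' generative model). Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return List with elements `bags` (list of [patient_bag()], each
#'   carrying its `signal` flags), `truth` (tibble `patient_id,
#'   true_risk, signal_fraction, n_signal, time, event`), `motif` (the
#'   signal direction), and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  cf <- config
  local_seeded(cf$seed, {
    motif <- rnorm(cf$d)
    motif <- motif / sqrt(sum(motif^2))

    n <- cf$n_patients
    sizes <- sample(seq(cf$instances_range[1], cf$instances_range[2]),
                    n, replace = TRUE)
    if (cf$signal_fraction > 0) {
      a <- cf$prevalence_shape
      b <- a * (1 - cf$signal_fraction) / cf$signal_fraction
      prev <- rbeta(n, a, b)
      prev_mean <- a / (a + b)
      prev_sd <- sqrt(a * b / ((a + b)^2 * (a + b + 1)))
      # the risk is carried by the realised signal fraction of each bag
      # (the share of instances actually flagged), standardised by the
      # prevalence distribution's moments so effect_beta is a per-SD
      # log hazard ratio
      flags <- lapply(seq_len(n),
                      function(i) as.logical(rbinom(sizes[i], 1, prev[i])))
      frac <- vapply(flags, mean, numeric(1))
      risk <- cf$effect_beta * (frac - prev_mean) / prev_sd
    } else {
      prev <- rep(0, n)
      flags <- lapply(sizes, function(m) rep(FALSE, m))
      frac <- rep(0, n)
      risk <- rep(0, n)
    }

    hazard <- cf$baseline_hazard * exp(risk)
    event_time <- rexp(n, rate = hazard)
    if (cf$censor_rate > 0) {
      # solve the censoring rate so that E[ P(C < T) ] = censor_rate
      target <- function(hc) mean(hc / (hc + hazard)) - cf$censor_rate
      hc <- uniroot(target, lower = 1e-10, upper = 1e6, tol = 1e-12)$root
      censor_time <- rexp(n, rate = hc)
    } else {
      censor_time <- rep(Inf, n)
    }
    time <- pmin(event_time, censor_time)
    event <- as.integer(event_time <= censor_time)

    ids <- sprintf("SIM%04d", seq_len(n))
    bags <- vector("list", n)
    for (i in seq_len(n)) {
      m <- sizes[i]
      fl <- flags[[i]]
      X <- matrix(rnorm(m * cf$d), m, cf$d)
      if (any(fl)) {
        X[fl, ] <- X[fl, , drop = FALSE] +
          rep(cf$signal_shift * motif, each = sum(fl))
      }
      bags[[i]] <- patient_bag(ids[i], X, time = time[i],
                               event = event[i], d = cf$d, grid = 1L,
                               signal = fl)
    }
    names(bags) <- ids
    list(
      bags = bags,
      truth = tibble::tibble(
        patient_id = ids, true_risk = risk, signal_fraction = frac,
        prevalence = prev,
        n_signal = vapply(flags, sum, integer(1)), n_instances = sizes,
        time = time, event = event
      ),
      motif = motif,
      config = cf
    )
  })
}

#' Simulate a toy tissue-core image
#'
#' White background with dark elliptical tissue fragments and optional
#' interior holes of specified pixel area, plus the ground-truth tissue
#' mask — a fixture for exercising the masking and tiling stages.
#'
#' @param width,height Image dimensions in pixels.
#' @param n_fragments Number of dark tissue fragments (0 gives a blank
#'   image).
#' @param hole_areas_px Numeric vector of interior hole areas (pixels^2),
#'   punched into the first fragment.
#' @param resolution Micrometres per pixel recorded on the image.
#' @param intensity Grey level of tissue (0 = black).
#' @param noise_sd Gaussian texture noise added to tissue pixels.
#' @param seed Integer seed.
#' @return List of class `core_image`: `pixels` (height x width x 3 array
#'   in [0, 1]), `truth_mask` (logical matrix), `resolution`, `core_id`.
#' @export
simulate_core_image <- function(width = 512L, height = 512L,
                                n_fragments = 1L, hole_areas_px = numeric(),
                                resolution = 0.25, intensity = 0.35,
                                noise_sd = 0.02, seed = 1L) {
  stopifnot(width > 0, height > 0)
  local_seeded(seed, {
    mask <- matrix(FALSE, height, width)
    rows <- matrix(rep(seq_len(height), width), height, width)
    cols <- matrix(rep(seq_len(width), each = height), height, width)
    if (n_fragments == 1) {
      centers <- cbind(height / 2, width / 2)
    } else if (n_fragments > 1) {
      centers <- cbind(runif(n_fragments, 0.25, 0.75) * height,
                       runif(n_fragments, 0.25, 0.75) * width)
    } else {
      centers <- matrix(numeric(), 0, 2)
    }
    for (f in seq_len(n_fragments)) {
      ry <- height * runif(1, 0.28, 0.38) / sqrt(n_fragments)
      rx <- width * runif(1, 0.28, 0.38) / sqrt(n_fragments)
      mask <- mask |
        (((rows - centers[f, 1]) / ry)^2 +
           ((cols - centers[f, 2]) / rx)^2 <= 1)
    }
    for (area in hole_areas_px) {
      r <- sqrt(area / pi)
      # place the hole at the first fragment's center
      hole <- ((rows - centers[1, 1])^2 + (cols - centers[1, 2])^2) <= r^2
      mask <- mask & !hole
      cols_shift <- 2.5 * r # next hole placed to the right, if any
      centers[1, 2] <- centers[1, 2] + cols_shift
    }
    grey <- matrix(1, height, width)
    grey[mask] <- pmin(pmax(
      intensity + rnorm(sum(mask), sd = noise_sd), 0), 0.95)
    g2 <- grey
    g2[mask] <- grey[mask] * 0.92  # slight eosin-like hue on tissue only
    g3 <- grey
    g3[mask] <- grey[mask] * 0.97
    pixels <- array(c(grey, g2, g3), dim = c(height, width, 3))
    pixels[pixels > 1] <- 1
    structure(
      list(pixels = pixels, truth_mask = mask, resolution = resolution,
           core_id = sprintf("toy-core-%d", seed)),
      class = "core_image"
    )
  })
}

#' @export
print.core_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat("<core_image> ", x$core_id, ": ", d[1], " x ", d[2], " px @ ",
      x$resolution, " um/px\n", sep = "")
  invisible(x)
}
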
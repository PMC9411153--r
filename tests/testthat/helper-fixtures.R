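# In-code fixtures shared across the suite.

# Per-core manifest rows matching the printed TNBC cohort composition:
# 236 patients with 3 cores, 7 with 2 cores, 1 with a single core.
tnbc_like_manifest <- function() {
  n_cores <- c(rep(3L, 236), rep(2L, 7), 1L)
  pid <- sprintf("PT%03d", seq_along(n_cores))
  tibble::tibble(
    patient_id = rep(pid, n_cores),
    core_id = unlist(lapply(seq_along(n_cores), function(i) {
      paste0(pid[i], "-", LETTERS[seq_len(n_cores[i])])
    })),
    time_years = rep(round(seq(0.1, 16, length.out = length(pid)), 2),
                     n_cores),
    event = rep(rep_len(c(1L, 0L, 0L, 1L, 0L), length(pid)), n_cores)
  )
}

# A tiny bag with Gaussian instances.
toy_bag <- function(id = "P1", n = 8, d = 6, time = 2, event = 1L,
                    seed = 1) {
  set.seed(seed)
  patient_bag(id, matrix(rnorm(n * d), n, d), time = time, event = event,
              d = d)
}

toy_bags <- function(n_bags = 6, n = 8, d = 6, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_bags), function(i) {
    patient_bag(sprintf("P%02d", i), matrix(rnorm(n * d), n, d),
                time = runif(1, 0.5, 8), event = rbinom(1, 1, 0.7), d = d)
  })
}

# O(n^2) brute-force concordance enumerator: explicit rule per ordered
# pair, no vectorised shortcuts (the oracle for the fast implementation).
brute_force_cindex <- function(risk, time, event,
                               pairs = c("permissible", "all")) {
  pairs <- match.arg(pairs)
  n <- length(risk)
  C <- 0L; D <- 0L; R <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (!(time[i] < time[j])) next
      if (pairs == "permissible" && event[i] != 1L) next
      if (risk[i] > risk[j]) C <- C + 1L
      else if (risk[i] < risk[j]) D <- D + 1L
      else R <- R + 1L
    }
  }
  list(c_index = (C + R / 2) / (C + D + R), C = C, D = D, R = R)
}

# Brute-force negative partial log-likelihood: literal double loop over
# events and risk sets, no log-sum-exp rearrangement.
brute_force_npll <- function(risk, time, event) {
  total <- 0
  for (i in seq_along(risk)) {
    if (event[i] != 1) next
    s <- 0
    for (j in seq_along(risk)) {
      if (time[j] >= time[i]) s <- s + exp(risk[j])
    }
    total <- total + (-risk[i] + log(s))
  }
  total
}

# All within-cluster sum of squares of the best 2-partition, by
# exhaustive enumeration (oracle for k-means on well-separated data).
best_two_partition <- function(X) {
  n <- nrow(X)
  best <- list(wss = Inf, membership = NULL)
  for (code in 1:(2^(n - 1) - 1)) {
    memb <- c(1L, as.integer(intToBits(code))[seq_len(n - 1)] + 1L)
    wss <- 0
    for (g in unique(memb)) {
      Xg <- X[memb == g, , drop = FALSE]
      wss <- wss + sum(scale(Xg, scale = FALSE)^2)
    }
    if (wss < best$wss) best <- list(wss = wss, membership = memb)
  }
  best
}
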
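#' Cluster a patient's instances into phenotypes
#'
#' Per-patient k-means over the bag's (flattened) instance vectors, used
#' by the clustered model variant: each cluster is a "phenotype" whose
#' feature stack becomes one input unit of the network. Lloyd iterations
#' start from k-means++-style seeded centers; 10 restarts are run and the
#' solution with the lowest within-cluster sum of squares is kept, all
#' deterministic under `seed`. When the bag holds fewer distinct vectors
#' than `k`, the effective number of clusters is reduced to match.
#'
#' @param bag A [patient_bag()].
#' @param k Number of clusters requested (>= 1).
#' @param seed Integer seed.
#' @param n_restarts Number of restarts (best inertia kept).
#' @return A list of class `phenotype_set`: `patient_id`, `k` (requested),
#'   `k_effective`, `assignment` (integer per instance, in `1..k_effective`),
#'   `stacks` (list of per-cluster feature matrices), and `withinss`
#'   (total within-cluster sum of squares).
#' @export
cluster_bag <- function(bag, k = 10L, seed = 1L, n_restarts = 10L) {
  stopifnot(k >= 1)
  X <- bag$instances
  n <- nrow(X)
  k_eff <- min(k, n, nrow(unique(X)))
  # canonical (lexicographic) row order makes the result invariant to
  # the order instances arrive in, up to cluster relabelling
  ord <- do.call(order, as.data.frame(X))
  Xs <- X[ord, , drop = FALSE]
  if (k_eff == 1) {
    assignment <- rep(1L, n)
    wss <- sum(scale(X, scale = FALSE)^2)
  } else if (k_eff == n) {
    assignment <- seq_len(n)
    wss <- 0
  } else {
    fit <- local_seeded(seed, {
      best <- NULL
      for (r in seq_len(n_restarts)) {
        centers <- Xs[kmeanspp_centers(Xs, k_eff), , drop = FALSE]
        f <- suppressWarnings(
          kmeans(Xs, centers = centers, iter.max = 50L,
                 algorithm = "Lloyd")
        )
        if (is.null(best) || f$tot.withinss < best$tot.withinss) best <- f
      }
      best
    })
    assignment <- integer(n)
    assignment[ord] <- as.integer(fit$cluster)
    wss <- fit$tot.withinss
  }
  structure(
    list(patient_id = bag$patient_id, k = as.integer(k),
         k_effective = as.integer(length(unique(assignment))),
         assignment = assignment,
         stacks = split.data.frame(X, assignment),
         withinss = wss),
    class = "phenotype_set"
  )
}

# k-means++ style seeding: first center uniform, then each next center
# drawn with probability proportional to squared distance to the nearest
# chosen center. Returns row indices.
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums((X - X[rep(idx[1], n), , drop = FALSE])^2)
  for (j in seq_len(k - 1)) {
    if (all(d2 == 0)) {
      idx[j + 1] <- sample.int(n, 1)
    } else {
      idx[j + 1] <- sample.int(n, 1, prob = d2)
    }
    d2 <- pmin(d2, rowSums((X - X[rep(idx[j + 1], n), , drop = FALSE])^2))
  }
  idx
}

#' @export
print.phenotype_set <- function(x, ...) {
  cat("<phenotype_set> ", x$patient_id, ": ", x$k_effective,
      " phenotype(s) (k = ", x$k, ") over ", length(x$assignment),
      " instances\n", sep = "")
  invisible(x)
}

#' Cluster every bag of a cohort
#'
#' @param bags List of [patient_bag()] objects.
#' @inheritParams cluster_bag
#' @return Named list of `phenotype_set` objects (one per patient).
#' @export
cluster_cohort <- function(bags, k = 10L, seed = 1L) {
  out <- purrr::map(bags, cluster_bag, k = k, seed = seed)
  names(out) <- vapply(bags, `[[`, character(1), "patient_id")
  out
}

#' Cluster assignments as a tidy table
#'
#' @param phenotypes A `phenotype_set` or list of them.
#' @return Tibble `patient_id, instance_index, cluster`.
#' @export
cluster_assignments <- function(phenotypes) {
  if (inherits(phenotypes, "phenotype_set")) phenotypes <- list(phenotypes)
  purrr::map_dfr(phenotypes, function(p) {
    tibble::tibble(patient_id = p$patient_id,
                   instance_index = seq_along(p$assignment),
                   cluster = p$assignment)
  })
}
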
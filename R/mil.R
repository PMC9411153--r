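#' Construct a patient bag
#'
#' A bag holds one patient's instance feature vectors together with the
#' survival label. Instances are rows of a numeric matrix; super-patch
#' instances (a g x g grid of d-vectors) are stored flattened as rows of
#' length `g^2 * d` with the grid size recorded in `grid`.
#'
#' @param patient_id Patient identifier.
#' @param instances Numeric matrix, one instance per row.
#' @param time,event Survival label: follow-up time (years) and event
#'   indicator.
#' @param d Feature dimension of one patch vector.
#' @param grid Super-patch grid size g (1 for plain patch vectors).
#' @param signal Optional logical vector flagging ground-truth signal
#'   instances (used by the simulator).
#' @return Object of class `patient_bag`.
#' @export
patient_bag <- function(patient_id, instances, time, event,
                        d = ncol(instances), grid = 1L, signal = NULL) {
  instances <- as.matrix(instances)
  if (nrow(instances) < 1) abort("A bag must contain at least 1 instance.")
  if (ncol(instances) != d * grid^2) {
    abort("Instance width must equal d * grid^2.")
  }
  if (anyNA(instances) || any(!is.finite(instances))) {
    abort("Instance features must be finite.")
  }
  structure(
    list(patient_id = as.character(patient_id), instances = instances,
         time = as.numeric(time), event = as.integer(event),
         d = as.integer(d), grid = as.integer(grid), signal = signal),
    class = "patient_bag"
  )
}

#' @export
print.patient_bag <- function(x, ...) {
  cat("<patient_bag> ", x$patient_id, ": ", nrow(x$instances),
      " instances x ", ncol(x$instances), " features (d = ", x$d,
      ", grid = ", x$grid, "), t = ", signif(x$time, 4),
      ", event = ", x$event, "\n", sep = "")
  invisible(x)
}

#' Survival labels of a list of bags
#'
#' @param bags List of [patient_bag()] objects.
#' @return Tibble `patient_id, time, event`.
#' @export
bag_labels <- function(bags) {
  tibble::tibble(
    patient_id = unname(vapply(bags, `[[`, character(1), "patient_id")),
    time = unname(vapply(bags, `[[`, numeric(1), "time")),
    event = unname(vapply(bags, `[[`, integer(1), "event"))
  )
}

#' Initialise the trainable parameters of the MIL network
#'
#' The network is a shared instance embedder (a single linear convolution
#' over the instance grid, ReLU, global average pooling), an attention
#' block with hidden size L computing softmax weights
#' \eqn{a_i \propto \exp(w^\top \tanh(V h_i))}, and a fully connected risk
#' head mapping the pooled M-vector to a scalar risk score.
#'
#' @param d Patch feature dimension.
#' @param grid Super-patch grid size (the convolution spans the grid).
#' @param M Embedding channels (output of the embedder).
#' @param L Attention hidden size.
#' @param hidden Width of the risk head's hidden layer.
#' @param dropout_rate Dropout probability on embedded representations
#'   during training (0 disables).
#' @param seed Integer seed for the random initialisation.
#' @return Object of class `mil_params`.
#' @export
mil_params <- function(d = 128L, grid = 1L, M = 64L, L = 128L,
                       hidden = 32L, dropout_rate = 0, seed = 1L) {
  stopifnot(dropout_rate >= 0, dropout_rate < 1)
  p <- d * grid^2
  local_seeded(seed, {
    structure(
      list(
        W = matrix(rnorm(p * M, sd = sqrt(2 / p)), p, M),
        b = rep(0, M),
        V = matrix(rnorm(L * M, sd = sqrt(1 / M)), L, M),
        w = rnorm(L, sd = sqrt(1 / L)),
        W1 = matrix(rnorm(M * hidden, sd = sqrt(2 / M)), M, hidden),
        b1 = rep(0, hidden),
        W2 = matrix(rnorm(hidden, sd = sqrt(1 / hidden)), hidden, 1),
        b2 = 0,
        d = as.integer(d), grid = as.integer(grid), M = as.integer(M),
        L = as.integer(L), hidden = as.integer(hidden),
        dropout_rate = dropout_rate
      ),
      class = "mil_params"
    )
  })
}

trainable_names <- c("W", "b", "V", "w", "W1", "b1", "W2", "b2")

#' Embed one input unit into its local representation
#'
#' A unit is either a phenotype stack (several instance rows) or a single
#' instance. The embedder applies the shared linear convolution and ReLU
#' per instance row and global-average-pools over the stack:
#' `h = GAP(ReLU(conv(unit)))`, a non-negative M-vector.
#'
#' @param unit Numeric matrix (rows = instances of the unit) or a single
#'   feature vector.
#' @param params [mil_params()] object.
#' @return Numeric M-vector.
#' @export
embed_unit <- function(unit, params) {
  X <- if (is.matrix(unit)) unit else matrix(unit, nrow = 1)
  if (ncol(X) != nrow(params$W)) {
    abort("Unit has wrong number of feature channels.")
  }
  A <- pmax(X %*% params$W + rep(params$b, each = nrow(X)), 0)
  colMeans(A)
}

#' Attention weights over local representations
#'
#' Softmax over units of the logits \eqn{w^\top \tanh(V h_i)}; the weights
#' are positive, sum to one, and are invariant to shifting all logits by a
#' constant.
#'
#' @param H Matrix of local representations (one unit per row) or a list
#'   of M-vectors.
#' @param params [mil_params()] object.
#' @return Numeric vector of attention weights summing to 1.
#' @export
attention_weights <- function(H, params) {
  H <- as_h_matrix(H)
  U <- tanh(H %*% t(params$V))
  e <- drop(U %*% params$w)
  softmax(e)
}

#' Attention-weighted aggregation of local representations
#'
#' Computes the bag representation `z = sum_i a_i h_i`. Permuting units
#' together with their weights leaves `z` unchanged.
#'
#' @param H Matrix of local representations (rows) or list of vectors.
#' @param a Attention weights, one per unit.
#' @return Numeric M-vector.
#' @export
attention_aggregate <- function(H, a) {
  H <- as_h_matrix(H)
  if (nrow(H) != length(a)) abort("H and a must have matching lengths.")
  drop(crossprod(H, a))
}

as_h_matrix <- function(H) {
  if (is.list(H)) H <- do.call(rbind, H)
  if (!is.matrix(H)) H <- matrix(H, nrow = 1)
  H
}

softmax <- function(e) {
  w <- exp(e - max(e))
  w / sum(w)
}

#' Forward pass: risk score and attention for one patient
#'
#' Runs the full network on a bag. With `phenotypes` supplied (the
#' clustered variant), instances are grouped into phenotype stacks and the
#' attention runs over phenotypes; otherwise every instance is its own
#' input unit and the attention is per instance.
#'
#' @param bag A [patient_bag()].
#' @param params [mil_params()] object.
#' @param phenotypes Optional [cluster_bag()] result for the clustered
#'   variant.
#' @return A list of class `risk_prediction`: `patient_id`, `risk`
#'   (scalar) and `attention` (per input unit, sums to 1).
#' @export
forward_risk <- function(bag, params, phenotypes = NULL) {
  unit_index <- if (is.null(phenotypes)) {
    seq_len(nrow(bag$instances))
  } else {
    if (!identical(phenotypes$patient_id, bag$patient_id)) {
      abort("Phenotype set belongs to a different patient.")
    }
    phenotypes$assignment
  }
  fwd <- mil_forward(bag$instances, unit_index, params)
  structure(
    list(patient_id = bag$patient_id, risk = fwd$o, attention = fwd$a),
    class = "risk_prediction"
  )
}

#' @export
print.risk_prediction <- function(x, ...) {
  cat("<risk_prediction> ", x$patient_id, ": risk = ", signif(x$risk, 5),
      " over ", length(x$attention), " unit(s)\n", sep = "")
  invisible(x)
}

# Full forward pass on an instance matrix with a unit grouping.
# unit_index maps instance rows to input units (identity for the
# instance-level variant, cluster ids for the phenotype variant).
# Returns the scalar risk, attention vector and a cache for backprop.
mil_forward <- function(X, unit_index, params, dropout_mask = NULL) {
  if (nrow(X) == 0) abort("Empty bag.")
  if (ncol(X) != nrow(params$W)) {
    abort("Feature width does not match the embedder (d * grid^2).")
  }
  unit_index <- as.integer(factor(unit_index))
  counts <- tabulate(unit_index)
  Apre <- X %*% params$W + rep(params$b, each = nrow(X))
  A <- pmax(Apre, 0)
  Hmat <- rowsum(A, unit_index) / counts           # GAP per unit (C x M)
  rownames(Hmat) <- NULL
  if (!is.null(dropout_mask)) Hmat <- Hmat * dropout_mask
  U <- tanh(Hmat %*% t(params$V))                  # C x L
  e <- drop(U %*% params$w)
  a <- softmax(e)
  z <- drop(crossprod(Hmat, a))                    # M
  s_pre <- drop(z %*% params$W1) + params$b1       # hidden
  s <- pmax(s_pre, 0)
  o <- drop(s %*% params$W2) + params$b2
  list(o = o, a = a,
       cache = list(X = X, unit_index = unit_index, counts = counts,
                    Apre = Apre, A = A, Hmat = Hmat, U = U, a = a, z = z,
                    s_pre = s_pre, s = s, dropout_mask = dropout_mask))
}

# Backward pass: gradient of (do * o) wrt all trainable parameters.
mil_backward <- function(cache, do, params) {
  with(cache, {
    ds <- drop(do * params$W2)                     # hidden
    ds_pre <- ds * (s_pre > 0)
    gW2 <- matrix(s * do, ncol = 1)
    gb2 <- do
    gW1 <- outer(z, ds_pre)
    gb1 <- ds_pre
    dz <- drop(params$W1 %*% ds_pre)               # M
    da <- drop(Hmat %*% dz)                        # C
    de <- a * (da - sum(a * da))
    gw <- drop(crossprod(U, de))                   # L
    dU <- outer(de, params$w)                      # C x L
    dUpre <- dU * (1 - U^2)
    gV <- crossprod(dUpre, Hmat)                   # L x M
    dH <- outer(a, dz) + dUpre %*% params$V        # C x M
    if (!is.null(dropout_mask)) dH <- dH * dropout_mask
    dA <- dH[unit_index, , drop = FALSE] / counts[unit_index]
    dApre <- dA * (Apre > 0)
    gW <- crossprod(X, dApre)
    gb <- colSums(dApre)
    list(W = gW, b = gb, V = gV, w = gw, W1 = gW1, b1 = gb1,
         W2 = gW2, b2 = gb2)
  })
}
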
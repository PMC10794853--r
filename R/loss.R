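# Differentiable surrogate losses for masked minimizer training.
#
# The density loss pulls the content-based priority scores P toward the
# positional template T at the positions most likely to be sampled,
# while a regularizer pushes all scores toward 1.  "Most likely to be
# sampled" is expressed by per-window softmin weights of both T and P
# (a window's sampled position is its score argmin; the softmin is its
# smooth relaxation), and the mask enters by restricting the weighted
# sum to qualifying offsets.  The weights are treated as constants in
# the backward pass (stop-gradient), as with hard argmin selection.

# Per-window softmin weight matrix (Lwk x w) of a score vector: row i
# holds softmax_j(-scores[i + j] / tau), j = 0..w-1.
loss_weights_one <- function(scores, w, tau) {
  n <- length(scores) - w + 1L
  idx <- rep(seq_len(n), w) + rep(0:(w - 1L), each = n)
  m <- matrix(scores[idx], nrow = n, ncol = w)
  e <- exp(-(m - apply(m, 1L, min)) / tau)
  e / rowSums(e)
}

#' Sampling-likelihood weights for the density loss
#'
#' Sum of the per-window softmin weights of the template and priority
#' score vectors: entry `(i, j)` weighs how likely k-mer `i + j` is to
#' be the sampled minimum of window `i` under either vector.
#'
#' @param P,T priority and template score vectors (equal length `Lk`).
#' @param w window size.
#' @param tau softmin temperature; small values approach the hard
#'   argmin.
#' @return an `Lwk x w` weight matrix.
#' @export
loss_weights <- function(P, T, w, tau = 0.05) {
  stopifnot(length(P) == length(T))
  loss_weights_one(T, w, tau) + loss_weights_one(P, w, tau)
}

#' Masked density loss
#'
#' `lambda * ||1 - P||^2 + sum_i sum_{j in v} weight(i, j) *
#' (P[i+j] - T[i+j])^2`, summing over all (w,k)-windows `i` and the
#' qualifying offsets `j` of the mask.  The regularizer stops both
#' vectors from trivially collapsing to 0; the weighted term is a
#' smooth surrogate of the masked minimizer's per-window sampling.
#' With `v` empty only the regularizer remains; with `P = T = 1` the
#' loss is 0.
#'
#' @inheritParams loss_weights
#' @param mask an `offset_mask` of width `w` (or integer offsets).
#' @param lambda_reg regularization weight.
#' @param weights optional precomputed `Lwk x w` weight matrix (frozen);
#'   by default [loss_weights()] is used.
#' @return scalar loss (non-negative).
#' @export
density_loss <- function(P, T, mask, w, lambda_reg = 1, tau = 0.05,
                         weights = NULL) {
  density_loss_grad(P, T, mask, w, lambda_reg, tau, weights)$loss
}

# Loss plus analytic gradients dL/dP, dL/dT (weights held constant).
density_loss_grad <- function(P, T, mask, w, lambda_reg = 1, tau = 0.05,
                              weights = NULL) {
  if (length(P) != length(T)) stop("P and T must have equal length")
  n <- length(P)
  if (n < w) stop("score vectors shorter than one window")
  mask <- as_mask(mask, w)
  Lwk <- n - w + 1L
  dP <- -2 * lambda_reg * (1 - P)
  dT <- numeric(n)
  loss <- lambda_reg * sum((1 - P)^2)
  if (length(mask$bits) > 0L) {
    if (is.null(weights)) weights <- loss_weights(P, T, w, tau)
    if (!all(dim(weights) == c(Lwk, w)))
      stop("weights must be an Lwk x w matrix")
    for (j in mask$bits) {
      pos <- seq_len(Lwk) + j                 # 1-based positions i + j
      wcol <- weights[, j + 1L]
      d <- P[pos] - T[pos]
      loss <- loss + sum(wcol * d^2)
      g <- 2 * wcol * d
      # accumulate because different offsets hit overlapping positions
      dP[pos] <- dP[pos] + g
      dT[pos] <- dT[pos] - g
    }
  }
  list(loss = loss, dP = dP, dT = dT)
}

#' Combined density + conservation (GSS) loss
#'
#' `density_loss(P_ref, T) + lambda_con * mean_i density_loss(P_i, T)`
#' over priority score vectors `P_i` of `n` substitution-mutated
#' homologs: the extra term pulls the homolog scores toward the same
#' template, so the induced sketch tends to survive substitutions.
#' With `lambda_con = 0` it equals the density loss exactly; with all
#' homologs identical to the reference it equals
#' `(1 + lambda_con) * density_loss`.
#'
#' @inheritParams density_loss
#' @param P_ref priority scores of the reference sequence.
#' @param P_homologs list of priority score vectors of the homologs.
#' @param lambda_con conservation weight (`lambda_c`).
#' @return scalar loss.
#' @export
gss_loss <- function(P_ref, P_homologs, T, mask, w, lambda_reg = 1,
                     lambda_con = 1, tau = 0.05) {
  n <- length(P_homologs)
  if (n == 0L && lambda_con > 0)
    stop("need at least one homolog score vector when lambda_con > 0")
  loss <- density_loss(P_ref, T, mask, w, lambda_reg, tau)
  if (lambda_con > 0) {
    hom <- vapply(P_homologs, function(Pi)
      density_loss(Pi, T, mask, w, lambda_reg, tau), numeric(1))
    loss <- loss + lambda_con * mean(hom)
  }
  loss
}
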
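# Twin scoring models for the differentiable sketch surrogate.
#
# The priority model scores each k-mer from its content only (so it
# defines a valid ordering: identical k-mers get identical scores); the
# template model scores positions only, with a period-w profile whose
# induced minimizer sketch has density ~ 1/w.  Both output in (0, 1)
# via a sigmoid.  Gradients are computed analytically.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Initialize the content-based priority model
#'
#' A one-hidden-layer network over the one-hot encoding of a k-mer:
#' `score = sigmoid(W2 . tanh(W1 x + b1) + b2)` with `x` the 4k-long
#' one-hot of the k-mer.  Scores depend on k-mer content only.
#'
#' @param k k-mer length.
#' @param hidden hidden layer width.
#' @param seed seed for the weight draw.
#' @param init_scale standard deviation of the initial weights.
#' @return an object of class `priority_model`.
#' @export
priority_model <- function(k, hidden = 96L, seed = 1L, init_scale = 0.5) {
  k <- as.integer(k); hidden <- as.integer(hidden)
  nf <- 4L * k
  par <- local_seed(seed, list(
    W1 = matrix(stats::rnorm(hidden * nf, sd = init_scale / sqrt(k)),
                nrow = hidden, ncol = nf),
    b1 = stats::rnorm(hidden, sd = 0.01),
    W2 = stats::rnorm(hidden, sd = init_scale / sqrt(hidden)),
    b2 = 0
  ))
  structure(list(k = k, hidden = hidden, par = par), class = "priority_model")
}

# Forward pass over every k-mer of a coded (sub)sequence.
# Returns P (length n k-mer scores) and a cache for the backward pass.
priority_forward <- function(pm, codes) {
  k <- pm$k
  n <- length(codes) - k + 1L
  if (n < 1L) stop("subsequence shorter than k")
  par <- pm$par
  H <- matrix(par$b1, nrow = pm$hidden, ncol = n)
  cols <- vector("list", k)
  for (p in seq_len(k)) {
    cp <- 4L * (p - 1L) + codes[p:(p + n - 1L)] + 1L
    cols[[p]] <- cp
    H <- H + par$W1[, cp, drop = FALSE]
  }
  hid <- tanh(H)
  z <- as.numeric(crossprod(hid, par$W2)) + par$b2
  P <- sigmoid(z)
  list(P = P, hid = hid, cols = cols)
}

# Backward pass: gradient of the loss w.r.t. the model parameters given
# dL/dP.  Returns a list shaped like pm$par.
priority_backward <- function(pm, cache, dP) {
  P <- cache$P
  dz <- dP * P * (1 - P)
  hid <- cache$hid
  dW2 <- as.numeric(hid %*% dz)
  db2 <- sum(dz)
  dH <- (pm$par$W2 %o% dz) * (1 - hid^2)
  db1 <- rowSums(dH)
  dW1 <- matrix(0, nrow = pm$hidden, ncol = 4L * pm$k)
  tdH <- t(dH)
  for (p in seq_len(pm$k)) {
    cp <- cache$cols[[p]]
    acc <- rowsum(tdH, group = cp)
    dW1[, as.integer(rownames(acc))] <-
      dW1[, as.integer(rownames(acc)), drop = FALSE] + t(acc)
  }
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

# Score every k-mer of a full coded sequence (no cache).
priority_scores <- function(pm, codes) priority_forward(pm, codes)$P

#' Initialize the positional template model
#'
#' `T[i] = sigmoid(-A cos(2 pi i / w) + delta[i])` over 0-based k-mer
#' positions `i`: a period-`w` profile with minima at multiples of `w`
#' (so the minimizer sketch it induces picks every w-th k-mer, density
#' ~ 1/w), plus a trainable per-position correction `delta`
#' (initialized at 0).
#'
#' @param Lk number of k-mer positions the template covers.
#' @param w window size (template period).
#' @param amplitude `A`, depth of the sinusoid in logit units.
#' @return an object of class `template_model`.
#' @export
template_model <- function(Lk, w, amplitude = 3) {
  structure(list(Lk = as.integer(Lk), w = as.integer(w),
                 amplitude = amplitude,
                 par = list(delta = numeric(Lk))),
            class = "template_model")
}

# Forward pass at 0-based positions `pos`; returns TT and cache.
template_forward <- function(tm, pos) {
  u <- -tm$amplitude * cos(2 * pi * pos / tm$w) + tm$par$delta[pos + 1L]
  TT <- sigmoid(u)
  list(TT = TT, pos = pos)
}

template_backward <- function(tm, cache, dT) {
  TT <- cache$TT
  ddelta <- numeric(tm$Lk)
  g <- dT * TT * (1 - TT)
  # positions are distinct within a batch, plain assignment suffices
  ddelta[cache$pos + 1L] <- g
  list(delta = ddelta)
}

# ---- Adam optimizer over a list-of-arrays parameter set -------------------

adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0), v = lapply(par, function(p) p * 0),
       t = 0L)
}

adam_step <- function(par, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(par)) {
    g <- grad[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

#' Wrap a priority model as a k-mer ordering
#'
#' The resulting ordering scores a k-mer by the model's output on that
#' k-mer alone, so duplicated k-mers anywhere receive identical scores.
#' Inference determinism is re-checked by scoring a probe k-mer twice.
#'
#' @param model a `priority_model` (or a `sketch_fit`, whose priority
#'   model is used).
#' @return a [new_kmer_ordering()] object.
#' @export
scores_to_ordering <- function(model) {
  if (inherits(model, "sketch_fit")) model <- model$priority
  stopifnot(inherits(model, "priority_model"))
  k <- model$k
  score <- function(kmers) {
    vapply(kmers, function(km) {
      if (nchar(km) != k) stop("k-mer length mismatch")
      priority_scores(model, chartr_codes(km))
    }, numeric(1), USE.NAMES = FALSE)
  }
  score_codes <- function(codes) priority_scores(model, codes)
  probe <- paste(rep("A", k), collapse = "")
  if (!identical(score(probe), score(probe)))
    stop("priority model inference is not deterministic")
  new_kmer_ordering(k, score, label = "learned priority model",
                    score_codes = score_codes)
}
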
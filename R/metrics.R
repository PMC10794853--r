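#' Sketch density
#'
#' Sketch size relative to the number of k-mers in the sequence (lower
#' is better); in `[0, 1]`.
#'
#' @param sketch integer vector of selected 0-based k-mer indices.
#' @param Lk number of k-mers in the sequence (`L - k + 1`).
#' @return density in `[0, 1]`.
#' @export
sketch_density <- function(sketch, Lk) {
  stopifnot(Lk >= 1)
  length(sketch) / Lk
}

#' Window coverage of a sketch
#'
#' Fraction of (w,k)-windows that overlap at least one sketched k-mer:
#' window `i` (0-based) overlaps index `j` iff `i <= j <= i + w - 1`.
#' A plain minimizer sketch has coverage exactly 1 by construction; an
#' empty sketch has coverage 0.
#'
#' @param sketch integer vector of 0-based k-mer indices.
#' @param L sequence length.
#' @param w window size in k-mers.
#' @param k k-mer length.
#' @return coverage fraction in `[0, 1]`.
#' @export
w_coverage <- function(sketch, L, w, k) {
  cnt <- seq_counts(L, w, k)
  if (cnt$Lwk < 1L) stop("no (w,k)-windows: sequence too short")
  if (length(sketch) == 0L) return(0)
  covered <- logical(cnt$Lwk)
  for (j in sketch) {
    lo <- max(1L, j - w + 2L)       # window i covers j iff i <= j <= i+w-1
    hi <- min(cnt$Lwk, j + 1L)      # (1-based window rows)
    if (lo <= hi) covered[lo:hi] <- TRUE
  }
  mean(covered)
}

#' Conservation of a sketch across homologs
#'
#' Monte-Carlo estimate of the expected number of sketched k-mer
#' positions shared between the reference and a substitution-mutated
#' homolog, relative to `Lk`.  Homologs must have the same length as the
#' reference (substitution-only model), so k-mer start indices align.
#' Conservation never exceeds density.
#'
#' @param sketch_fn function mapping a sequence (character scalar) to a
#'   sketch (integer vector of 0-based indices) under the scheme being
#'   measured.
#' @param seq reference sequence.
#' @param homologs character vector (or list) of homologous sequences.
#' @param k k-mer length (for `Lk`).
#' @return mean shared-index fraction in `[0, 1]`.
#' @export
sketch_conservation <- function(sketch_fn, seq, homologs, k) {
  seq <- as_dna(seq)
  homologs <- as.list(homologs)
  if (length(homologs) == 0L) stop("need at least one homolog")
  L <- nchar(seq)
  Lk <- L - k + 1L
  ref <- sketch_fn(seq)
  shared <- vapply(homologs, function(h) {
    h <- as_dna(h)
    if (nchar(h) != L)
      stop("homolog length differs from reference; indels are unsupported")
    length(intersect(ref, sketch_fn(h))) / Lk
  }, numeric(1))
  mean(shared)
}

#' Generalized sketch score (GSS)
#'
#' Combines the three sketch metrics as
#' `(conservation / density) * coverage`; since conservation is bounded
#' by density and coverage lies in `[0, 1]`, the score lies in `[0, 1]`.
#' The empty sketch (density 0, coverage 0) is assigned 0.
#'
#' @param density,conservation,coverage metrics from the same scheme,
#'   sequence and homolog draws.
#' @return GSS in `[0, 1]`.
#' @export
gss <- function(density, conservation, coverage) {
  if (density == 0) return(0)
  (conservation / density) * coverage
}

#' All four metrics for a masked minimizer scheme
#'
#' Computes density, Monte-Carlo conservation, w-coverage and GSS for
#' the masked minimizer scheme `(w, k, mask, ordering)` on `seq`.
#' Homologs are either supplied or drawn from the i.i.d. substitution
#' model at `rate` under `seed` (common random numbers: the same seed
#' yields the same homolog set, so metrics are comparable across masks
#' and orderings).
#'
#' @inheritParams masked_minimizer_sketch
#' @param homologs optional character vector of homologous sequences; if
#'   `NULL`, `n_homologs` are simulated.
#' @param n_homologs number of homolog draws for the Monte-Carlo
#'   conservation estimate.
#' @param rate per-base substitution probability of the homolog model.
#' @param seed seed for the homolog draws.
#' @return one-row `data.frame`: `scheme`, `w`, `k`, `mask`, `density`,
#'   `conservation`, `coverage`, `gss`, `n_homologs`,
#'   `substitution_rate`, `seed`.
#' @export
sketch_metrics <- function(seq, w, k, mask, ordering, homologs = NULL,
                           n_homologs = 8L, rate = 0.05, seed = 1L) {
  seq <- if (is.numeric(seq)) codes_to_seq(as.integer(seq)) else as_dna(seq)
  w <- as.integer(w); k <- as.integer(k)
  mask <- as_mask(mask, w)
  cnt <- seq_counts(nchar(seq), w, k)
  if (is.null(homologs)) {
    homologs <- draw_homologs(seq, n = n_homologs, rate = rate, seed = seed)
  } else {
    homologs <- as.list(homologs)
    n_homologs <- length(homologs)
    rate <- NA_real_
  }
  sketch_fn <- function(s) masked_minimizer_sketch(s, w, k, mask, ordering)
  sk <- sketch_fn(seq)
  d <- sketch_density(sk, cnt$Lk)
  cons <- sketch_conservation(sketch_fn, seq, homologs, k)
  cov <- w_coverage(sk, cnt$L, w, k)
  data.frame(scheme = "masked_minimizer", w = w, k = k,
             mask = format_mask(mask),
             density = d, conservation = cons, coverage = cov,
             gss = gss(d, cons, cov),
             n_homologs = as.integer(n_homologs),
             substitution_rate = rate,
             seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
             stringsAsFactors = FALSE)
}
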
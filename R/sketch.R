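#' Minimizer sketch
#'
#' Selects from each (w,k)-window the start index of its lowest-scoring
#' k-mer under `ordering` (ties leftmost).  The sketch is the
#' deduplicated, sorted set of selected 0-based k-mer indices; every
#' (w,k)-window overlaps at least one selected index by construction.
#'
#' @param seq DNA sequence (character scalar) or 0-based code vector.
#' @param w window size in k-mers (`>= 1`).
#' @param k k-mer length.
#' @param ordering a [new_kmer_ordering()] over k-mers.
#' @return sorted integer vector of 0-based k-mer start indices.
#' @export
minimizer_sketch <- function(seq, w, k, ordering) {
  masked_minimizer_sketch(seq, w, k, minimizer_mask(w), ordering)
}

#' Masked minimizer sketch
#'
#' Like [minimizer_sketch()], but a window's minimizer is reported only
#' when its in-window offset lies in the mask `v`.  The full mask
#' recovers plain minimizers; the empty mask yields an empty sketch; and
#' for `v` a subset of `v'` the sketch under `v` is a subset of the
#' sketch under `v'`.
#'
#' @inheritParams minimizer_sketch
#' @param mask an `offset_mask` of width `w` (or an integer vector of
#'   offsets).
#' @return sorted integer vector of 0-based k-mer start indices.
#' @export
masked_minimizer_sketch <- function(seq, w, k, mask, ordering) {
  w <- as.integer(w); k <- as.integer(k)
  codes <- if (is.numeric(seq)) as.integer(seq) else chartr_codes(as_dna(seq))
  check_kmer_params(length(codes), w, k)
  mask <- as_mask(mask, w)
  if (ordering$k != k) stop("ordering k does not match requested k")
  scores <- kmer_scores(ordering, codes)
  sketch_from_scores(scores, w, mask)
}

# Shared kernel: masked minimizer sketch from a precomputed score vector.
sketch_from_scores <- function(scores, w, mask) {
  mask <- as_mask(mask, w)
  off <- window_argmin(scores, w)          # leftmost argmin per window
  keep <- off %in% mask$bits
  picks <- (which(keep) - 1L) + off[keep]  # window index + offset, 0-based
  sort(unique(picks))
}

#' Parameterized syncmer sketch
#'
#' A k-mer is sampled iff the leftmost lowest-scoring of its
#' `ks = k - s + 1` constituent s-mers sits at an offset in `v`.
#' Unlike minimizers the rule is context-free: it looks only inside each
#' k-mer.  `v = {t}` recovers open syncmers; `v = {0, ks - 1}` the closed
#' syncmer rule; the full mask samples every k-mer.
#'
#' @inheritParams minimizer_sketch
#' @param s s-mer length, `s < k`.
#' @param mask an `offset_mask` of width `ks = k - s + 1` (or an integer
#'   vector of offsets).
#' @param ordering a [new_kmer_ordering()] over s-mers.
#' @return sorted integer vector of 0-based k-mer start indices.
#' @export
parameterized_syncmer_sketch <- function(seq, k, s, mask, ordering) {
  k <- as.integer(k); s <- as.integer(s)
  if (s >= k) stop("s must be smaller than k")
  ks <- k - s + 1L
  mask <- as_mask(mask, ks)
  codes <- if (is.numeric(seq)) as.integer(seq) else chartr_codes(as_dna(seq))
  if (length(codes) < k) stop("sequence shorter than k")
  if (ordering$k != s) stop("ordering must score s-mers")
  sscores <- kmer_scores(ordering, codes)       # length L - s + 1
  off <- window_argmin(sscores, ks)             # length Lk, offset per k-mer
  which(off %in% mask$bits) - 1L
}

#' Open syncmer sketch
#'
#' Samples every k-mer whose lowest-scoring constituent s-mer sits
#' exactly at offset `t` (0-based, `t` in `[0, ks - 1]`,
#' `ks = k - s + 1`).
#'
#' @inheritParams parameterized_syncmer_sketch
#' @param t the qualifying offset.
#' @export
open_syncmer_sketch <- function(seq, k, s, t, ordering) {
  ks <- as.integer(k) - as.integer(s) + 1L
  if (length(t) != 1L || t < 0L || t > ks - 1L)
    stop(sprintf("t must lie in [0, %d]", ks - 1L))
  parameterized_syncmer_sketch(seq, k, s, new_mask(t, ks), ordering)
}

#' Brute-force reference sketcher
#'
#' Recomputes any of the four schemes by literal per-window or per-k-mer
#' scanning of freshly extracted k-mer strings, with no shared score
#' vector and no rolling-minimum reuse.  Intended as an independent
#' cross-check on small inputs only.
#'
#' @param scheme one of `"minimizer"`, `"masked_minimizer"`,
#'   `"open_syncmer"`, `"parameterized_syncmer"`.
#' @param seq DNA sequence (character scalar).
#' @param params named list of scheme parameters: `w`, `k` and `mask` for
#'   (masked) minimizers; `k`, `s` and `t` or `mask` for syncmers.
#' @param ordering a [new_kmer_ordering()] (over k-mers or s-mers as the
#'   scheme requires).
#' @return sorted integer vector of 0-based k-mer start indices.
#' @export
naive_oracle_sketch <- function(scheme, seq, params, ordering) {
  scheme <- match.arg(scheme, c("minimizer", "masked_minimizer",
                                "open_syncmer", "parameterized_syncmer"))
  x <- as_dna(seq)
  L <- nchar(x)
  k <- as.integer(params$k)
  scan_min <- function(strings) {
    # literal leftmost-argmin over explicit score calls
    best <- 1L
    best_score <- ordering$score(strings[1L])
    for (j in seq_along(strings)[-1L]) {
      sj <- ordering$score(strings[j])
      if (sj < best_score) { best <- j; best_score <- sj }
    }
    best - 1L
  }
  if (scheme %in% c("minimizer", "masked_minimizer")) {
    w <- as.integer(params$w)
    check_kmer_params(L, w, k)
    mask <- if (scheme == "minimizer") minimizer_mask(w)
            else as_mask(params$mask, w)
    Lwk <- L - (w + k - 1L) + 1L
    picks <- integer(0)
    for (i in 0:(Lwk - 1L)) {
      kmers <- vapply(0:(w - 1L), function(j)
        substr(x, i + j + 1L, i + j + k), character(1))
      m <- scan_min(kmers)
      if (m %in% mask$bits) picks <- c(picks, i + m)
    }
    return(sort(unique(picks)))
  }
  s <- as.integer(params$s)
  if (s >= k) stop("s must be smaller than k")
  ks <- k - s + 1L
  mask <- if (scheme == "open_syncmer") new_mask(params$t, ks)
          else as_mask(params$mask, ks)
  Lk <- L - k + 1L
  picks <- integer(0)
  for (i in 0:(Lk - 1L)) {
    smers <- vapply(0:(ks - 1L), function(j)
      substr(x, i + j + 1L, i + j + s), character(1))
    if (scan_min(smers) %in% mask$bits) picks <- c(picks, i)
  }
  sort(unique(picks))
}
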
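#' Uniform random DNA sequence
#'
#' I.i.d. uniform symbols over the alphabet; bit-reproducible under a
#' fixed seed without disturbing the caller's RNG stream.
#'
#' @param L sequence length (`>= 1`).
#' @param alphabet symbol set.
#' @param seed integer seed (`NULL` uses the ambient RNG stream).
#' @return character scalar of length `L`.
#' @export
random_sequence <- function(L, alphabet = DNA_ALPHABET, seed = NULL) {
  if (L < 1) stop("L must be >= 1")
  local_seed(seed, paste(sample(alphabet, L, replace = TRUE), collapse = ""))
}

#' Homopolymer-rich synthetic sequence
#'
#' A uniform random sequence into which non-overlapping single-base runs
#' are written so that runs cover approximately `fraction * L` positions.
#' Runs have length `min_run` (default 20); their count is
#' `round(fraction * L / min_run)`, so total run coverage is within one
#' run length of the target.  `fraction = 0` reduces to
#' [random_sequence()]; `fraction = 1` yields a single run covering the
#' whole sequence.
#'
#' @inheritParams random_sequence
#' @param fraction target fraction of positions inside homopolymer runs.
#' @param min_run run length (each inserted run has exactly this length).
#' @return character scalar of length `L`.
#' @export
homopolymer_sequence <- function(L, fraction, min_run = 20L,
                                 alphabet = DNA_ALPHABET, seed = NULL) {
  if (L < 1) stop("L must be >= 1")
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  if (fraction == 0) return(random_sequence(L, alphabet, seed))
  if (fraction == 1) {
    return(local_seed(seed,
      paste(rep(sample(alphabet, 1L), L), collapse = "")))
  }
  target <- fraction * L
  if (target < min_run)
    stop(sprintf(
      "infeasible homopolymer config: fraction * L = %.1f < min_run = %d",
      target, min_run))
  n_runs <- max(1L, as.integer(round(target / min_run)))
  if (n_runs * min_run > L)
    stop("infeasible homopolymer config: runs would exceed the sequence")
  local_seed(seed, {
    chars <- sample(alphabet, L, replace = TRUE)
    placed <- 0L
    occupied <- logical(L)
    tries <- 0L
    while (placed < n_runs) {
      tries <- tries + 1L
      if (tries > 1000L * n_runs)
        stop("infeasible homopolymer config: could not place runs")
      start <- sample.int(L - min_run + 1L, 1L)
      span <- start:(start + min_run - 1L)
      # keep runs disjoint and separated by >= 1 base so each stays a
      # maximal single-base run
      guard <- max(1L, start - 1L):min(L, start + min_run)
      if (any(occupied[guard])) next
      base <- sample(alphabet, 1L)
      # avoid silently extending the run into matching neighbors
      if (start > 1L && chars[start - 1L] == base)
        chars[start - 1L] <- sample(setdiff(alphabet, base), 1L)
      if (start + min_run <= L && chars[start + min_run] == base)
        chars[start + min_run] <- sample(setdiff(alphabet, base), 1L)
      chars[span] <- base
      occupied[span] <- TRUE
      placed <- placed + 1L
    }
    paste(chars, collapse = "")
  })
}

#' Substitution-mutated copy of a sequence
#'
#' Each position is independently substituted with probability `rate`;
#' a substituted base is drawn uniformly from the other three symbols,
#' so substitutions are never silent and `rate` is the expected Hamming
#' fraction.  Length is always preserved (no indels).
#'
#' @param seq reference sequence (character scalar).
#' @param rate per-base substitution probability in `[0, 1]`.
#' @param seed integer seed (`NULL` uses the ambient RNG stream).
#' @return mutated sequence of the same length.
#' @export
mutate_sequence <- function(seq, rate, seed = NULL) {
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  codes <- chartr_codes(as_dna(seq))
  a <- length(DNA_ALPHABET)
  local_seed(seed, {
    hit <- which(stats::runif(length(codes)) < rate)
    if (length(hit) > 0L) {
      shift <- sample.int(a - 1L, length(hit), replace = TRUE)
      codes[hit] <- (codes[hit] + shift) %% a
    }
    codes_to_seq(codes)
  })
}

#' Draw a panel of homologous sequences
#'
#' `n` independent substitution-mutated copies of `seq`.  With a fixed
#' `seed` the same panel is drawn every time (common random numbers),
#' which keeps conservation comparable across schemes.
#'
#' @inheritParams mutate_sequence
#' @param n number of homologs.
#' @return list of `n` sequences.
#' @export
draw_homologs <- function(seq, n, rate = 0.05, seed = NULL) {
  stopifnot(n >= 1)
  local_seed(seed, lapply(seq_len(n), function(i)
    mutate_sequence(seq, rate, seed = NULL)))
}
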
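#' Construct a k-mer ordering
#'
#' An ordering is a deterministic scoring function `score` from k-mer
#' strings to `[0, 1]`; lower scores rank earlier.  Ties between equal
#' scores are always broken by leftmost position in the window, so the
#' score function need not be injective to define a valid sampling rule.
#'
#' @param k k-mer (or s-mer) length the ordering applies to.
#' @param score function taking a character vector of k-mers and
#'   returning a numeric vector of scores in `[0, 1]`.
#' @param label short description, used by print methods.
#' @param score_codes optional fast path: a function taking a 0-based
#'   integer code vector for a whole sequence and returning the score of
#'   every k-mer position directly.  Must agree with `score`.
#' @return an object of class `kmer_ordering`.
#' @export
new_kmer_ordering <- function(k, score, label = "custom", score_codes = NULL) {
  stopifnot(k >= 1, is.function(score))
  structure(list(k = as.integer(k), score = score, label = label,
                 score_codes = score_codes,
                 tiebreak = "leftmost"),
            class = "kmer_ordering")
}

#' @export
print.kmer_ordering <- function(x, ...) {
  cat(sprintf("<kmer_ordering> k = %d, %s (ties: leftmost in window)\n",
              x$k, x$label))
  invisible(x)
}

MOD_P <- 2147483647  # 2^31 - 1, prime

# Exact (a * x) %% MOD_P for 0 <= a, x < 2^31 using double arithmetic.
# Split a into 16-bit halves so every intermediate stays below 2^53.
modmul <- function(a, x, p = MOD_P) {
  a1 <- a %/% 65536
  a0 <- a %% 65536
  (((a1 * x) %% p) * 65536 + a0 * x) %% p
}

# Base-4 integer code of every k-mer of a coded sequence, reduced mod p by
# Horner's rule.  For 4^k < p (k <= 15) this is the exact base-4 value and
# hence injective on k-mers.
kmer_hash_codes <- function(codes, k, p = MOD_P) {
  n <- length(codes) - k + 1L
  if (n < 1L) stop("sequence shorter than k")
  acc <- numeric(n)
  for (j in seq_len(k)) {
    acc <- (modmul(4, acc, p) + codes[j:(j + n - 1L)]) %% p
  }
  acc
}

#' Random one-to-one k-mer ordering
#'
#' Scores k-mers by a seeded affine map of their base-4 integer codes
#' modulo the Mersenne prime 2^31 - 1, rescaled to `[0, 1)`.  For
#' `k <= 15` the map is injective, so distinct k-mers never tie; for
#' larger k it is a high-quality hash (collisions are broken leftmost,
#' like any tie).
#'
#' @param k k-mer length.
#' @param seed integer seed fixing the ordering.
#' @return a [new_kmer_ordering()] object.
#' @export
random_ordering <- function(k, seed = 1L) {
  ab <- local_seed(seed, {
    c(2L * sample.int((MOD_P - 1L) %/% 2L, 1L) - 1L,  # odd multiplier
      sample.int(MOD_P, 1L) - 1L)
  })
  a <- ab[1L]; b <- ab[2L]
  score_hash <- function(h) ((modmul(a, h) + b) %% MOD_P) / MOD_P
  score <- function(kmers) {
    vapply(kmers, function(km) {
      if (nchar(km) != k) stop("k-mer length mismatch")
      score_hash(kmer_hash_codes(chartr_codes(km), k))
    }, numeric(1), USE.NAMES = FALSE)
  }
  score_codes <- function(codes) score_hash(kmer_hash_codes(codes, k))
  new_kmer_ordering(k, score, label = sprintf("random hash (seed %d)", seed),
                    score_codes = score_codes)
}

#' Lexicographic k-mer ordering
#'
#' Scores each k-mer by its base-4 integer value rescaled to `[0, 1)`,
#' i.e. plain alphabetical order (requires `k <= 15` for exactness).
#'
#' @param k k-mer length.
#' @return a [new_kmer_ordering()] object.
#' @export
lexicographic_ordering <- function(k) {
  stopifnot(k <= 15)
  denom <- 4^k
  score <- function(kmers) {
    vapply(kmers, function(km) {
      if (nchar(km) != k) stop("k-mer length mismatch")
      kmer_hash_codes(chartr_codes(km), k) / denom
    }, numeric(1), USE.NAMES = FALSE)
  }
  score_codes <- function(codes) kmer_hash_codes(codes, k) / denom
  new_kmer_ordering(k, score, label = "lexicographic",
                    score_codes = score_codes)
}

#' Score every k-mer position of a sequence under an ordering
#'
#' @param ordering a [new_kmer_ordering()] object.
#' @param seq DNA sequence (character scalar) or a 0-based integer code
#'   vector.
#' @return numeric vector of length `Lk = L - k + 1`.
#' @export
kmer_scores <- function(ordering, seq) {
  stopifnot(inherits(ordering, "kmer_ordering"))
  k <- ordering$k
  codes <- if (is.numeric(seq)) as.integer(seq) else chartr_codes(as_dna(seq))
  L <- length(codes)
  if (L < k) stop("sequence shorter than k")
  if (!is.null(ordering$score_codes)) {
    s <- ordering$score_codes(codes)
  } else {
    x <- codes_to_seq(codes)
    kmers <- substring(x, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
    s <- ordering$score(kmers)
  }
  if (length(s) != L - k + 1L)
    stop("ordering returned wrong number of scores")
  if (any(s < 0 | s > 1)) stop("ordering scores must lie in [0, 1]")
  s
}

#' Leftmost index of the minimum score in a window of k-mers
#'
#' The index selector `m(a, b)`: among the `b` k-mers starting at
#' positions `a, a+1, ..., a+b-1` (0-based), returns the offset
#' `j in [0, b-1]` of the lowest-scoring one, ties to the smallest `j`.
#'
#' @param seq sequence (character or code vector).
#' @param ordering a [new_kmer_ordering()] object.
#' @param a 0-based start k-mer index of the window.
#' @param b window width in k-mers.
#' @return 0-based offset of the winning k-mer within the window.
#' @export
index_selector <- function(seq, ordering, a, b) {
  stopifnot(b >= 1, a >= 0)
  s <- kmer_scores(ordering, seq)
  if (a + b > length(s))
    stop(sprintf("window [%d, %d] out of range: only %d k-mers", a, a + b - 1L,
                 length(s)))
  which.min(s[(a + 1L):(a + b)]) - 1L
}

# Leftmost argmin (0-based offset) of every length-w window of a score
# vector: row i of the implicit Lwk x w matrix is scores[i .. i+w-1].
window_argmin <- function(scores, w) {
  n <- length(scores) - w + 1L
  if (n < 1L) stop("score vector shorter than window")
  if (w == 1L) return(integer(n))
  idx <- rep(seq_len(n), w) + rep(0:(w - 1L), each = n)
  m <- matrix(scores[idx], nrow = n, ncol = w)
  max.col(-m, ties.method = "first") - 1L
}
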
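#' @keywords internal
#' @importFrom stats coef predict simulate runif rnorm setNames
#' @importFrom graphics plot legend matplot
#' @importFrom utils read.table write.table
"_PACKAGE"

DNA_ALPHABET <- c("A", "C", "G", "T")

#' Validate and normalize a DNA sequence
#'
#' Sequences are plain character scalars over a finite alphabet
#' (default `A`, `C`, `G`, `T`).  Lowercase input is uppercased.  Ambiguous
#' bases (`N`) are rejected by default with the offending position named;
#' with `n_policy = "split"` the caller should instead use
#' [split_at_ambiguous()] to obtain clean fragments.
#'
#' @param x character scalar, the sequence.
#' @param alphabet character vector of allowed single-letter symbols.
#' @param n_policy `"reject"` (default) errors on any symbol outside the
#'   alphabet; `"keep"` leaves them (used internally by
#'   [split_at_ambiguous()]).
#' @return the normalized sequence (uppercase character scalar).
#' @export
as_dna <- function(x, alphabet = DNA_ALPHABET, n_policy = c("reject", "keep")) {
  n_policy <- match.arg(n_policy)
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop("sequence must be a single character string")
  x <- toupper(x)
  if (nchar(x) < 1L)
    stop("sequence must have length >= 1")
  if (n_policy == "reject") {
    codes <- chartr_codes(x, alphabet, check = FALSE)
    bad <- which(is.na(codes))
    if (length(bad) > 0L) {
      sym <- substr(x, bad[1L], bad[1L])
      stop(sprintf("illegal symbol '%s' at position %d (1-based); alphabet is {%s}",
                   sym, bad[1L], paste(alphabet, collapse = ",")))
    }
  }
  x
}

#' Split a sequence at runs of out-of-alphabet symbols
#'
#' Alternative to the default reject policy for ambiguous bases: returns
#' the maximal clean fragments between runs of symbols outside the
#' alphabet (e.g. `N` runs).
#'
#' @inheritParams as_dna
#' @return character vector of clean fragments (possibly empty).
#' @export
split_at_ambiguous <- function(x, alphabet = DNA_ALPHABET) {
  x <- as_dna(x, alphabet, n_policy = "keep")
  codes <- chartr_codes(x, alphabet, check = FALSE)
  ok <- !is.na(codes)
  if (all(ok)) return(x)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  vapply(keep, function(i) substr(x, starts[i], ends[i]), character(1))
}

# 0-based integer codes of each symbol; NA for out-of-alphabet symbols.
chartr_codes <- function(x, alphabet = DNA_ALPHABET, check = TRUE) {
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  codes <- match(chars, alphabet) - 1L
  if (check && anyNA(codes))
    stop("sequence contains symbols outside the alphabet")
  codes
}

# Inverse of chartr_codes().
codes_to_seq <- function(codes, alphabet = DNA_ALPHABET) {
  paste(alphabet[codes + 1L], collapse = "")
}

#' Sequence length bookkeeping for (w,k)-windows
#'
#' For a sequence of length `L`: `Lk = L - k + 1` k-mers, window length
#' `wk = w + k - 1`, and `Lwk = L - wk + 1` overlapping (w,k)-windows.
#'
#' @param L sequence length.
#' @param w window size in k-mers.
#' @param k k-mer length.
#' @return named list with `L`, `Lk`, `wk`, `Lwk`.
#' @export
seq_counts <- function(L, w, k) {
  stopifnot(L >= 1, k >= 1, w >= 1)
  list(L = L, Lk = L - k + 1L, wk = w + k - 1L, Lwk = L - (w + k - 1L) + 1L)
}

check_kmer_params <- function(L, w, k) {
  if (k < 1L) stop("k must be >= 1")
  if (w < 1L) stop("w must be >= 1")
  if (L - (w + k - 1L) + 1L < 1L)
    stop(sprintf("sequence too short: need L >= w + k - 1 = %d, got %d",
                 w + k - 1L, L))
  invisible(TRUE)
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.  seed = NULL runs expr with the ambient stream.
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}
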
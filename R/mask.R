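#' Qualifying-offset masks
#'
#' A mask is a subset `v` of offsets `[0, width - 1]`.  For masked
#' minimizers the width is the window size `w`; for parameterized
#' syncmers it is the number of constituent s-mers `ks = k - s + 1`.
#' The empty mask is valid (vacuous scheme, empty sketch); the full mask
#' recovers plain minimizers (or the all-offset syncmer rule).
#'
#' @param bits integer vector of set offsets (0-based), any order,
#'   duplicates removed.
#' @param width mask width.
#' @return an object of class `offset_mask` with sorted `bits`.
#' @export
new_mask <- function(bits, width) {
  width <- as.integer(width)
  stopifnot(width >= 1)
  bits <- sort(unique(as.integer(bits)))
  if (length(bits) > 0L && (min(bits) < 0L || max(bits) >= width))
    stop(sprintf("mask offsets must lie in [0, %d]", width - 1L))
  structure(list(bits = bits, width = width), class = "offset_mask")
}

#' @rdname new_mask
#' @param w window size.
#' @export
minimizer_mask <- function(w) new_mask(0:(w - 1L), w)

#' @rdname new_mask
#' @param t single qualifying offset.
#' @export
open_syncmer_mask <- function(t, width) new_mask(t, width)

#' @rdname new_mask
#' @export
closed_syncmer_mask <- function(width) new_mask(c(0L, width - 1L), width)

#' @rdname new_mask
#' @export
complement_mask <- function(t, w) new_mask(setdiff(0:(w - 1L), t), w)

#' @export
print.offset_mask <- function(x, ...) {
  cat(sprintf("<offset_mask> width %d: %s ({%s})\n", x$width,
              format_mask(x), paste(x$bits, collapse = ",")))
  invisible(x)
}

#' @export
format.offset_mask <- function(x, ...) format_mask(x)

#' Serialize a mask as a bit-string
#'
#' Position `j` (0-based, left to right) is `1` iff offset `j` is in the
#' mask, e.g. the complement mask of offset 0 at width 5 is `"01111"`.
#'
#' @param mask an `offset_mask`.
#' @return character scalar.
#' @export
format_mask <- function(mask) {
  v <- integer(mask$width)
  v[mask$bits + 1L] <- 1L
  paste(v, collapse = "")
}

#' Parse a mask from a bit-string or comma-separated offsets
#'
#' Accepts either a bit-string (`"1111101"`, width inferred or checked)
#' or comma-separated 0-based offsets (`"0,2,5"`, width required), or the
#' keywords `"full"` and `"empty"`.
#'
#' @param x character scalar.
#' @param width mask width; required for offset lists and keywords,
#'   checked against bit-string length when given.
#' @return an `offset_mask`.
#' @export
parse_mask <- function(x, width = NULL) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- trimws(x)
  if (x == "full") {
    if (is.null(width)) stop("width required for mask keyword 'full'")
    return(minimizer_mask(width))
  }
  if (x == "empty") {
    if (is.null(width)) stop("width required for mask keyword 'empty'")
    return(new_mask(integer(0), width))
  }
  if (grepl("^[01]+$", x)) {
    if (!is.null(width) && nchar(x) != width)
      stop(sprintf("bit-string length %d != width %d", nchar(x), width))
    bits <- which(strsplit(x, "", fixed = TRUE)[[1L]] == "1") - 1L
    return(new_mask(bits, nchar(x)))
  }
  if (grepl("^[0-9]+(,[0-9]+)*$", x)) {
    if (is.null(width)) stop("width required for comma-separated mask offsets")
    return(new_mask(as.integer(strsplit(x, ",", fixed = TRUE)[[1L]]), width))
  }
  stop(sprintf("cannot parse mask '%s'", x))
}

# coerce: integer vectors allowed wherever a mask is expected
as_mask <- function(v, width) {
  if (inherits(v, "offset_mask")) {
    if (v$width != width)
      stop(sprintf("mask width %d does not match expected width %d",
                   v$width, width))
    return(v)
  }
  new_mask(v, width)
}

#' Is one mask a subset of another?
#' @param a,b `offset_mask` objects of equal width.
#' @return logical.
#' @export
mask_subset <- function(a, b) {
  stopifnot(a$width == b$width)
  all(a$bits %in% b$bits)
}
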
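#' Read a FASTA file
#'
#' Records are uppercase-normalized and validated against the alphabet.
#' Ambiguous bases are rejected with the offending record and position
#' named (`n_policy = "reject"`), or each record is split into clean
#' fragments at ambiguous runs (`n_policy = "split"`, fragments named
#' `<record>_part<i>`).
#'
#' @param path FASTA file path.
#' @param n_policy `"reject"` or `"split"`.
#' @return named character vector of sequences, in file order.
#' @export
read_fasta <- function(path, n_policy = c("reject", "split")) {
  n_policy <- match.arg(n_policy)
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop(sprintf("malformed FASTA '%s': %s", path,
                                 conditionMessage(e))))
  if (length(set) == 0L) stop(sprintf("FASTA file '%s' contains no records", path))
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(names(seqs) == ""))
    stop(sprintf("FASTA file '%s' has an empty record header", path))
  if (n_policy == "reject") {
    for (i in seq_along(seqs)) {
      tryCatch(as_dna(seqs[[i]]), error = function(e)
        stop(sprintf("record '%s': %s", names(seqs)[i], conditionMessage(e))))
    }
    return(seqs)
  }
  out <- character(0)
  for (i in seq_along(seqs)) {
    parts <- split_at_ambiguous(seqs[[i]])
    if (length(parts) == 1L && parts == seqs[[i]]) {
      out[names(seqs)[i]] <- parts
    } else if (length(parts) > 0L) {
      names(parts) <- sprintf("%s_part%d", names(seqs)[i], seq_along(parts))
      out <- c(out, parts)
    }
  }
  if (length(out) == 0L) stop("no clean fragments after splitting at ambiguous bases")
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(length(seqs) >= 1, !is.null(names(seqs)))
  set <- Biostrings::BStringSet(unlist(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Write a sketch as BED3
#'
#' One line per selected k-mer in 0-based half-open coordinates:
#' `name <tab> start <tab> start + k`, sorted by start.
#'
#' @param sketch integer vector of 0-based k-mer start indices.
#' @param name record name for column 1.
#' @param k k-mer length.
#' @param path output path (or connection).
#' @export
write_sketch_bed <- function(sketch, name, k, path) {
  sketch <- sort(unique(as.integer(sketch)))
  df <- data.frame(name = name, start = sketch, end = sketch + as.integer(k))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3 sketch back as 0-based start indices
#'
#' @param path BED file path.
#' @return data.frame with `name`, `start`, `end`.
#' @export
read_sketch_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("name", "start", "end"),
                          stringsAsFactors = FALSE)
  df
}
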
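#' Normalize a nucleotide string to the RNA alphabet
#'
#' Upper-cases the input and converts DNA thymine (T) to uracil (U). Any
#' symbol outside \code{A, C, G, U, N} is an error: downstream k-mer
#' counting understands exactly this alphabet, and windows containing
#' \code{N} are skipped rather than guessed at.
#'
#' @param x character vector of sequences.
#' @return character vector over \code{A, C, G, U, N}.
#' @export
normalize_rna <- function(x) {
  out <- chartr("t", "u", toupper(x))
  out <- chartr("T", "U", out)
  bad <- grepl("[^ACGUN]", out)
  if (any(bad))
    stop("sequence(s) ", paste(which(bad), collapse = ", "),
         " contain symbols outside {A,C,G,U,N}")
  out
}

#' Reverse complement of RNA sequences
#'
#' @param x character vector over \code{A, C, G, U, N}.
#' @return reverse complement, same alphabet.
#' @export
rna_reverse_complement <- function(x) {
  comp <- chartr("ACGUN", "UGCAN", normalize_rna(x))
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""), "")
}

#' Read peak intervals from a BED-like file
#'
#' Expects at least three tab-separated columns (chrom, start, end) with an
#' optional strand in column 6 (or column 4 when only four columns are
#' present). Coordinates follow the BED convention: 0-based, half-open.
#' Malformed lines are reported with their line numbers.
#'
#' @param path path to a BED3/BED6-style file.
#' @return a data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{strand} (class \code{peak_intervals}).
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) stop("no peak records in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("line(s) ", paste(lineno[nf < 3], collapse = ", "),
         ": fewer than 3 tab-separated columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start) | is.na(end)
  if (any(bad))
    stop("line(s) ", paste(lineno[bad], collapse = ", "),
         ": non-integer coordinates")
  if (any(end <= start))
    stop("line(s) ", paste(lineno[end <= start], collapse = ", "),
         ": end <= start (intervals are 0-based half-open and non-empty)")
  strand <- rep("+", length(lines))
  scol <- ifelse(nf >= 6, 6L, ifelse(nf >= 4, 4L, NA_integer_))
  for (i in seq_along(fields)) {
    if (!is.na(scol[i]) && fields[[i]][scol[i]] %in% c("+", "-"))
      strand[i] <- fields[[i]][scol[i]]
  }
  structure(
    data.frame(chrom = chrom, start = start, end = end, strand = strand,
               stringsAsFactors = FALSE),
    class = c("peak_intervals", "data.frame"))
}

#' Extract interval sequences from a genome
#'
#' Returns the sense-strand sequence for \code{+} intervals and the reverse
#' complement for \code{-} intervals, normalized to RNA (T becomes U).
#'
#' @param genome a named character vector of sequences, or a
#'   \code{Biostrings::XStringSet}.
#' @param intervals a data.frame as returned by [read_peaks()].
#' @return character vector of RNA sequences, one per interval.
#' @export
extract_sequence <- function(genome, intervals) {
  if (inherits(genome, "XStringSet"))
    genome <- stats::setNames(as.character(genome), names(genome))
  missing <- setdiff(unique(intervals$chrom), names(genome))
  if (length(missing))
    stop("chromosome(s) not in genome: ", paste(missing, collapse = ", "))
  lens <- nchar(genome)[intervals$chrom]
  oob <- intervals$start < 0 | intervals$end > lens
  if (any(oob))
    stop("interval(s) ", paste(which(oob), collapse = ", "),
         " out of chromosome bounds")
  seqs <- substr(genome[intervals$chrom], intervals$start + 1L, intervals$end)
  seqs <- normalize_rna(unname(seqs))
  neg <- intervals$strand == "-"
  if (any(neg)) seqs[neg] <- rna_reverse_complement(seqs[neg])
  seqs
}

#' Read a FASTA file of RNA sequences
#'
#' Parses with Biostrings and normalizes to the RNA alphabet.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta_rna <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no FASTA records in ", path)
  seqs <- normalize_rna(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("FASTA record with empty id in ", path)
  if (any(!nzchar(seqs))) stop("FASTA record with empty sequence in ", path)
  stats::setNames(unname(seqs), ids)
}

#' Write RNA sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width (default 70).
#' @return \code{path}, invisibly.
#' @export
write_fasta_rna <- function(seqs, path, width = 70) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
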
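#' Burrows-Wheeler transform
#'
#' Computes the last column of the sorted-rotation matrix of \code{text}.
#' The final character is taken as the sentinel: it must occur exactly once
#' and be lexicographically smaller than every other character.
#'
#' @param text a single string with its sentinel already appended.
#' @return the transformed string.
#' @examples
#' bwt_transform("banana$")  # "annb$aa"
#' @export
bwt_transform <- function(text) {
  stopifnot(is.character(text), length(text) == 1, nchar(text) >= 1)
  chars <- strsplit(text, "")[[1]]
  sentinel <- chars[length(chars)]
  if (sum(chars == sentinel) != 1)
    stop("sentinel '", sentinel, "' occurs inside the text")
  if (length(chars) > 1 && any(chars[-length(chars)] <= sentinel))
    stop("sentinel must be lexicographically smallest")
  cpp_bwt(text)
}

#' Build an FM-index over a set of sequences
#'
#' Sequences are concatenated with separator symbols (outside the query
#' alphabet, so matches can never straddle a sequence boundary) plus a final
#' sentinel; the suffix array, transformed text, first-column ranks and a
#' checkpointed occurrence table are kept for backward search.
#'
#' @param seqs character vector of RNA sequences over \code{A, C, G, U}.
#' @return an object of class \code{fm_index}.
#' @export
fm_index <- function(seqs) {
  seqs <- normalize_rna(seqs)
  if (any(grepl("N", seqs, fixed = TRUE)))
    stop("FM-index sequences may not contain N")
  idx <- cpp_fm_build(seqs)
  idx$names <- names(seqs) %||% as.character(seq_along(seqs))
  structure(idx, class = "fm_index")
}

#' @export
print.fm_index <- function(x, ...) {
  cat("FM-index over", x$n_seq, "sequence(s),",
      x$text_length, "symbols (incl. separators/sentinel)\n")
  invisible(x)
}

#' Exact substring search on an FM-index
#'
#' Backward search; positions agree exactly with a naive substring scan.
#' Queries containing symbols outside the index alphabet return no hits.
#'
#' @param index an [fm_index()].
#' @param query k-mer to search.
#' @return data.frame with columns \code{seq} (1-based sequence index),
#'   \code{pos} (0-based start offset).
#' @export
fm_locate <- function(index, query) {
  stopifnot(inherits(index, "fm_index"))
  hits <- cpp_fm_locate(index, toupper(query))
  data.frame(seq = hits[, 1] + 1L, pos = hits[, 2])
}

#' Enumerate the Hamming ball of a k-mer
#'
#' All k-mers over \code{A, C, G, U} within the given Hamming distance of
#' \code{root} (the "relatives" searched jointly with a seed). The ball size
#' is \eqn{\sum_{i=0}^{m} \binom{k}{i} 3^i}.
#'
#' @param root k-mer string.
#' @param max_mismatches radius (0 to k).
#' @return list with \code{root}, \code{max_mismatches} and the character
#'   vector \code{members}; class \code{relative_set}.
#' @export
enumerate_relatives <- function(root, max_mismatches) {
  root <- normalize_rna(root)
  stopifnot(max_mismatches >= 0, max_mismatches <= nchar(root))
  members <- cpp_enumerate_relatives(root, as.integer(max_mismatches))
  structure(list(root = root, max_mismatches = as.integer(max_mismatches),
                 members = members),
            class = "relative_set")
}

#' Mismatch-tolerant k-mer search via relative enumeration
#'
#' Unions exact FM-index hits over the whole Hamming ball of \code{root}.
#' Equivalent to a naive per-sequence Hamming-distance scan.
#'
#' @param index an [fm_index()].
#' @param root k-mer to search.
#' @param max_mismatches mismatch budget.
#' @return data.frame with columns \code{seq}, \code{pos}, \code{mismatches}.
#' @export
inexact_locate <- function(index, root, max_mismatches) {
  stopifnot(inherits(index, "fm_index"))
  hits <- cpp_fm_inexact_locate(index, toupper(root), as.integer(max_mismatches))
  data.frame(seq = hits[, 1] + 1L, pos = hits[, 2], mismatches = hits[, 3])
}

# mismatch budget for an expanded motif of length k: the "30% mismatches"
# rule, except the explicit two-mismatch allowance at the 6-mer seed stage
mismatch_budget <- function(k, seed_k = 6L, seed_budget = 2L) {
  ifelse(k == seed_k, seed_budget, floor(0.3 * k))
}
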
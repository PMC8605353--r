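#' Scan sequences for binding sites with a fitted model
#'
#' Locates prime-motif occurrences (inexact, the model's mismatch budget) on
#' the requested strand(s), skips occurrences whose 75-base flanks would run
#' off the sequence, featurizes each anchored context with the model's
#' schema and tensors, scores it with the classifier, and reports calls at
#' or above the threshold. Minus-strand calls are reported in forward
#' coordinates with strand \code{-}. Deterministic for a fixed model and
#' input; every reported call re-featurized in isolation reproduces its
#' score.
#'
#' @param object an \code{rbp_model}.
#' @param newdata named character vector of RNA sequences (or an
#'   XStringSet); sequences shorter than the instance length are skipped
#'   with a warning.
#' @param strand_mode \code{"sense"}, \code{"antisense"}, or \code{"both"}.
#' @param threshold score threshold (default: the model's control value,
#'   0.5).
#' @param keep_all keep sub-threshold candidates too (default FALSE).
#' @param ... unused.
#' @return data.frame of class \code{rbp_calls}: \code{seq_id},
#'   \code{strand}, \code{start}, \code{end} (0-based half-open, forward
#'   coordinates), \code{motif}, \code{mismatches}, \code{score},
#'   \code{verdict}.
#' @export
predict.rbp_model <- function(object, newdata,
                              strand_mode = c("sense", "antisense", "both"),
                              threshold = NULL, keep_all = FALSE, ...) {
  strand_mode <- match.arg(strand_mode)
  threshold <- threshold %||% object$control$threshold
  if (inherits(newdata, "XStringSet"))
    newdata <- stats::setNames(as.character(newdata), names(newdata))
  seqs <- normalize_rna(newdata)
  ids <- names(seqs) %||% as.character(seq_along(seqs))

  consensus <- object$prime_motif$consensus
  k <- nchar(consensus)
  flank <- object$instance_set$flank
  ilen <- k + 2 * flank
  budget <- mismatch_budget(k)

  short <- nchar(seqs) < ilen
  if (any(short)) {
    warning(sum(short), " sequence(s) shorter than the instance length (",
            ilen, ") skipped")
    seqs <- seqs[!short]; ids <- ids[!short]
  }

  strands <- switch(strand_mode, sense = "+", antisense = "-",
                    both = c("+", "-"))
  rows <- list()
  for (strand in strands) {
    work <- if (strand == "+") seqs else rna_reverse_complement(seqs)
    hits <- cpp_hamming_scan(work, consensus, as.integer(budget))
    for (i in seq_along(work)) {
      pos <- hits[[i]]
      pos <- pos[pos >= flank & pos + k + flank <= nchar(work[i])]
      if (length(pos) == 0) next
      inst <- substr(rep(work[i], length(pos)), pos - flank + 1,
                     pos + k + flank)
      feats <- assemble_features(inst, object$schema)
      scores <- predict(object$classifier, feats)
      mm <- vapply(pos, function(p) {
        win <- substr(work[i], p + 1, p + k)
        sum(strsplit(win, "")[[1]] != strsplit(consensus, "")[[1]])
      }, 0L)
      L <- nchar(work[i])
      start <- if (strand == "+") pos else L - (pos + k)
      rows[[length(rows) + 1]] <- data.frame(
        seq_id = ids[i], strand = strand, start = start, end = start + k,
        motif = consensus, mismatches = mm, score = as.vector(scores),
        verdict = as.vector(scores) >= threshold,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seq_id = character(0), strand = character(0),
               start = integer(0), end = integer(0), motif = character(0),
               mismatches = integer(0), score = numeric(0),
               verdict = logical(0))
  if (!keep_all) out <- out[out$verdict, , drop = FALSE]
  out <- out[order(out$seq_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rbp_calls", "data.frame")
  out
}

#' Write binding-site calls as BED6 and TSV
#'
#' BED score column is \code{round(1000 * classifier score)}; minus-strand
#' calls keep their forward-reference coordinates with strand \code{-}.
#' Empty call sets produce a header-only TSV and an empty BED.
#'
#' @param calls an \code{rbp_calls} data.frame.
#' @param prefix output path prefix (writes \code{<prefix>.bed} and
#'   \code{<prefix>.tsv}).
#' @return \code{prefix}, invisibly.
#' @export
report_calls <- function(calls, prefix) {
  bed_path <- paste0(prefix, ".bed")
  tsv_path <- paste0(prefix, ".tsv")
  if (nrow(calls) > 0) {
    bed <- data.frame(calls$seq_id, calls$start, calls$end, calls$motif,
                      round(1000 * calls$score), calls$strand)
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    file.create(bed_path)
  }
  write.table(as.data.frame(calls), tsv_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(prefix)
}

#' Collapse overlapping calls
#'
#' Optional greedy merge: calls on the same sequence and strand overlapping
#' by at least \code{min_overlap} of the shorter anchor keep only the
#' highest-scoring representative.
#'
#' @param calls an \code{rbp_calls} data.frame.
#' @param min_overlap overlap fraction triggering a merge (default 0.5).
#' @return filtered \code{rbp_calls}.
#' @export
merge_calls <- function(calls, min_overlap = 0.5) {
  if (nrow(calls) < 2) return(calls)
  keep <- rep(TRUE, nrow(calls))
  ord <- order(-calls$score)
  for (a in seq_along(ord)) {
    i <- ord[a]
    if (!keep[i]) next
    for (b in seq_along(ord)) {
      j <- ord[b]
      if (j == i || !keep[j] || calls$score[j] > calls$score[i]) next
      if (calls$seq_id[i] != calls$seq_id[j] ||
          calls$strand[i] != calls$strand[j]) next
      ov <- min(calls$end[i], calls$end[j]) - max(calls$start[i], calls$start[j])
      wl <- min(calls$end[i] - calls$start[i], calls$end[j] - calls$start[j])
      if (ov >= min_overlap * wl) keep[j] <- FALSE
    }
  }
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
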
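#' Filter peaks by length and deduplicate
#'
#' Keeps peaks of 5 to 300 bases (inclusive: the discard rule removes
#' lengths below 5 and above 300) and collapses duplicates (identical
#' coordinates and strand for interval input; identical sequence strings for
#' sequence input).
#'
#' @param peaks a \code{peak_intervals} data.frame or a character vector of
#'   peak sequences.
#' @return the retained peaks, same type as the input.
#' @export
filter_peaks <- function(peaks) {
  if (is.data.frame(peaks)) {
    len <- peaks$end - peaks$start
    keep <- len >= 5 & len <= 300
    out <- peaks[keep, , drop = FALSE]
    key <- paste(out$chrom, out$start, out$end, out$strand)
    out <- out[!duplicated(key), , drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    len <- nchar(peaks)
    out <- peaks[len >= 5 & len <= 300]
    out[!duplicated(out)]
  }
}

#' Does an RBP have enough unique peaks to model?
#'
#' Model building requires more than 500 unique binding peaks.
#'
#' @param peaks deduplicated peaks (intervals or sequences).
#' @return \code{TRUE} when the peak count exceeds 500 (strict).
#' @export
rbp_eligible <- function(peaks) {
  n <- if (is.data.frame(peaks)) nrow(peaks) else length(peaks)
  n > 500
}

instance_length <- function(motif_length, flank = 75) motif_length + 2L * flank

# occurrences of the motif in each sequence; returns data.frame(seq, pos)
motif_occurrences <- function(seqs, consensus, budget) {
  hits <- cpp_hamming_scan(seqs, consensus, as.integer(budget))
  data.frame(seq = rep(seq_along(seqs), lengths(hits)),
             pos = unlist(hits) %||% integer(0))
}

# build instances from motif occurrences inside source sequences: every
# occurrence whose +/- flank fits inside the source contributes one instance
instances_from_sources <- function(sources, ids, consensus, budget, flank,
                                   strategy = NA_character_) {
  k <- nchar(consensus)
  occ <- motif_occurrences(sources, consensus, budget)
  if (nrow(occ) == 0)
    return(data.frame(sequence = character(0), origin = character(0),
                      anchor_start = integer(0), strategy = character(0)))
  lens <- nchar(sources)[occ$seq]
  ok <- occ$pos >= flank & occ$pos + k + flank <= lens
  occ <- occ[ok, , drop = FALSE]
  data.frame(
    sequence = substr(sources[occ$seq], occ$pos - flank + 1,
                      occ$pos + k + flank),
    origin = ids[occ$seq],
    anchor_start = occ$pos,
    strategy = strategy,
    stringsAsFactors = FALSE)
}

#' Build positive instances around anchored prime-motif occurrences
#'
#' Every prime-motif occurrence (inexact, mismatch budget
#' \code{floor(0.3 k)}) in a peak is expanded by \code{flank} bases on both
#' sides; peaks with several occurrences contribute several instances. With
#' interval input the flanks come from the source genome/transcript, so they
#' may extend beyond the peak; occurrences whose flanks run off the source
#' sequence are skipped so that all instances share the same length
#' (motif length + 2 flank).
#'
#' @param peaks \code{peak_intervals} data.frame (with \code{genome}) or a
#'   character vector of peak-region sequences long enough to hold the
#'   flanks.
#' @param genome named character vector (or XStringSet) backing the
#'   intervals; ignored for sequence input.
#' @param prime_motif a \code{prime_motif} (or consensus string).
#' @param flank flank width (default 75).
#' @return data.frame of instances: \code{sequence}, \code{origin},
#'   \code{anchor_start} (0-based within the source), \code{strategy} (NA).
#' @export
build_positive <- function(peaks, genome = NULL, prime_motif, flank = 75) {
  consensus <- if (inherits(prime_motif, "prime_motif"))
    prime_motif$consensus else normalize_rna(prime_motif)
  budget <- mismatch_budget(nchar(consensus))
  if (is.data.frame(peaks)) {
    if (is.null(genome)) stop("interval input requires a genome")
    if (inherits(genome, "XStringSet"))
      genome <- stats::setNames(as.character(genome), names(genome))
    genome <- normalize_rna(genome)
    # search within the peak, then pull flanks from the source sequence
    peak_seqs <- extract_sequence(genome, peaks)
    k <- nchar(consensus)
    occ <- motif_occurrences(peak_seqs, consensus, budget)
    if (nrow(occ) == 0) stop("prime motif not found in any peak")
    rows <- lapply(seq_len(nrow(occ)), function(i) {
      pk <- peaks[occ$seq[i], ]
      p <- occ$pos[i]
      if (pk$strand == "+") {
        mstart <- pk$start + p
      } else {
        mstart <- pk$end - p - k
      }
      istart <- mstart - flank; iend <- mstart + k + flank
      if (istart < 0 || iend > nchar(genome[[pk$chrom]])) return(NULL)
      iv <- data.frame(chrom = pk$chrom, start = istart, end = iend,
                       strand = pk$strand)
      data.frame(sequence = extract_sequence(genome, iv),
                 origin = sprintf("%s:%d-%d(%s)", pk$chrom, pk$start,
                                  pk$end, pk$strand),
                 anchor_start = p, strategy = NA_character_,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out) || nrow(out) == 0)
      stop("no motif occurrence had full flanks inside the source sequence")
    rownames(out) <- NULL
    out
  } else {
    peaks <- normalize_rna(peaks)
    ids <- names(peaks) %||% as.character(seq_along(peaks))
    out <- instances_from_sources(peaks, ids, consensus, budget, flank)
    if (nrow(out) == 0) stop("prime motif (with full flanks) not found in any peak")
    out
  }
}

#' Build Set A negatives: motif sites on expressed-but-unbound transcripts
#'
#' Instances are anchored exactly as positives, but on transcripts that
#' never appear in the peak data for this RBP (expressed in the same
#' condition, unbound).
#'
#' @param transcripts named character vector of unbound transcript
#'   sequences.
#' @param prime_motif the anchor motif.
#' @param flank flank width (default 75).
#' @param bound_ids transcript ids that appear in the peak data; any
#'   transcript listed here is excluded.
#' @param n_required minimum number of negatives needed to balance the
#'   classes (optional); a shortfall is an error naming the deficit.
#' @return data.frame of instances (strategy \code{"A"}).
#' @export
build_negative_setA <- function(transcripts, prime_motif, flank = 75,
                                bound_ids = character(0), n_required = NULL) {
  consensus <- if (inherits(prime_motif, "prime_motif"))
    prime_motif$consensus else normalize_rna(prime_motif)
  transcripts <- normalize_rna(transcripts)
  ids <- names(transcripts) %||% as.character(seq_along(transcripts))
  keep <- !(ids %in% bound_ids)
  out <- instances_from_sources(transcripts[keep], ids[keep], consensus,
                                mismatch_budget(nchar(consensus)), flank,
                                strategy = "A")
  if (!is.null(n_required) && nrow(out) < n_required)
    stop("Set A shortfall: need ", n_required, " negatives but only ",
         nrow(out), " motif-bearing unbound instances are available")
  out
}

#' Build Set B negatives: distal motif sites on bound transcripts
#'
#' Motif occurrences on transcripts that do overlap peaks, but lying at
#' least \code{min_distance} bases from every peak on that transcript (and
#' never overlapping one), expanded by the usual flanks.
#'
#' @param transcripts named character vector of bound transcript sequences.
#' @param peak_intervals data.frame with \code{chrom} (transcript id),
#'   \code{start}, \code{end} giving peak positions on those transcripts.
#' @param prime_motif the anchor motif.
#' @param flank flank width (default 75).
#' @param min_distance minimum anchor-to-peak separation (default 300).
#' @return data.frame of instances (strategy \code{"B"}); may under-fill.
#' @export
build_negative_setB <- function(transcripts, peak_intervals, prime_motif,
                                flank = 75, min_distance = 300) {
  consensus <- if (inherits(prime_motif, "prime_motif"))
    prime_motif$consensus else normalize_rna(prime_motif)
  k <- nchar(consensus)
  transcripts <- normalize_rna(transcripts)
  ids <- names(transcripts) %||% as.character(seq_along(transcripts))
  bound <- ids[ids %in% unique(peak_intervals$chrom)]
  rows <- list()
  for (id in bound) {
    pks <- peak_intervals[peak_intervals$chrom == id, , drop = FALSE]
    occ <- motif_occurrences(transcripts[id], consensus,
                             mismatch_budget(k))
    if (nrow(occ) == 0) next
    for (p in occ$pos) {
      if (p < flank || p + k + flank > nchar(transcripts[[id]])) next
      dist <- pmax(pks$start - (p + k), p - pks$end)   # gap to each peak
      if (any(dist < min_distance)) next
      rows[[length(rows) + 1]] <- data.frame(
        sequence = substr(transcripts[[id]], p - flank + 1, p + k + flank),
        origin = id, anchor_start = p, strategy = "B",
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(sequence = character(0), origin = character(0),
                      anchor_start = integer(0), strategy = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Balance classes and split into train/test partitions
#'
#' Drops any sequence string present in both classes (leakage), downsamples
#' the larger class to exact balance, and performs a stratified,
#' seed-deterministic split. No sequence string appears in both partitions.
#'
#' @param positives,negatives instance data.frames (from the builders).
#' @param motif_length length of the anchor motif.
#' @param train_fraction fraction assigned to training (0.6 during feature
#'   evaluation, 0.7 for final models).
#' @param rng_seed integer seed controlling the downsampling and split.
#' @param min_per_class minimum class size after balancing (default 50).
#' @param flank flank width used when building the instances (default 75).
#' @return an \code{instance_set}: data.frame \code{instances} with columns
#'   \code{sequence}, \code{label} (1/0), \code{origin}, \code{strategy},
#'   \code{split}, plus metadata fields.
#' @export
balance_and_split <- function(positives, negatives, motif_length,
                              train_fraction = 0.7, rng_seed = 1,
                              min_per_class = 50, flank = 75) {
  if (nrow(positives) == 0 || nrow(negatives) == 0)
    stop("both classes must be non-empty")
  leaked <- intersect(positives$sequence, negatives$sequence)
  if (length(leaked) > 0) {
    warning(length(leaked),
            " sequence(s) occurred in both classes and were dropped")
    positives <- positives[!positives$sequence %in% leaked, , drop = FALSE]
    negatives <- negatives[!negatives$sequence %in% leaked, , drop = FALSE]
  }
  ilen <- instance_length(motif_length, flank)
  stopifnot(all(nchar(positives$sequence) == ilen),
            all(nchar(negatives$sequence) == ilen))
  n <- min(nrow(positives), nrow(negatives))
  if (n < min_per_class)
    stop("fewer than ", min_per_class, " instances per class after balancing")
  with_seed(rng_seed, {
    pos <- positives[sample(nrow(positives), n), , drop = FALSE]
    neg <- negatives[sample(nrow(negatives), n), , drop = FALSE]
    ntr <- round(train_fraction * n)
    split_of <- function() {
      s <- rep("test", n); s[sample(n, ntr)] <- "train"; s
    }
    pos$split <- split_of()
    neg$split <- split_of()
  })
  pos$label <- 1L; neg$label <- 0L
  inst <- rbind(pos, neg)
  rownames(inst) <- NULL
  structure(list(instances = inst, motif_length = motif_length,
                 instance_length = ilen, flank = flank,
                 train_fraction = train_fraction, rng_seed = rng_seed),
            class = "instance_set")
}

#' @export
print.instance_set <- function(x, ...) {
  tab <- table(x$instances$label, x$instances$split)
  cat(sprintf("<instance_set> %d instances of length %d (motif %d + 2x%d flanks)\n",
              nrow(x$instances), x$instance_length, x$motif_length, x$flank))
  cat(sprintf("  train: %d pos / %d neg; test: %d pos / %d neg\n",
              tab["1", "train"], tab["0", "train"],
              tab["1", "test"], tab["0", "test"]))
  invisible(x)
}

#' Serialize an instance set as FASTA plus a TSV manifest
#'
#' Record ids encode label, strategy and origin; the manifest carries the
#' full metadata.
#'
#' @param x an \code{instance_set}.
#' @param prefix output path prefix (writes \code{<prefix>.fa} and
#'   \code{<prefix>.tsv}).
#' @return \code{prefix}, invisibly.
#' @export
write_instance_set <- function(x, prefix) {
  inst <- x$instances
  ids <- sprintf("inst%05d|label=%d|strategy=%s|split=%s|origin=%s",
                 seq_len(nrow(inst)), inst$label,
                 ifelse(is.na(inst$strategy), ".", inst$strategy),
                 inst$split, inst$origin)
  write_fasta_rna(stats::setNames(inst$sequence, ids), paste0(prefix, ".fa"))
  write.table(cbind(id = sprintf("inst%05d", seq_len(nrow(inst))), inst),
              paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(prefix)
}
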
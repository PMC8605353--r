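#' Offsets of a candidate motif relative to an anchored motif
#'
#' For each anchored instance sequence, finds the candidate occurrence
#' nearest to the anchor (smallest absolute offset) within the flanking
#' window and reports its signed offset: candidate start minus anchor start,
#' so a candidate sitting at the anchor gives 0 and one 30 bases upstream
#' gives -30. Instances without a candidate hit contribute nothing.
#'
#' @param instances character vector of anchored instance sequences
#'   (anchor at columns \code{flank + 1 .. flank + motif length}).
#' @param anchor_motif the anchor \code{prime_motif} (or consensus string).
#' @param candidate_motif the candidate \code{prime_motif} (or string).
#' @param flank flank width on each side (default 75).
#' @param budget candidate mismatch budget (default \code{floor(0.3 k)}).
#' @return integer vector of signed offsets in \code{[-flank, +flank]}.
#' @export
distance_distribution <- function(instances, anchor_motif, candidate_motif,
                                  flank = 75, budget = NULL) {
  cand <- if (inherits(candidate_motif, "prime_motif"))
    candidate_motif$consensus else normalize_rna(candidate_motif)
  if (nchar(cand) > flank) stop("candidate motif longer than the flank window")
  budget <- budget %||% mismatch_budget(nchar(cand))
  hits <- cpp_hamming_scan(instances, cand, as.integer(budget))
  offs <- lapply(hits, function(h) {
    if (length(h) == 0) return(integer(0))
    d <- h - flank                       # candidate start relative to anchor start
    d[which.min(abs(d))]
  })
  out <- unlist(offs)
  out[abs(out) <= flank]
}

#' Two-sample KS test on co-occurrence offsets
#'
#' Compares observed anchor-to-candidate offsets against offsets measured in
#' a random/background corpus. Small samples (n < 5 on either side) trigger
#' a warning and are flagged unstable.
#'
#' @param observed_offsets offsets from the bound instances.
#' @param random_offsets offsets from the background corpus.
#' @return list with \code{D}, \code{pvalue}, \code{unstable}.
#' @export
ks_cooccurrence_test <- function(observed_offsets, random_offsets) {
  if (length(observed_offsets) == 0 || length(random_offsets) == 0)
    stop("both offset samples must be non-empty")
  unstable <- length(observed_offsets) < 5 || length(random_offsets) < 5
  if (unstable)
    warning("KS test on fewer than 5 offsets; p-value is unstable")
  kt <- suppressWarnings(ks.test(observed_offsets, random_offsets))
  list(D = unname(kt$statistic), pvalue = kt$p.value, unstable = unstable)
}

#' Frequency ratio of a motif pair
#'
#' Conditional-rate ratio measuring the tendency of a candidate motif to
#' co-occur with the anchor: \eqn{FR = (N/X) / (M/Y)} where \code{X}
#' sequences contain the anchor, \code{N} of those also contain the
#' candidate, \code{Y} sequences lack the anchor and \code{M} of those
#' contain the candidate. \code{FR > 1} means enrichment alongside the
#' anchor. \code{N = 0} gives 0; \code{M = 0} with \code{N > 0} gives
#' \code{Inf}.
#'
#' @param X sequences containing the anchor motif (count > 0).
#' @param N among \code{X}, sequences also containing the candidate.
#' @param Y sequences lacking the anchor motif (count > 0).
#' @param M among \code{Y}, sequences containing the candidate.
#' @return the frequency ratio.
#' @export
frequency_ratio <- function(X, N, Y, M) {
  if (X <= 0 || Y <= 0) stop("X and Y must be positive")
  if (N == 0) return(0)
  if (M == 0) return(Inf)
  (N / X) / (M / Y)
}

#' Hypergeometric over-representation test for motif co-occurrence
#'
#' Upper-tail probability of seeing at least \code{with_both} sequences
#' carrying both motifs under hypergeometric sampling.
#'
#' @param universe total number of sequences.
#' @param with_m1 sequences containing motif 1.
#' @param with_m2 sequences containing motif 2.
#' @param with_both sequences containing both.
#' @return p-value.
#' @export
hypergeometric_cooccurrence <- function(universe, with_m1, with_m2, with_both) {
  if (with_both > min(with_m1, with_m2) || max(with_m1, with_m2) > universe)
    stop("inconsistent counts")
  phyper(with_both - 1, with_m1, universe - with_m1, with_m2,
         lower.tail = FALSE)
}

#' Shift-maximized Jaccard-style PWM similarity
#'
#' Aligns two position-frequency matrices at every relative shift with at
#' least \code{min_overlap} overlapping columns; each aligned column
#' contributes its min/max frequency-vector ratio, summed and divided by
#' the shorter motif's width (off-overlap columns count as disagreement).
#' The best shift's raw agreement is then rescaled against the 0.25
#' alphabet-chance level, so unrelated motifs score near 0 and identical
#' ones score 1. Symmetric; used to screen out candidate partners that are
#' really the anchor motif again (threshold 0.2).
#'
#' @param pwmA,pwmB 4-row count or frequency matrices (rows A, C, G, U), or
#'   \code{prime_motif} objects.
#' @param min_overlap minimum aligned columns (default 4, or the shorter
#'   motif's width if smaller).
#' @return similarity in \code{[0, 1]}.
#' @export
pwm_jaccard <- function(pwmA, pwmB, min_overlap = 4) {
  get_freq <- function(p) {
    if (inherits(p, "prime_motif")) p <- p$pwm
    sweep(p, 2, pmax(colSums(p), .Machine$double.eps), "/")
  }
  fa <- get_freq(pwmA); fb <- get_freq(pwmB)
  la <- ncol(fa); lb <- ncol(fb)
  min_overlap <- min(min_overlap, la, lb)
  best <- 0
  for (shift in -(lb - 1):(la - 1)) {
    ia <- max(0, shift); ib <- max(0, -shift)
    ov <- min(la - ia, lb - ib)
    if (ov < min_overlap) next
    vals <- vapply(seq_len(ov), function(j) {
      a <- fa[, ia + j]; b <- fb[, ib + j]
      sum(pmin(a, b)) / sum(pmax(a, b))
    }, 0)
    best <- max(best, sum(vals) / min(la, lb))
  }
  max(0, (best - 0.25) / 0.75)
}

#' Mononucleotide shuffle of sequences
#'
#' Per-sequence random permutation of the bases: preserves base composition
#' and length while destroying motifs and dinucleotide structure. The
#' standard null for motif co-occurrence screening.
#'
#' @param seqs character vector of sequences.
#' @param seed RNG seed.
#' @return shuffled sequences, same lengths.
#' @export
shuffle_sequences <- function(seqs, seed = NULL) {
  with_seed(seed, vapply(strsplit(seqs, ""), function(ch)
    paste(sample(ch), collapse = ""), ""))
}

#' Candidate secondary motifs from the positive instance set
#'
#' A co-occurring partner concentrates at a preferred offset from the
#' anchor, so candidates are ranked by *positional* excess: for every 6-mer
#' family the per-position match fraction (mismatch radius 2) is computed on
#' the positive instances and on their composition-matched shuffle, and the
#' seed's score is the maximum per-position difference. Diffuse
#' compositional signal (e.g. CG-rich context) barely moves any single
#' position and is screened out, while a planted partner produces a sharp
#' spike. Top seeds are deduplicated against the anchor and each other and
#' expanded on the instances (column-agreement threshold relaxed to 0.5
#' because only the carrier subset aligns at the planted offset).
#'
#' @param instances positive instance sequences.
#' @param background shuffle/background instance sequences, same length.
#' @param anchor the anchor \code{prime_motif}.
#' @param n_candidates candidates to return (default 8).
#' @param radius seed mismatch radius (default 2).
#' @param min_excess minimum peak positional excess (default 0.08).
#' @param flank flank width; positions overlapping the anchor columns are
#'   masked so the anchor's own relatives cannot dominate (default 75).
#' @return list of \code{prime_motif} objects (kind \code{"candidate"}).
#' @export
cooccurrence_candidates <- function(instances, background, anchor,
                                    n_candidates = 8, radius = 2,
                                    min_excess = 0.08, flank = 75) {
  tp <- cpp_kmer_tensor(instances, 6L, as.integer(radius))
  tb <- cpp_kmer_tensor(background, 6L, as.integer(radius))
  diff <- tp - tb
  # mask window positions overlapping the anchored motif
  k_anchor <- nchar(anchor$consensus)
  mask <- seq(max(1, flank - 4), min(ncol(diff), flank + k_anchor))
  diff[, mask] <- 0
  excess <- apply(diff, 1, max)
  at_pos <- apply(diff, 1, which.max)
  seeds <- kmer_spectrum(6)
  ord <- order(-excess)
  taken <- anchor$consensus
  out <- list()
  for (i in ord) {
    if (length(out) >= n_candidates || excess[i] < min_excess) break
    cand <- positional_expand(instances, seeds[i], at_pos[i], radius = radius)
    if (is.null(cand)) next
    if (any(vapply(taken, function(t)
      consensus_identity(cand$consensus, t) >= 0.7, TRUE))) next
    out[[length(out) + 1]] <- cand
    taken <- c(taken, cand$consensus)
  }
  out
}

# grow a candidate consensus anchored near a fixed instance position.
# Long instances saturate global best-hit alignment for short k-mers, so the
# candidate is anchored where its positional signal peaks; instances are
# re-aligned locally (within +/- `slack` columns, to absorb offset jitter)
# to the current consensus, the consensus is refined to the aligned column
# majority, and it grows into adjacent columns while the majority base
# stays frequent enough (EM-style, a few iterations).
positional_expand <- function(instances, seed, start, max_len = 10,
                              min_identity = 0.6, min_count = 20,
                              radius = 2, slack = 3) {
  n <- length(instances)
  L <- nchar(instances[1])
  align <- function(cons, start) {
    k <- nchar(cons)
    cc <- strsplit(cons, "")[[1]]
    offs <- start + order(abs(-slack:slack)) - slack - 1  # centre first
    offs <- offs[offs >= 1 & offs + k - 1 <= L]
    mm <- matrix(NA_integer_, n, length(offs))
    for (j in seq_along(offs)) {
      m <- do.call(rbind, strsplit(substr(instances, offs[j],
                                          offs[j] + k - 1), ""))
      mm[, j] <- rowSums(m != matrix(cc, n, k, byrow = TRUE))
    }
    bj <- apply(mm, 1, which.min)
    bmm <- mm[cbind(seq_len(n), bj)]
    sel <- which(bmm <= mismatch_budget(k))
    list(sel = sel, off = offs[bj][sel])
  }
  column <- function(sel, off) substr(instances[sel], off, off)
  maj_of <- function(col) {
    tab <- table(factor(col, levels = c("A", "C", "G", "U")))
    list(base = names(tab)[which.max(tab)], freq = max(tab) / length(col))
  }
  cons <- seed
  al <- align(cons, start)
  if (length(al$sel) < min_count) return(NULL)
  for (it in 1:10) {
    k <- nchar(cons)
    # refine to the aligned column majority
    newc <- vapply(seq_len(k), function(j)
      maj_of(column(al$sel, al$off + j - 1))$base, "")
    cons2 <- paste(newc, collapse = "")
    changed <- cons2 != cons
    if (changed) {
      cons <- cons2
      al <- align(cons, start)
      if (length(al$sel) < min_count) return(NULL)
    }
    # try one extension on each side
    extended <- FALSE
    if (nchar(cons) < max_len) {
      ok <- al$off > 1
      if (sum(ok) >= min_count) {
        mj <- maj_of(column(al$sel[ok], al$off[ok] - 1))
        if (mj$freq >= min_identity) {
          cons <- paste0(mj$base, cons)
          start <- start - 1
          al <- align(cons, start)
          if (length(al$sel) < min_count) return(NULL)
          extended <- TRUE
        }
      }
    }
    if (nchar(cons) < max_len) {
      k <- nchar(cons)
      ok <- al$off + k <= L
      if (sum(ok) >= min_count) {
        mj <- maj_of(column(al$sel[ok], al$off[ok] + k))
        if (mj$freq >= min_identity) {
          cons <- paste0(cons, mj$base)
          al <- align(cons, start)
          if (length(al$sel) < min_count) return(NULL)
          extended <- TRUE
        }
      }
    }
    if (!extended && !changed) break
  }
  k <- nchar(cons)
  pwm <- matrix(0L, 4, k, dimnames = list(c("A", "C", "G", "U"), NULL))
  for (j in seq_len(k)) {
    tab <- table(factor(column(al$sel, al$off + j - 1),
                        levels = rownames(pwm)))
    pwm[, j] <- as.integer(tab)
  }
  new_prime_motif(cons, pwm, length(al$sel) / n, al$sel, "candidate",
                  NA_real_)
}

onehot_pwm <- function(consensus) {
  chars <- strsplit(consensus, "")[[1]]
  pwm <- matrix(0, 4, length(chars), dimnames = list(c("A", "C", "G", "U"), NULL))
  for (j in seq_along(chars)) pwm[chars[j], j] <- 1
  pwm
}

#' Evaluate candidate motifs for co-occurrence with an anchor
#'
#' For each candidate, measures the anchor-relative offset distribution in
#' the bound instances and in a background instance set, and applies the
#' four screening criteria: KS p < \code{ks_cutoff}, hypergeometric
#' p < 0.05, frequency ratio > 1, and PWM Jaccard similarity to the anchor
#' < 0.2.
#'
#' @param instances anchored positive instance sequences.
#' @param background background instance sequences of the same length
#'   (random or negative set).
#' @param anchor the anchor \code{prime_motif}.
#' @param candidates list of candidate \code{prime_motif}s.
#' @param flank flank width (default 75).
#' @param ks_cutoff KS significance threshold (default 0.05; the stricter
#'   0.01 used for screening pairs is available via this knob).
#' @return data.frame with counts (X, N, Y, M), FR, KS D and p,
#'   hypergeometric p, Jaccard, and the verdict, one row per candidate;
#'   offset vectors attached as the \code{"offsets"} attribute.
#' @export
find_cooccurring <- function(instances, background, anchor, candidates,
                             flank = 75, ks_cutoff = 0.05) {
  stopifnot(length(candidates) > 0)
  has_motif <- function(seqs, motif) {
    hits <- cpp_hamming_scan(seqs, motif$consensus,
                             mismatch_budget(nchar(motif$consensus)))
    lengths(hits) > 0
  }
  all_seqs <- c(instances, background)
  anchor_in <- c(rep(TRUE, length(instances)), has_motif(background, anchor))
  X <- sum(anchor_in); Y <- sum(!anchor_in)
  rows <- list(); offsets <- list()
  for (ci in seq_along(candidates)) {
    cand <- candidates[[ci]]
    cand_in <- has_motif(all_seqs, cand)
    N <- sum(cand_in & anchor_in)
    M <- sum(cand_in & !anchor_in)
    fr <- frequency_ratio(X, N, Y, M)
    hp <- hypergeometric_cooccurrence(length(all_seqs), X, sum(cand_in), N)
    obs <- distance_distribution(instances, anchor, cand, flank = flank)
    rnd <- distance_distribution(background, anchor, cand, flank = flank)
    ks <- if (length(obs) >= 1 && length(rnd) >= 1)
      tryCatch(suppressWarnings(ks_cooccurrence_test(obs, rnd)),
               error = function(e) list(D = NA_real_, pvalue = NA_real_))
    else list(D = NA_real_, pvalue = NA_real_)
    # screen on the consensus profiles: count PWMs from mismatch-tolerant
    # matching are dominated by the mismatch dilution and all look alike
    jac <- pwm_jaccard(onehot_pwm(anchor$consensus),
                       onehot_pwm(cand$consensus))
    verdict <- isTRUE(ks$pvalue < ks_cutoff) && isTRUE(hp < 0.05) &&
      isTRUE(fr > 1) && jac < 0.2
    rows[[ci]] <- data.frame(
      anchor = anchor$consensus, partner = cand$consensus,
      X = X, N = N, Y = Y, M = M, FR = fr,
      ks_D = ks$D, ks_pvalue = ks$pvalue, hyper_pvalue = hp,
      jaccard = jac, significant = verdict)
    offsets[[cand$consensus]] <- obs
  }
  out <- do.call(rbind, rows)
  attr(out, "offsets") <- offsets
  out
}

#' Write a co-occurrence pair report and offset histograms
#'
#' @param pairs data.frame from [find_cooccurring()].
#' @param path output TSV path; offset histograms go to
#'   \code{<path>.offsets.tsv}.
#' @return \code{path}, invisibly.
#' @export
write_cooccurrence_tsv <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  offs <- attr(pairs, "offsets")
  if (!is.null(offs) && length(offs)) {
    hist_df <- do.call(rbind, lapply(names(offs), function(p) {
      if (length(offs[[p]]) == 0) return(NULL)
      tab <- table(offs[[p]])
      data.frame(partner = p, offset = as.integer(names(tab)),
                 count = as.integer(tab))
    }))
    if (!is.null(hist_df))
      write.table(hist_df, paste0(path, ".offsets.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
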
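#' All k-mers over the RNA alphabet
#'
#' The seed spectrum searched during discovery: \eqn{4^k} strings in
#' lexicographic order (4,096 for the default 6-mers).
#'
#' @param k k-mer length (default 6).
#' @return character vector of length \code{4^k}.
#' @export
kmer_spectrum <- function(k = 6) {
  bases <- c("A", "C", "G", "U")
  grid <- do.call(expand.grid,
                  c(rep(list(bases), k), stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; reverse for lexicographic
  do.call(paste0, rev(grid))
}

kmer_to_code <- function(kmers) {
  k <- nchar(kmers[1])
  m <- t(vapply(strsplit(chartr("ACGU", "0123", kmers), ""),
                as.integer, integer(k)))
  if (k == 1) m <- matrix(as.integer(unlist(strsplit(chartr("ACGU", "0123", kmers), ""))), ncol = 1)
  as.integer(m %*% 4^((k - 1):0))
}

code_to_kmer <- function(codes, k) {
  bases <- c("A", "C", "G", "U")
  out <- character(length(codes))
  for (i in seq_along(codes)) {
    c0 <- codes[i]
    chs <- character(k)
    for (j in k:1) { chs[j] <- bases[c0 %% 4 + 1]; c0 <- c0 %/% 4 }
    out[i] <- paste(chs, collapse = "")
  }
  out
}

#' Count sequences hit by every possible k-mer seed
#'
#' Builds an FM-index over \code{seqs} and, for each of the \eqn{4^k}
#' possible seeds, counts the sequences containing the seed or any relative
#' within the mismatch budget.
#'
#' @param seqs character vector of RNA sequences.
#' @param k seed length (default 6).
#' @param budget mismatch budget (default 2, the seed-stage allowance).
#' @return named integer vector of length \code{4^k} (names are the seeds in
#'   lexicographic order).
#' @export
scan_seed_counts <- function(seqs, k = 6, budget = 2) {
  idx <- fm_index(seqs)
  counts <- cpp_fm_seed_scan(idx, as.integer(k), as.integer(budget))
  names(counts) <- kmer_spectrum(k)
  counts
}

#' Null occurrence probability of a seed family
#'
#' Fraction of random-corpus sequences containing the seed or a relative
#' within the radius. A zero count is floored at the pseudo-probability
#' \code{1/(2 * length(corpus))} so the binomial test stays defined.
#'
#' @param seed k-mer.
#' @param random_corpus character vector of length-matched random sequences.
#' @param radius mismatch radius (default 2).
#' @return probability in (0, 1).
#' @export
null_probability <- function(seed, random_corpus, radius = 2) {
  n <- length(random_corpus)
  if (n == 0) stop("empty random corpus")
  hits <- cpp_hamming_scan(random_corpus, normalize_rna(seed), as.integer(radius))
  x <- sum(lengths(hits) > 0)
  clamp_probability(x / n, n)
}

clamp_probability <- function(p, n) pmin(pmax(p, 1 / (2 * n)), 1 - 1 / (2 * n))

#' Binomial enrichment test for a seed family
#'
#' One-sided exact binomial upper tail \eqn{P(X \ge x \mid n, p_0)} for the
#' number of peaks containing the seed or a relative. A seed is flagged
#' significant when the p-value is at most \code{p_cutoff} and the family
#' covers at least \code{min_coverage} of the peaks.
#'
#' @param peaks character vector of peak sequences.
#' @param seed 6-mer seed.
#' @param radius mismatch radius (default 2).
#' @param p0 null occurrence probability (from [null_probability()]).
#' @param p_cutoff significance cutoff (default 0.01).
#' @param min_coverage coverage requirement (default 0.70).
#' @return list with \code{root}, \code{x}, \code{n}, \code{coverage},
#'   \code{p0}, \code{pvalue}, \code{significant}; class \code{kmer_seed}.
#' @export
seed_enrichment <- function(peaks, seed, radius = 2, p0,
                            p_cutoff = 0.01, min_coverage = 0.70) {
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie strictly inside (0, 1)")
  n <- length(peaks)
  hits <- cpp_hamming_scan(peaks, normalize_rna(seed), as.integer(radius))
  x <- sum(lengths(hits) > 0)
  pval <- pbinom(x - 1, n, p0, lower.tail = FALSE)
  structure(list(root = seed, x = x, n = n, coverage = x / n, p0 = p0,
                 pvalue = pval,
                 significant = (pval <= p_cutoff) && (x / n >= min_coverage)),
            class = "kmer_seed")
}

# aligned best-hit table for a consensus across peaks: position (0-based,
# NA if no hit within budget) and mismatch count
best_hits <- function(peaks, consensus, budget) {
  m <- cpp_hamming_best(peaks, consensus, as.integer(budget))
  data.frame(pos = ifelse(m[, 1] < 0, NA_integer_, m[, 1]), mismatches = m[, 2])
}

pwm_from_hits <- function(peaks, hits, len) {
  ok <- which(!is.na(hits$pos))
  pwm <- matrix(0L, 4, len, dimnames = list(c("A", "C", "G", "U"), NULL))
  for (i in ok) {
    win <- strsplit(substr(peaks[i], hits$pos[i] + 1, hits$pos[i] + len), "")[[1]]
    for (j in seq_len(len))
      if (win[j] %in% rownames(pwm)) pwm[win[j], j] <- pwm[win[j], j] + 1L
  }
  pwm
}

new_prime_motif <- function(consensus, pwm, coverage, matched, kind, pvalue) {
  structure(list(consensus = consensus, pwm = pwm, coverage = coverage,
                 matched_peak_ids = matched, kind = kind, pvalue = pvalue,
                 score = c(coverage = coverage, length = nchar(consensus),
                           neglogp = -log10(max(pvalue, .Machine$double.xmin)))),
            class = "prime_motif")
}

#' @export
print.prime_motif <- function(x, ...) {
  cat(sprintf("<prime_motif> %s (%d nt, %s)\n  coverage %.1f%% of peaks, enrichment p = %.3g\n",
              x$consensus, nchar(x$consensus), x$kind,
              100 * x$coverage, x$pvalue))
  invisible(x)
}

#' Expand a significant seed into a prime motif
#'
#' Bidirectional one-nucleotide expansion. Each round tries the left then the
#' right side independently: the majority base of the aligned flanking column
#' (ties broken A < C < G < U) is appended, the extended consensus is
#' re-searched across all peaks under the length-dependent mismatch budget
#' (\code{floor(0.3 k)}; 2 at the 6-mer seed stage), and the extension is
#' kept only while the flanking column agrees with its majority base in at
#' least \code{min_identity} of the matched instances and post-extension
#' coverage stays at or above \code{min_coverage}. Expansion stops at 10 nt
#' or when both sides fail.
#'
#' @param seed 6-mer seed (should be significant; see [seed_enrichment()]).
#' @param peaks character vector of peak sequences.
#' @param min_coverage minimum fraction of all peaks matched (default 0.70).
#' @param min_identity minimum majority-base agreement of an appended column
#'   (default 0.70).
#' @param max_len maximum motif length (default 10).
#' @param max_loss maximum tolerated fraction of matched instances lost per
#'   extension (default 1 = no constraint; the mutually-exclusive search uses
#'   0.10).
#' @param pvalue enrichment p-value to record on the motif.
#' @param kind \code{"primary"} or \code{"mutually_exclusive"}.
#' @return a \code{prime_motif} object.
#' @export
expand_seed <- function(seed, peaks, min_coverage = 0.70, min_identity = 0.70,
                        max_len = 10, max_loss = 1, pvalue = NA_real_,
                        kind = "primary") {
  consensus <- normalize_rna(seed)
  n <- length(peaks)
  hits <- best_hits(peaks, consensus, mismatch_budget(nchar(consensus)))
  if (!any(!is.na(hits$pos))) stop("seed not found in any peak")

  # refine the consensus to the PWM column majority of its matched
  # instances; accepted only while coverage does not drop (mismatched seed
  # positions self-correct toward the consensus the instances support)
  refine <- function(consensus, hits) {
    seen <- consensus
    repeat {
      pwm <- pwm_from_hits(peaks, hits, nchar(consensus))
      cand <- paste(rownames(pwm)[apply(pwm, 2, which.max)], collapse = "")
      if (cand == consensus || cand %in% seen) break
      cand_hits <- best_hits(peaks, cand, mismatch_budget(nchar(cand)))
      if (sum(!is.na(cand_hits$pos)) < 0.98 * sum(!is.na(hits$pos))) break
      consensus <- cand; hits <- cand_hits; seen <- c(seen, cand)
    }
    list(consensus = consensus, hits = hits)
  }
  r <- refine(consensus, hits); consensus <- r$consensus; hits <- r$hits

  repeat {
    k <- nchar(consensus)
    if (k >= max_len) break
    improved <- FALSE
    for (side in c("left", "right")) {
      if (nchar(consensus) >= max_len) break
      matched <- which(!is.na(hits$pos))
      # aligned flanking column on this side, where the peak has one
      if (side == "left") {
        has <- matched[hits$pos[matched] >= 1]
        col <- substr(peaks[has], hits$pos[has], hits$pos[has])
      } else {
        endp <- hits$pos[matched] + nchar(consensus)
        has <- matched[endp < nchar(peaks[matched])]
        col <- substr(peaks[has], hits$pos[has] + nchar(consensus) + 1,
                      hits$pos[has] + nchar(consensus) + 1)
      }
      col <- col[col %in% c("A", "C", "G", "U")]
      if (length(col) == 0) next
      tab <- table(factor(col, levels = c("A", "C", "G", "U")))
      maj <- names(tab)[which.max(tab)]        # which.max keeps A<C<G<U ties
      if (max(tab) / length(matched) < min_identity) next
      cand <- if (side == "left") paste0(maj, consensus) else paste0(consensus, maj)
      cand_hits <- best_hits(peaks, cand, mismatch_budget(nchar(cand)))
      cov <- sum(!is.na(cand_hits$pos)) / n
      if (cov < min_coverage) next
      if (sum(!is.na(cand_hits$pos)) < (1 - max_loss) * length(matched)) next
      consensus <- cand
      hits <- cand_hits
      improved <- TRUE
    }
    if (improved) {
      r <- refine(consensus, hits); consensus <- r$consensus; hits <- r$hits
    } else break
  }

  matched <- which(!is.na(hits$pos))
  new_prime_motif(consensus, pwm_from_hits(peaks, hits, nchar(consensus)),
                  length(matched) / n, matched, kind, pvalue)
}

#' Select the prime motif among expanded candidates
#'
#' Ranks lexicographically by (coverage, length, enrichment \eqn{-\log p}),
#' breaking full ties by alphabetical consensus.
#'
#' @param expanded list of \code{prime_motif} objects.
#' @return the best-ranked motif.
#' @export
select_prime <- function(expanded) {
  if (length(expanded) == 0) stop("no candidate motifs")
  ord <- order(-vapply(expanded, function(m) m$score["coverage"], 0),
               -vapply(expanded, function(m) m$score["length"], 0),
               -vapply(expanded, function(m) m$score["neglogp"], 0),
               vapply(expanded, function(m) m$consensus, ""))
  expanded[[ord[1]]]
}

#' Recursively find mutually exclusive motifs in residual peaks
#'
#' Repeats the seed-enrichment/expansion cycle on the peaks not matched by
#' any accepted motif. A residual seed is pursued only while it covers at
#' least \code{min_fraction} of the *original* peak count; expansion steps
#' that would lose 10\% or more of the matched instances are skipped.
#'
#' @param peaks all peak sequences.
#' @param covered_ids indices of peaks matched by already-accepted motifs.
#' @param p0 named vector of null probabilities for all seeds (lexicographic
#'   seed order, as from [null_probability()] applied per seed or a batch
#'   scan of the null corpus).
#' @param min_fraction minimum representation vs the original peak count
#'   (default 0.20).
#' @param p_cutoff binomial significance cutoff (default 0.01).
#' @param max_rounds safety bound on recursion depth (default 5).
#' @return list of \code{prime_motif} objects tagged
#'   \code{mutually_exclusive} (possibly empty).
#' @export
find_exclusive_motifs <- function(peaks, covered_ids, p0,
                                  min_fraction = 0.20, p_cutoff = 0.01,
                                  max_rounds = 5) {
  n_orig <- length(peaks)
  residual <- setdiff(seq_len(n_orig), covered_ids)
  out <- list()
  for (round in seq_len(max_rounds)) {
    if (length(residual) < min_fraction * n_orig) break
    counts <- scan_seed_counts(peaks[residual])
    pvals <- pbinom(counts - 1, length(residual), p0, lower.tail = FALSE)
    logp <- pbinom(counts - 1, length(residual), p0, lower.tail = FALSE,
                   log.p = TRUE)
    frac_orig <- counts / n_orig
    ok <- which(pvals <= p_cutoff & frac_orig >= min_fraction)
    if (length(ok) == 0) break
    best <- ok[order(logp[ok], -counts[ok])][1]
    motif <- expand_seed(names(counts)[best], peaks[residual],
                         min_coverage = min_fraction * n_orig / length(residual),
                         max_loss = 0.10, pvalue = pvals[best],
                         kind = "mutually_exclusive")
    # re-anchor matched ids onto the original peak indexing
    motif$matched_peak_ids <- residual[motif$matched_peak_ids]
    motif$coverage <- length(motif$matched_peak_ids) / n_orig
    if (length(motif$matched_peak_ids) < min_fraction * n_orig) break
    out[[length(out) + 1]] <- motif
    residual <- setdiff(residual, motif$matched_peak_ids)
  }
  out
}

# best-offset ungapped identity between two consensus strings:
# max over relative shifts of matches / min(length)
consensus_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  la <- length(ca); lb <- length(cb)
  best <- 0
  for (shift in -(lb - 1):(la - 1)) {
    ia <- max(0, shift); ib <- max(0, -shift)
    ov <- min(la - ia, lb - ib)
    if (ov < 1) next
    m <- sum(ca[ia + seq_len(ov)] == cb[ib + seq_len(ov)])
    best <- max(best, m / min(la, lb))
  }
  best
}

#' Cluster prime motifs by consensus similarity
#'
#' Single-linkage clustering on best-offset ungapped identity between
#' consensus strings: two motifs join a cluster when they share at least
#' \code{min_similarity} identity with some member.
#'
#' @param motifs list of \code{prime_motif} objects (or consensus strings).
#' @param min_similarity linkage threshold (default 0.70).
#' @return integer vector of cluster labels, one per motif.
#' @export
cluster_motifs <- function(motifs, min_similarity = 0.70) {
  cons <- vapply(motifs, function(m)
    if (inherits(m, "prime_motif")) m$consensus else as.character(m), "")
  n <- length(cons)
  if (n == 0) stop("no motifs to cluster")
  # union-find over the >= min_similarity graph
  parent <- seq_len(n)
  find2 <- function(p, i) { while (p[i] != i) i <- p[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (consensus_identity(cons[i], cons[j]) >= min_similarity) {
      ri <- find2(parent, i); rj <- find2(parent, j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), function(i) find2(parent, i), 0L)
  match(roots, unique(roots))
}

#' Discover the prime motif and companions in a peak set
#'
#' Runs the full discovery cycle: scan all 4,096 6-mer seed families through
#' the FM-index with two mismatches, estimate per-seed null probabilities
#' from a length-matched random corpus, flag enriched seeds (binomial
#' p <= \code{p_cutoff} and coverage >= \code{min_coverage}), expand the top
#' candidates bidirectionally, pick the prime motif, and recurse on the
#' residual for mutually exclusive motifs. Other significant (but sub-prime)
#' expanded families are retained as candidates for co-occurrence analysis.
#'
#' @param peaks character vector of peak sequences (already length-filtered).
#' @param null_corpus character vector of length-matched random sequences
#'   (see [null_corpus()]).
#' @param min_coverage prime-motif coverage requirement (default 0.70).
#' @param p_cutoff binomial cutoff (default 0.01).
#' @param min_fraction mutually-exclusive representation floor (default 0.20).
#' @param max_expand number of top seeds expanded per stage (default 5).
#' @param n_candidates number of sub-prime candidate motifs kept for
#'   co-occurrence analysis (default 5).
#' @return object of class \code{rbp_motifs}: list with \code{prime},
#'   \code{exclusive}, \code{candidates}, and the full \code{seed_table}.
#' @export
discover_motifs <- function(peaks, null_corpus,
                            min_coverage = 0.70, p_cutoff = 0.01,
                            min_fraction = 0.20, max_expand = 5,
                            n_candidates = 5) {
  n <- length(peaks)
  counts <- scan_seed_counts(peaks)
  null_counts <- scan_seed_counts(null_corpus)
  p0 <- clamp_probability(null_counts / length(null_corpus), length(null_corpus))
  pvals <- pbinom(counts - 1, n, p0, lower.tail = FALSE)
  # log-scale tail for ranking: the raw p-value underflows for strong seeds
  logp <- pbinom(counts - 1, n, p0, lower.tail = FALSE, log.p = TRUE)
  coverage <- counts / n
  seed_table <- data.frame(seed = names(counts), x = as.integer(counts), n = n,
                           coverage = coverage, p0 = p0, pvalue = pvals,
                           log_pvalue = logp,
                           significant = pvals <= p_cutoff & coverage >= min_coverage,
                           row.names = NULL)

  prime <- NULL
  covered <- integer(0)
  cand_idx <- which(seed_table$significant)
  if (length(cand_idx) > 0) {
    top <- cand_idx[order(logp[cand_idx], -coverage[cand_idx])]
    top <- head(top, max_expand)
    expanded <- lapply(top, function(i)
      expand_seed(seed_table$seed[i], peaks, min_coverage = min_coverage,
                  pvalue = pvals[i], kind = "primary"))
    # the prime motif grows out of the most enriched seed families: restrict
    # the coverage/length ranking to expansions of seeds whose enrichment is
    # within an order of magnitude of the best
    best_lp <- min(logp[top])
    contenders <- expanded[logp[top] <= best_lp + log(10)]
    prime <- select_prime(contenders)
    covered <- prime$matched_peak_ids
  }

  exclusive <- find_exclusive_motifs(peaks, covered, p0,
                                     min_fraction = min_fraction,
                                     p_cutoff = p_cutoff)

  # sub-prime significant families: co-occurrence candidate pool
  candidates <- list()
  sig_any <- which(pvals <= p_cutoff)
  if (length(sig_any) > 0) {
    pool <- sig_any[order(logp[sig_any], -coverage[sig_any])]
    taken <- character(0)
    if (!is.null(prime)) taken <- prime$consensus
    for (i in pool) {
      if (length(candidates) >= n_candidates) break
      sd <- seed_table$seed[i]
      if (any(vapply(taken, function(t) consensus_identity(sd, t) >= 0.7, TRUE)))
        next
      cand <- tryCatch(
        expand_seed(sd, peaks, min_coverage = min(coverage[i], min_coverage),
                    pvalue = pvals[i], kind = "primary"),
        error = function(e) NULL)
      if (is.null(cand)) next
      cand$kind <- "candidate"
      candidates[[length(candidates) + 1]] <- cand
      taken <- c(taken, cand$consensus)
    }
  }

  structure(list(prime = prime, exclusive = exclusive,
                 candidates = candidates, seed_table = seed_table),
            class = "rbp_motifs")
}

#' @export
print.rbp_motifs <- function(x, ...) {
  cat("<rbp_motifs>\n")
  if (!is.null(x$prime)) {
    cat("  prime: "); print(x$prime)
  } else cat("  prime: none (no seed reached the coverage threshold)\n")
  if (length(x$exclusive))
    for (m in x$exclusive) { cat("  exclusive: "); print(m) }
  cat("  ", sum(x$seed_table$pvalue <= 0.01), "of", nrow(x$seed_table),
      "seeds enriched at p <= 0.01\n")
  invisible(x)
}

#' Write a motif report as TSV
#'
#' @param motifs an \code{rbp_motifs} object or list of \code{prime_motif}s.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_motif_tsv <- function(motifs, path) {
  ml <- if (inherits(motifs, "rbp_motifs"))
    c(if (!is.null(motifs$prime)) list(motifs$prime), motifs$exclusive)
  else motifs
  df <- do.call(rbind, lapply(ml, function(m)
    data.frame(consensus = m$consensus, length = nchar(m$consensus),
               coverage = m$coverage, pvalue = m$pvalue, kind = m$kind,
               matched_peaks = length(m$matched_peak_ids))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write motif PWMs in MEME minimal motif format
#'
#' @param motifs list of \code{prime_motif} objects (or \code{rbp_motifs}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_meme <- function(motifs, path) {
  ml <- if (inherits(motifs, "rbp_motifs"))
    c(if (!is.null(motifs$prime)) list(motifs$prime), motifs$exclusive)
  else motifs
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGU", "",
               "strands: +", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 U 0.25", ""), con)
  for (m in ml) {
    freq <- t(m$pwm) / pmax(colSums(m$pwm), 1)
    writeLines(sprintf("MOTIF %s", m$consensus), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d",
                       nchar(m$consensus), length(m$matched_peak_ids)), con)
    apply(freq, 1, function(r)
      writeLines(sprintf(" %.6f %.6f %.6f %.6f", r[1], r[2], r[3], r[4]), con))
    writeLines("", con)
  }
  invisible(path)
}
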
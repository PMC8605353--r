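#' Configuration for the synthetic CLIP-seq-like generator
#'
#' Defines the statistical structure the method assumes: a planted consensus
#' motif covering a controlled fraction of peaks with per-base substitution
#' noise, CG-enriched flanks around bound sites, and an optional secondary
#' motif co-occurring at a preferred offset. Every generator is a pure
#' function of (config, seed).
#'
#' @param n_peaks number of peaks (default 500).
#' @param peak_length integer range of peak lengths (default 20-50, the
#'   width range typical of eCLIP/PAR-CLIP peak calls, within the 5-300
#'   filter).
#' @param background_freq base composition of the background (default
#'   uniform).
#' @param motif planted consensus, 6-10 nt (default \code{"UGCAUGCC"}).
#' @param coverage fraction of peaks carrying the motif (default 0.8).
#' @param substitution_rate per-base substitution probability at planted
#'   sites (default 0.1).
#' @param cg_bias CG-dinucleotide enrichment factor in the flanks of bound
#'   sites (default 2; 1 disables the bias).
#' @param partner_motif optional co-occurring secondary motif (default
#'   \code{"GAAGGAAG"}; NULL disables it).
#' @param partner_offset mean signed offset of the partner start relative to
#'   the prime-motif start (default -30).
#' @param partner_jitter uniform jitter around the offset (default 2).
#' @param partner_carriage fraction of motif-bearing peaks carrying the
#'   partner (default 0.6).
#' @param background_carriage partner carriage in background/negative
#'   flanks (default 0.05).
#' @param n_background number of background transcripts (default
#'   \code{n_peaks}).
#' @param flank_pad transcript padding on each side of a peak, so that
#'   75-base flanks always have sequence to draw on (default 150).
#' @param setB_distance distance between a Set-B distal motif and the peak
#'   (default 500).
#' @param rng_seed integer seed (default 1).
#' @return validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_peaks = 500, peak_length = c(20, 50),
                       background_freq = c(A = 0.25, C = 0.25,
                                           G = 0.25, U = 0.25),
                       motif = "UGCAUGCC", coverage = 0.8,
                       substitution_rate = 0.1, cg_bias = 2,
                       partner_motif = "GAAGGAAG", partner_offset = -30,
                       partner_jitter = 2, partner_carriage = 0.6,
                       background_carriage = 0.05,
                       n_background = n_peaks, flank_pad = 150,
                       setB_distance = 500, rng_seed = 1) {
  motif <- normalize_rna(motif)
  stopifnot(nchar(motif) >= 6, nchar(motif) <= 10,
            coverage >= 0, coverage <= 1,
            substitution_rate >= 0, substitution_rate <= 1,
            partner_carriage >= 0, partner_carriage <= 1,
            background_carriage >= 0, background_carriage <= 1,
            length(peak_length) == 2, peak_length[1] <= peak_length[2])
  if (peak_length[1] < nchar(motif))
    stop("motif longer than the minimum peak length")
  if (!is.null(partner_motif)) partner_motif <- normalize_rna(partner_motif)
  structure(list(n_peaks = as.integer(n_peaks),
                 peak_length = as.integer(peak_length),
                 background_freq = background_freq / sum(background_freq),
                 motif = motif, coverage = coverage,
                 substitution_rate = substitution_rate, cg_bias = cg_bias,
                 partner_motif = partner_motif,
                 partner_offset = partner_offset,
                 partner_jitter = as.integer(partner_jitter),
                 partner_carriage = partner_carriage,
                 background_carriage = background_carriage,
                 n_background = as.integer(n_background),
                 flank_pad = as.integer(flank_pad),
                 setB_distance = as.integer(setB_distance),
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

random_rna <- function(n, len, freq) {
  vapply(rep(len, length.out = n), function(L)
    paste(sample(names(freq), L, replace = TRUE, prob = freq), collapse = ""),
    "")
}

mutate_motif <- function(motif, rate) {
  chars <- strsplit(motif, "")[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    for (i in which(hit))
      chars[i] <- sample(setdiff(c("A", "C", "G", "U"), chars[i]), 1)
  }
  list(seq = paste(chars, collapse = ""), mismatches = sum(hit))
}

cg_density <- function(seq) {
  L <- nchar(seq)
  if (L < 2) return(0)
  hits <- gregexpr("(?=CG)", seq, perl = TRUE)[[1]]
  (if (hits[1] == -1) 0 else length(hits)) / (L - 1)
}

# rejection-sample a flank whose CG dinucleotide density reaches the target
# (background density x bias factor), tolerance 0.025, capped tries
biased_flank <- function(len, freq, bias) {
  if (bias == 1 || len < 2) return(random_rna(1, len, freq))
  base_cg <- freq["C"] * freq["G"]
  target <- min(bias * base_cg, 0.5)
  best <- NULL; best_d <- Inf
  for (try in 1:200) {
    cand <- random_rna(1, len, freq)
    d <- cg_density(cand)
    if (abs(d - target) <= 0.025) return(cand)
    if (abs(d - target) < best_d) { best <- cand; best_d <- abs(d - target) }
  }
  best
}

plant <- function(seq, sub, at) {              # 0-based insertion
  paste0(substr(seq, 1, at), sub, substr(seq, at + nchar(sub) + 1, nchar(seq)))
}

#' Simulate a peak set with a planted prime motif
#'
#' Each peak lives on its own synthetic transcript (peak interval in the
#' middle, \code{flank_pad} background on both sides). Exactly
#' \code{round(coverage * n_peaks)} peaks carry the noised motif; those
#' flanks receive the CG bias, and a configured fraction also carry the
#' partner motif at its preferred offset. The truth table records every
#' planted position (0-based on the transcript), mismatch count and partner
#' placement.
#'
#' @param config a [sim_config()].
#' @return list with \code{genome} (named transcripts), \code{peaks}
#'   (interval data.frame), \code{peak_seqs}, and \code{truth}.
#' @export
simulate_peakset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$rng_seed, {
    n <- config$n_peaks
    k <- nchar(config$motif)
    pad <- config$flank_pad
    lens <- sample(seq(config$peak_length[1], config$peak_length[2]),
                   n, replace = TRUE)
    carriers <- sort(sample(n, round(config$coverage * n)))
    has_partner <- rep(FALSE, n)
    if (!is.null(config$partner_motif) && length(carriers) > 0) {
      np <- round(config$partner_carriage * length(carriers))
      if (np > 0) has_partner[sample(carriers, np)] <- TRUE
    }
    genome <- character(n)
    truth <- data.frame(peak = seq_len(n), has_motif = FALSE,
                        motif_start = NA_integer_, mismatches = NA_integer_,
                        partner = has_partner, partner_start = NA_integer_)
    for (i in seq_len(n)) {
      tl <- lens[i] + 2 * pad
      tx <- random_rna(1, tl, config$background_freq)
      if (i %in% carriers) {
        mpos <- pad + sample.int(lens[i] - k + 1, 1) - 1   # 0-based
        mut <- mutate_motif(config$motif, config$substitution_rate)
        # the CG enrichment is contextual: it flanks the bound footprint,
        # outside the peak interval itself
        if (config$cg_bias != 1) {
          lf <- biased_flank(75, config$background_freq, config$cg_bias)
          rf <- biased_flank(75, config$background_freq, config$cg_bias)
          tx <- plant(tx, lf, pad - 75)
          tx <- plant(tx, rf, pad + lens[i])
        }
        tx <- plant(tx, mut$seq, mpos)
        truth$has_motif[i] <- TRUE
        truth$motif_start[i] <- mpos
        truth$mismatches[i] <- mut$mismatches
        if (has_partner[i]) {
          off <- config$partner_offset +
            sample(seq(-config$partner_jitter, config$partner_jitter), 1)
          ppos <- mpos + off
          if (ppos >= 0 && ppos + nchar(config$partner_motif) <= tl) {
            tx <- plant(tx, config$partner_motif, ppos)
            truth$partner_start[i] <- ppos
          } else truth$partner[i] <- FALSE
        }
      }
      genome[i] <- tx
    }
    names(genome) <- sprintf("tx%04d", seq_len(n))
    peaks <- structure(
      data.frame(chrom = names(genome), start = pad, end = pad + lens,
                 strand = "+", stringsAsFactors = FALSE),
      class = c("peak_intervals", "data.frame"))
    list(genome = genome, peaks = peaks,
         peak_seqs = stats::setNames(substr(genome, pad + 1, pad + lens),
                                     names(genome)),
         truth = truth)
  })
}

#' Simulate background transcripts for negative-set construction
#'
#' Set-A pool: motif-bearing transcripts flagged unbound (flanks unbiased,
#' partner planted at the background carriage rate). Set-B pool: transcripts
#' with one bound "peak" region plus at least one distal motif occurrence at
#' a recorded distance of \code{setB_distance} or more.
#'
#' @param config a [sim_config()].
#' @param type \code{"setA"} or \code{"setB"}.
#' @param n number of transcripts (default \code{config$n_background}).
#' @param seed_offset added to the config seed so peak and background draws
#'   are independent (default 1).
#' @return list with \code{transcripts} and \code{truth} (and for Set B the
#'   \code{peaks} intervals on those transcripts).
#' @export
simulate_background <- function(config, type = c("setA", "setB"),
                                n = config$n_background, seed_offset = 1) {
  stopifnot(inherits(config, "sim_config"))
  type <- match.arg(type)
  k <- nchar(config$motif)
  pad <- config$flank_pad
  with_seed(config$rng_seed + seed_offset, {
    if (type == "setA") {
      tl <- 2 * pad + k
      tx <- character(n)
      truth <- data.frame(transcript = seq_len(n), motif_start = NA_integer_,
                          mismatches = NA_integer_, partner = FALSE)
      for (i in seq_len(n)) {
        s <- random_rna(1, tl, config$background_freq)
        mpos <- pad      # centred; flanks always available
        mut <- mutate_motif(config$motif, config$substitution_rate)
        s <- plant(s, mut$seq, mpos)
        truth$motif_start[i] <- mpos
        truth$mismatches[i] <- mut$mismatches
        if (!is.null(config$partner_motif) &&
            runif(1) < config$background_carriage) {
          off <- sample(setdiff(seq(-75, 75 - nchar(config$partner_motif)),
                                seq(-nchar(config$partner_motif) + 1, k - 1)), 1)
          s <- plant(s, config$partner_motif, mpos + off)
          truth$partner[i] <- TRUE
        }
        tx[i] <- s
      }
      names(tx) <- sprintf("bgA%04d", seq_len(n))
      list(transcripts = tx, truth = truth)
    } else {
      # bound peak region at the start, distal motif far downstream
      d <- config$setB_distance
      tl <- pad + k + d + k + pad
      tx <- character(n)
      truth <- data.frame(transcript = seq_len(n),
                          peak_motif_start = pad,
                          distal_motif_start = pad + k + d,
                          distance = d)
      for (i in seq_len(n)) {
        s <- random_rna(1, tl, config$background_freq)
        s <- plant(s, mutate_motif(config$motif, config$substitution_rate)$seq,
                   pad)
        s <- plant(s, mutate_motif(config$motif, config$substitution_rate)$seq,
                   pad + k + d)
        tx[i] <- s
      }
      names(tx) <- sprintf("bgB%04d", seq_len(n))
      peaks <- data.frame(chrom = names(tx), start = pad - 10,
                          end = pad + k + 10, strand = "+",
                          stringsAsFactors = FALSE)
      list(transcripts = tx, truth = truth, peaks = peaks)
    }
  })
}

#' Random corpus matched to a peak length multiset
#'
#' Length-matched sequences carved from the background model with no planted
#' signal; the null model for seed enrichment.
#'
#' @param lengths integer vector: the peak length multiset to match.
#' @param config a [sim_config()] (for the background composition and seed).
#' @param seed_offset seed offset (default 2).
#' @return character vector of random sequences with exactly those lengths.
#' @export
null_corpus <- function(lengths, config, seed_offset = 2) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$rng_seed + seed_offset,
            random_rna(length(lengths), lengths, config$background_freq))
}
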
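#' Control parameters for model fitting
#'
#' Collects the tunable parameters of the discovery-to-classifier pipeline
#' with their established defaults: 6-mer seeds with two mismatches, 70%
#' coverage and a 1% binomial cutoff for the prime motif, 20% representation
#' for mutually exclusive motifs, 75-base flanks, and a 70:30 train/test
#' split.
#'
#' @param min_coverage prime-motif coverage requirement (default 0.70).
#' @param p_cutoff binomial significance cutoff (default 0.01).
#' @param min_fraction mutually-exclusive representation floor (default
#'   0.20).
#' @param flank flank width in bases (default 75).
#' @param min_distance Set-B anchor-to-peak separation (default 300 nt).
#' @param train_fraction training fraction (default 0.7; 0.6 is the
#'   feature-evaluation setting).
#' @param window_sizes candidate dinucleotide window sizes; odd values from
#'   the 17-131 grid (default \code{c(17, 43, 71, 91, 131)}).
#' @param classifier \code{"gbt"} (default) or \code{"dnn"}.
#' @param nrounds boosting rounds for the fitted model (default 300).
#' @param dnn_hidden,dnn_epochs feed-forward net size/epochs when
#'   \code{classifier = "dnn"}.
#' @param threshold decision threshold on the classifier score (default
#'   0.5).
#' @param max_expand seeds expanded per discovery stage (default 5).
#' @param n_candidates co-occurrence candidate motifs retained (default 8).
#' @param cooccurrence run the co-occurrence analysis (default TRUE).
#' @param ks_cutoff KS threshold for co-occurring pairs (default 0.05).
#' @return list of class \code{rbp_control}.
#' @export
rbp_control <- function(min_coverage = 0.70, p_cutoff = 0.01,
                        min_fraction = 0.20, flank = 75, min_distance = 300,
                        train_fraction = 0.7,
                        window_sizes = c(17, 43, 71, 91, 131),
                        classifier = c("gbt", "dnn"), nrounds = 300,
                        dnn_hidden = c(128, 128), dnn_epochs = 60,
                        threshold = 0.5, max_expand = 5, n_candidates = 8,
                        cooccurrence = TRUE, ks_cutoff = 0.05) {
  structure(list(min_coverage = min_coverage, p_cutoff = p_cutoff,
                 min_fraction = min_fraction, flank = flank,
                 min_distance = min_distance,
                 train_fraction = train_fraction,
                 window_sizes = window_sizes,
                 classifier = match.arg(classifier), nrounds = nrounds,
                 dnn_hidden = dnn_hidden, dnn_epochs = dnn_epochs,
                 threshold = threshold, max_expand = max_expand,
                 n_candidates = n_candidates, cooccurrence = cooccurrence,
                 ks_cutoff = ks_cutoff),
            class = "rbp_control")
}

#' Fit an RBP binding-site model from peak data
#'
#' Runs the full pipeline: peak filtering, FM-index seed scan and binomial
#' enrichment against a length-matched random corpus, bidirectional seed
#' expansion to the prime motif (plus mutually exclusive motifs on the
#' residual), anchored positive/negative instance construction, contextual
#' featurization (dinucleotide window densities at the validation-selected
#' window size, mismatch-tolerant pentamer and heptamer positional
#' probabilities from the training positives), classifier training, and
#' held-out evaluation. Co-occurring secondary motifs are screened with the
#' KS / hypergeometric / frequency-ratio / PWM-Jaccard criteria.
#'
#' @param peaks peak intervals (a \code{peak_intervals} data.frame, with
#'   \code{genome}) or a character vector of peak-region sequences long
#'   enough to carry the 75-base flanks.
#' @param background named character vector of background transcripts:
#'   the null corpus is carved from them, and with
#'   \code{negative_strategy = "A"} they are the expressed-but-unbound pool.
#' @param genome named character vector (or XStringSet) backing interval
#'   input.
#' @param negatives optional pre-built negative instance data.frame
#'   (columns as from the \code{build_negative_*} builders); overrides the
#'   strategy.
#' @param negative_strategy \code{"A"} (unbound transcripts, default) or
#'   \code{"B"} (distal regions of bound transcripts).
#' @param control an [rbp_control()].
#' @param seed master RNG seed.
#' @return an object of class \code{rbp_model}.
#' @seealso [predict.rbp_model()] to scan new sequences,
#'   [summary.rbp_model()] for the fit report.
#' @export
rbp_fit <- function(peaks, background, genome = NULL, negatives = NULL,
                    negative_strategy = c("A", "B"),
                    control = rbp_control(), seed = 1) {
  negative_strategy <- match.arg(negative_strategy)
  cl <- match.call()

  if (is.data.frame(peaks)) {
    if (is.null(genome)) stop("interval input requires a genome")
    if (inherits(genome, "XStringSet"))
      genome <- stats::setNames(as.character(genome), names(genome))
    genome <- normalize_rna(genome)
    peaks <- filter_peaks(peaks)
    peak_seqs <- extract_sequence(genome, peaks)
  } else {
    peak_seqs <- filter_peaks(normalize_rna(peaks))
    peaks <- NULL
  }
  if (!rbp_eligible(peak_seqs))
    warning("fewer than the recommended >500 unique peaks (",
            length(peak_seqs), "); the model may be unstable")
  background <- normalize_rna(background)

  ## 1. motif discovery against a length-matched random corpus
  null <- carve_null(background, nchar(peak_seqs), seed = seed + 17L)
  motifs <- discover_motifs(peak_seqs, null,
                            min_coverage = control$min_coverage,
                            p_cutoff = control$p_cutoff,
                            min_fraction = control$min_fraction,
                            max_expand = control$max_expand,
                            n_candidates = control$n_candidates)
  prime <- motifs$prime
  if (is.null(prime)) {
    if (length(motifs$exclusive) == 0)
      stop("no motif reached the coverage or representation thresholds")
    prime <- motifs$exclusive[[1]]
  }
  k <- nchar(prime$consensus)

  ## 2. instance construction
  positives <- if (!is.null(peaks))
    build_positive(peaks, genome, prime, flank = control$flank)
  else
    build_positive(peak_seqs, prime_motif = prime, flank = control$flank)
  if (is.null(negatives)) {
    bound_ids <- if (!is.null(peaks)) unique(peaks$chrom) else character(0)
    negatives <- if (negative_strategy == "A")
      build_negative_setA(background, prime, flank = control$flank,
                          bound_ids = bound_ids)
    else
      build_negative_setB(genome, peaks, prime, flank = control$flank,
                          min_distance = control$min_distance)
  }
  iset <- balance_and_split(positives, negatives, motif_length = k,
                            train_fraction = control$train_fraction,
                            rng_seed = seed, flank = control$flank)
  inst <- iset$instances
  tr <- inst$split == "train"

  ## 3. features: window selection and schema from the training split only
  window <- select_dinucleotide_window(inst$sequence[tr], inst$label[tr],
                                       control$window_sizes, seed = seed)
  schema <- build_feature_schema(inst$sequence[tr & inst$label == 1],
                                 inst$sequence[tr], dinuc_window = window)
  x_train <- assemble_features(inst$sequence[tr], schema)
  x_test <- assemble_features(inst$sequence[!tr], schema)

  ## 4. classifier and held-out evaluation
  classifier <- if (control$classifier == "gbt")
    train_gbt(x_train, inst$label[tr], nrounds = control$nrounds, seed = seed)
  else
    train_dnn(x_train, inst$label[tr], hidden = control$dnn_hidden,
              epochs = control$dnn_epochs, seed = seed)
  eval <- evaluate_model(classifier, x_test, inst$label[!tr],
                         threshold = control$threshold)
  fstats <- fscore_rank(x_train, inst$label[tr])

  ## 5. co-occurring secondary motifs: candidates come from scanning the
  ## positive instance set (flanks included) for other frequent k-mer
  ## families, plus any mutually exclusive motifs
  cooccurrence <- NULL
  if (control$cooccurrence) {
    pos_seqs <- inst$sequence[inst$label == 1]
    # composition-matched shuffle null: the universe for the
    # frequency-ratio/hypergeometric counts and the positional KS null
    bg_seqs <- shuffle_sequences(pos_seqs, seed = seed + 23L)
    cand <- c(cooccurrence_candidates(pos_seqs, bg_seqs, prime,
                                      n_candidates = control$n_candidates),
              if (!is.null(motifs$prime)) motifs$exclusive else list())
    if (length(cand) > 0)
      cooccurrence <- find_cooccurring(pos_seqs, bg_seqs, prime, cand,
                                       flank = control$flank,
                                       ks_cutoff = control$ks_cutoff)
  }

  structure(list(prime_motif = prime, motifs = motifs,
                 instance_set = iset, window = window, schema = schema,
                 classifier = classifier, metrics = eval$metrics,
                 confusion = eval$confusion,
                 feature_stats = head(fstats, 100),
                 cooccurrence = cooccurrence, control = control,
                 seed = seed, call = cl),
            class = "rbp_model")
}

# carve random length-matched segments out of background transcripts
carve_null <- function(background, lengths, seed = NULL) {
  with_seed(seed, {
    bl <- nchar(background)
    vapply(lengths, function(L) {
      ok <- which(bl >= L)
      if (length(ok) == 0)
        return(paste(sample(c("A", "C", "G", "U"), L, TRUE), collapse = ""))
      tx <- ok[sample.int(length(ok), 1)]
      s <- sample.int(bl[tx] - L + 1, 1)
      substr(background[[tx]], s, s + L - 1)
    }, "")
  })
}

#' @export
print.rbp_model <- function(x, ...) {
  cat("RBP binding-site model\n")
  cat("  prime motif: ", x$prime_motif$consensus,
      sprintf(" (%d nt, %.1f%% coverage, %s)\n", nchar(x$prime_motif$consensus),
              100 * x$prime_motif$coverage, x$prime_motif$kind))
  cat("  classifier:  ", x$classifier$kind,
      " on ", length(x$schema$feature_names), " features (dinucleotide window ",
      x$window, ")\n", sep = "")
  m <- x$metrics
  cat(sprintf("  held-out:    Acc %.3f | F1 %.3f | MCC %.3f | AUC %.3f\n",
              m["Acc"], m["F1"], m["MCC"], m["AUC"]))
  invisible(x)
}

#' Summarize a fitted RBP binding-site model
#'
#' @param object an \code{rbp_model}.
#' @param ... unused.
#' @return the model, invisibly; prints motif, dataset, feature and
#'   performance sections plus significant co-occurring pairs.
#' @export
summary.rbp_model <- function(object, ...) {
  print(object)
  iset <- object$instance_set
  cat(sprintf("\nInstances: %d of length %d (motif %d + 2 x %d flanks); train fraction %.2f\n",
              nrow(iset$instances), iset$instance_length, iset$motif_length,
              iset$flank, iset$train_fraction))
  if (length(object$motifs$exclusive))
    cat("Mutually exclusive motifs:",
        paste(vapply(object$motifs$exclusive, `[[`, "", "consensus"),
              collapse = ", "), "\n")
  cat("\nTop contextual features by F-score:\n")
  print(head(object$feature_stats[, c("feature", "F", "t_pvalue")], 5),
        row.names = FALSE)
  if (!is.null(object$cooccurrence)) {
    sig <- object$cooccurrence[object$cooccurrence$significant, , drop = FALSE]
    cat("\nCo-occurring motifs:", nrow(sig), "significant of",
        nrow(object$cooccurrence), "evaluated\n")
    if (nrow(sig))
      print(sig[, c("partner", "FR", "ks_pvalue", "hyper_pvalue", "jaccard")],
            row.names = FALSE)
  }
  invisible(object)
}

#' Plot a fitted model: motif profile and partner offsets
#'
#' Left panel: per-position base frequencies of the prime-motif PWM. Right
#' panel (when co-occurrence was run and a partner has offsets): histogram
#' of partner offsets relative to the anchor.
#'
#' @param x an \code{rbp_model}; @param ... passed to \code{barplot}.
#' @return \code{x}, invisibly.
#' @export
plot.rbp_model <- function(x, ...) {
  offs <- attr(x$cooccurrence, "offsets")
  has_offs <- !is.null(offs) && any(lengths(offs) > 0)
  old <- graphics::par(mfrow = c(1, if (has_offs) 2 else 1))
  on.exit(graphics::par(old))
  freq <- sweep(x$prime_motif$pwm, 2, pmax(colSums(x$prime_motif$pwm), 1), "/")
  graphics::barplot(freq, names.arg = strsplit(x$prime_motif$consensus, "")[[1]],
                    col = c("#66c2a5", "#fc8d62", "#8da0cb", "#e78ac3"),
                    border = NA, main = "Prime motif base frequencies",
                    xlab = "consensus position", ylab = "frequency", ...)
  graphics::legend("topright", legend = rownames(freq), bty = "n",
                   fill = c("#66c2a5", "#fc8d62", "#8da0cb", "#e78ac3"))
  if (has_offs) {
    best <- names(offs)[which.max(lengths(offs))]
    graphics::hist(offs[[best]], breaks = 30,
                   main = paste("Partner offsets:", best),
                   xlab = "offset from anchor start (nt)", col = "grey70",
                   border = "white")
  }
  invisible(x)
}

#' Simulate peak sets from a fitted model's motif
#'
#' Generates synthetic CLIP-seq-like peak sets carrying the model's prime
#' motif, for power checks and end-to-end testing.
#'
#' @param object an \code{rbp_model}.
#' @param nsim number of peak sets (default 1).
#' @param seed RNG seed for the first set (subsequent sets increment it).
#' @param ... passed to [sim_config()] (e.g. \code{n_peaks},
#'   \code{coverage}).
#' @return a list of [simulate_peakset()] results (length \code{nsim}).
#' @export
simulate.rbp_model <- function(object, nsim = 1, seed = 1, ...) {
  lapply(seq_len(nsim), function(i) {
    cfg <- sim_config(motif = object$prime_motif$consensus,
                      rng_seed = seed + i - 1, ...)
    simulate_peakset(cfg)
  })
}
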
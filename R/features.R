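#' Positional dinucleotide window densities
#'
#' Slides a window of \code{window} bases along each sequence (step 1) and
#' reports, for every placement, the density of each of the 16
#' dinucleotides: count / (window - 1). Densities of an N-free placement
#' sum to 1. Windows touching an N yield NA (imputed to the training column
#' mean during assembly).
#'
#' @param seqs character vector of equal-length RNA sequences.
#' @param window odd window size (candidate grid 17, 19, ..., 131).
#' @return numeric matrix, one row per sequence; per placement a block of 16
#'   columns named \code{w<window>.p<placement>.<dinucleotide>}.
#' @export
dinucleotide_densities <- function(seqs, window) {
  seqs <- normalize_rna(seqs)
  L <- nchar(seqs[1])
  if (window > L) stop("window larger than the sequences")
  out <- cpp_dinuc_densities(seqs, as.integer(window))
  di <- as.vector(t(outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"),
                          paste0)))
  npl <- L - window + 1
  colnames(out) <- paste0("w", window, ".p", rep(seq_len(npl), each = 16),
                          ".", rep(di, npl))
  out
}

#' Mismatch-tolerant positional k-mer probability tensor
#'
#' From the training positives only: cell \code{[m, p]} is the fraction of
#' training sequences whose k-mer starting at position p lies within the
#' mismatch budget of k-mer m. 1,024 rows for pentamers, 16,384 for
#' heptamers; one column per start position (sequence length - k + 1).
#'
#' @param training_positives equal-length training positive sequences.
#' @param k 5 or 7.
#' @param mismatch_budget Hamming budget (default 2).
#' @return object of class \code{kmer_tensor}: the probability matrix with
#'   \code{k}, \code{mismatch_budget} and \code{source_length} attributes.
#' @export
build_kmer_tensor <- function(training_positives, k, mismatch_budget = 2) {
  training_positives <- normalize_rna(training_positives)
  mat <- cpp_kmer_tensor(training_positives, as.integer(k),
                         as.integer(mismatch_budget))
  structure(mat, k = as.integer(k),
            mismatch_budget = as.integer(mismatch_budget),
            source_length = nchar(training_positives[1]),
            class = c("kmer_tensor", "matrix"))
}

#' @export
print.kmer_tensor <- function(x, ...) {
  cat(sprintf("<kmer_tensor> k=%d (%d rows) x %d positions, budget %d\n",
              attr(x, "k"), nrow(x), ncol(x), attr(x, "mismatch_budget")))
  invisible(x)
}

#' Project sequences through a k-mer tensor
#'
#' One value per position: the tensor cell for the k-mer observed at that
#' position (NA where the window contains an N; imputed downstream).
#'
#' @param tensor a [build_kmer_tensor()] result.
#' @param seqs sequences of the tensor's source length.
#' @return numeric matrix, rows = sequences, cols = positions.
#' @export
project_sequence <- function(tensor, seqs) {
  seqs <- normalize_rna(seqs)
  k <- attr(tensor, "k")
  if (any(nchar(seqs) != attr(tensor, "source_length")))
    stop("sequence length differs from the tensor's source length")
  codes <- cpp_encode_kmers(seqs, k)
  P <- ncol(codes)
  out <- matrix(NA_real_, nrow(codes), P)
  for (p in seq_len(P)) {
    ok <- !is.na(codes[, p])
    out[ok, p] <- tensor[codes[ok, p] + 1L, p]
  }
  colnames(out) <- paste0("k", k, ".p", seq_len(P))
  out
}

#' Structure-triplet densities of a dot-bracket string
#'
#' Densities of the 27 length-3 patterns over the alphabet \code{., (, )}
#' within a window. Implemented for completeness; disabled in final model
#' assembly by default since ab-initio structure features did not add value.
#'
#' @param dotbracket dot-bracket string over \code{., (, )}.
#' @param window window size (default: whole string).
#' @param start 1-based window start (default 1).
#' @return named numeric vector of 27 densities (sum 1 for windows of 3+
#'   characters).
#' @export
structure_triplet_densities <- function(dotbracket, window = nchar(dotbracket),
                                        start = 1) {
  if (grepl("[^.()]", dotbracket)) stop("illegal characters in dot-bracket string")
  sub <- substr(dotbracket, start, start + window - 1)
  if (nchar(sub) < 3) stop("window shorter than a triplet")
  alpha <- c(".", "(", ")")
  pats <- as.vector(outer(outer(alpha, alpha, paste0), alpha, paste0))
  pats <- sort(pats)
  chars <- strsplit(sub, "")[[1]]
  tri <- paste0(chars[-c(length(chars) - 1, length(chars))],
                chars[-c(1, length(chars))],
                chars[-c(1, 2)])
  counts <- table(factor(tri, levels = pats))
  as.numeric(counts) / length(tri) -> dens
  stats::setNames(dens, pats)
}

#' Rank features by F-score, with per-feature t-tests
#'
#' The F-score relates the squared deviations of the class means from the
#' global mean to the pooled within-class sample variances
#' ((n-1)-denominator); a small epsilon regularizes zero-variance features
#' so the schema stays stable. Symmetric under label swap; 0 when both
#' class means equal the global mean.
#'
#' @param matrix numeric feature matrix (rows = instances).
#' @param labels 0/1 vector.
#' @param eps denominator regularizer (default 1e-12).
#' @return data.frame sorted by descending F (stable ties): feature,
#'   F, class means, t-test p-value.
#' @export
fscore_rank <- function(matrix, labels, eps = 1e-12) {
  labels <- as.integer(labels)
  pos <- matrix[labels == 1, , drop = FALSE]
  neg <- matrix[labels == 0, , drop = FALSE]
  if (nrow(pos) < 2 || nrow(neg) < 2)
    stop("each class needs at least 2 instances")
  mp <- colMeans(pos); mn <- colMeans(neg); mall <- colMeans(matrix)
  vp <- apply(pos, 2, stats::var); vn <- apply(neg, 2, stats::var)
  Fv <- ((mp - mall)^2 + (mn - mall)^2) / (vp + vn + eps)
  tp <- vapply(seq_len(ncol(matrix)), function(j) {
    if (stats::sd(pos[, j]) == 0 && stats::sd(neg[, j]) == 0) return(NA_real_)
    t.test(pos[, j], neg[, j])$p.value
  }, 0)
  out <- data.frame(feature = colnames(matrix) %||%
                      paste0("f", seq_len(ncol(matrix))),
                    F = Fv, mean_pos = mp, mean_neg = mn, mean_all = mall,
                    t_pvalue = tp, row.names = NULL)
  out[order(-out$F), , drop = FALSE]
}

impute_col_means <- function(mat, means = NULL) {
  if (is.null(means)) means <- colMeans(mat, na.rm = TRUE)
  means[is.na(means)] <- 0
  for (j in which(colSums(is.na(mat)) > 0))
    mat[is.na(mat[, j]), j] <- means[j]
  list(mat = mat, means = means)
}

#' Assemble the combined contextual feature matrix
#'
#' Deterministic schema: dinucleotide window block (at the chosen window
#' size), pentamer projection, heptamer projection; the structure-triplet
#' block is appended only when enabled and dot-bracket strings are supplied.
#' Tensors must be built from the training split only; NA cells (N windows)
#' are imputed to the training column means carried in the schema.
#'
#' @param seqs instance sequences to featurize.
#' @param schema a \code{feature_schema} from [build_feature_schema()].
#' @return numeric matrix with one row per instance, columns per the schema.
#' @export
assemble_features <- function(seqs, schema) {
  stopifnot(inherits(schema, "feature_schema"))
  blocks <- list()
  if (!is.null(schema$dinuc_window))
    blocks$dinuc <- dinucleotide_densities(seqs, schema$dinuc_window)
  if (!is.null(schema$pent_tensor))
    blocks$pent <- project_sequence(schema$pent_tensor, seqs)
  if (!is.null(schema$hept_tensor))
    blocks$hept <- project_sequence(schema$hept_tensor, seqs)
  mat <- do.call(cbind, blocks)
  if (!identical(colnames(mat), schema$feature_names))
    stop("feature schema mismatch between train and test")
  impute_col_means(mat, schema$column_means)$mat
}

#' Build the feature schema from the training split
#'
#' Computes the pentamer and heptamer tensors and the imputation means from
#' the training positives/instances only, freezing the feature layout that
#' both partitions (and later scans) must share.
#'
#' @param train_positives training positive sequences (tensor source).
#' @param train_all all training sequences (for imputation means).
#' @param dinuc_window chosen dinucleotide window size (NULL disables the
#'   block).
#' @param use_pentamers,use_heptamers enable the projection blocks.
#' @param mismatch_budget tensor budget (default 2).
#' @return object of class \code{feature_schema}.
#' @export
build_feature_schema <- function(train_positives, train_all = train_positives,
                                 dinuc_window = 43, use_pentamers = TRUE,
                                 use_heptamers = TRUE, mismatch_budget = 2) {
  schema <- structure(list(dinuc_window = dinuc_window,
                           pent_tensor = NULL, hept_tensor = NULL,
                           feature_names = NULL, column_means = NULL),
                      class = "feature_schema")
  if (use_pentamers)
    schema$pent_tensor <- build_kmer_tensor(train_positives, 5, mismatch_budget)
  if (use_heptamers)
    schema$hept_tensor <- build_kmer_tensor(train_positives, 7, mismatch_budget)
  blocks <- list()
  if (!is.null(dinuc_window))
    blocks$dinuc <- dinucleotide_densities(train_all, dinuc_window)
  if (use_pentamers) blocks$pent <- project_sequence(schema$pent_tensor, train_all)
  if (use_heptamers) blocks$hept <- project_sequence(schema$hept_tensor, train_all)
  mat <- do.call(cbind, blocks)
  schema$feature_names <- colnames(mat)
  schema$column_means <- impute_col_means(mat)$means
  schema
}

#' @export
print.feature_schema <- function(x, ...) {
  cat(sprintf("<feature_schema> %d features (dinuc window %s%s%s)\n",
              length(x$feature_names),
              x$dinuc_window %||% "off",
              if (!is.null(x$pent_tensor)) " + pentamers" else "",
              if (!is.null(x$hept_tensor)) " + heptamers" else ""))
  invisible(x)
}
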
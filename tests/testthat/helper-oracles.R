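# Independent oracles: deliberately naive re-implementations used to verify
# the package's optimized paths.

BASES <- c("A", "C", "G", "U")

rand_rna <- function(len) paste(sample(BASES, len, replace = TRUE),
                                collapse = "")

# naive substring scan: all 0-based start positions of pattern in text
naive_exact_positions <- function(text, pattern) {
  k <- nchar(pattern)
  L <- nchar(text)
  if (k > L) return(integer(0))
  starts <- 0:(L - k)
  starts[vapply(starts, function(p)
    substr(text, p + 1, p + k) == pattern, TRUE)]
}

# naive Hamming-distance scan, one sequence
naive_hamming_positions <- function(text, pattern, budget) {
  k <- nchar(pattern)
  L <- nchar(text)
  if (k > L) return(integer(0))
  pc <- strsplit(pattern, "")[[1]]
  tc <- strsplit(text, "")[[1]]
  starts <- 0:(L - k)
  starts[vapply(starts, function(p)
    sum(tc[(p + 1):(p + k)] != pc) <= budget, TRUE)]
}

# brute-force Hamming ball over the full 4^k spectrum
naive_ball <- function(root, m) {
  k <- nchar(root)
  rc <- strsplit(root, "")[[1]]
  all_kmers <- kmer_spectrum(k)
  keep <- vapply(strsplit(all_kmers, ""), function(ch)
    sum(ch != rc) <= m, TRUE)
  all_kmers[keep]
}

# rotation-sort BWT oracle
naive_bwt <- function(text) {
  n <- nchar(text)
  rots <- vapply(0:(n - 1), function(i)
    paste0(substr(text, i + 1, n), substr(text, 1, i)), "")
  sorted <- sort(rots, method = "radix")
  paste(substr(sorted, n, n), collapse = "")
}

# direct transliteration of the F-score formula, one feature at a time
naive_fscore <- function(xpos, xneg, eps = 1e-12) {
  mp <- mean(xpos); mn <- mean(xneg); mall <- mean(c(xpos, xneg))
  num <- (mp - mall)^2 + (mn - mall)^2
  den <- sum((xpos - mp)^2) / (length(xpos) - 1) +
    sum((xneg - mn)^2) / (length(xneg) - 1)
  num / (den + eps)
}

# direct transliteration of the performance-metric equations
naive_metrics <- function(TP, TN, FP, FN) {
  den <- sqrt(as.numeric(TP + FP)) * sqrt(as.numeric(TP + FN)) *
    sqrt(as.numeric(TN + FP)) * sqrt(as.numeric(TN + FN))
  c(Acc = (TN + TP) / (TN + TP + FN + FP),
    Sn = if (TP + FN == 0) NA_real_ else TP / (TP + FN),
    Sp = if (TN + FP == 0) NA_real_ else TN / (TN + FP),
    Precision = if (TP + FP == 0) NA_real_ else TP / (TP + FP),
    F1 = if (TP + FP == 0 || TP + FN == 0 ||
             TP / (TP + FP) + TP / (TP + FN) == 0) NA_real_
         else 2 * (TP / (TP + FP)) * (TP / (TP + FN)) /
           (TP / (TP + FP) + TP / (TP + FN)),
    MCC = if (den == 0) 0 else (as.numeric(TP) * TN - as.numeric(FP) * FN) / den)
}

# exact upper-tail hypergeometric by direct combinatorial summation
naive_hyper_upper <- function(universe, m1, m2, both) {
  ks <- both:min(m1, m2)
  sum(choose(m1, ks) * choose(universe - m1, m2 - ks)) / choose(universe, m2)
}

# exact binomial upper tail by direct summation
naive_binom_upper <- function(x, n, p) {
  sum(vapply(x:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i), 0))
}
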
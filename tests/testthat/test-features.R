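test_that("dinucleotide window densities count per placement", {
  d1 <- dinucleotide_densities("AAAA", 4)
  expect_equal(unname(d1[1, "w4.p1.AA"]), 1)
  expect_equal(sum(d1), 1)
  d2 <- dinucleotide_densities("ACAC", 4)
  expect_equal(unname(d2[1, "w4.p1.AC"]), 2 / 3)
  expect_equal(unname(d2[1, "w4.p1.CA"]), 1 / 3)
  expect_error(dinucleotide_densities("ACGU", 10), "window")
})

test_that("densities of N-free windows always sum to one", {
  set.seed(71)
  seqs <- vapply(1:50, function(i) rand_rna(60), "")
  for (w in c(17, 31, 59)) {
    d <- dinucleotide_densities(seqs, w)
    npl <- 60 - w + 1
    for (p in sample(npl, min(4, npl)))
      expect_equal(unname(rowSums(d[, 16 * (p - 1) + 1:16])), rep(1, 50))
  }
})

test_that("k-mer tensors have the full spectrum as rows", {
  set.seed(72)
  seqs <- vapply(1:5, function(i) rand_rna(20), "")
  t5 <- build_kmer_tensor(seqs, 5)
  expect_equal(nrow(t5), 1024)
  expect_equal(ncol(t5), 16)
  t7 <- build_kmer_tensor(seqs, 7)
  expect_equal(nrow(t7), 16384)
  expect_equal(ncol(t7), 14)
  expect_true(all(t7 >= 0 & t7 <= 1))
})

test_that("a budget-0 tensor of identical sequences is an indicator", {
  seqs <- rep("ACGUACGUAC", 4)
  t0 <- build_kmer_tensor(seqs, 5, mismatch_budget = 0)
  codes <- rbpsites:::cpp_encode_kmers(seqs[1], 5L)
  for (p in seq_len(ncol(codes))) {
    expect_equal(t0[codes[1, p] + 1, p], 1)
    expect_equal(sum(t0[, p]), 1)
  }
})

test_that("tensor cells match a naive per-position Hamming fraction", {
  set.seed(73)
  seqs <- vapply(1:12, function(i) rand_rna(15), "")
  tens <- build_kmer_tensor(seqs, 5, mismatch_budget = 2)
  sp <- kmer_spectrum(5)
  for (trial in 1:25) {
    m <- sample(1024, 1); p <- sample(ncol(tens), 1)
    frac <- mean(vapply(seqs, function(s) {
      w <- substr(s, p, p + 4)
      sum(strsplit(w, "")[[1]] != strsplit(sp[m], "")[[1]]) <= 2
    }, TRUE))
    expect_equal(tens[m, p], frac)
  }
})

test_that("projection looks up the observed k-mer per position", {
  seqs <- rep("ACGUACGUAC", 3)
  tens <- build_kmer_tensor(seqs[1], 5, mismatch_budget = 0)
  proj <- project_sequence(tens, seqs)
  expect_true(all(proj == 1))
  # a sequence with no relative anywhere projects to zero
  other <- strrep("A", 10)
  tensA <- build_kmer_tensor("CGCGCGCGCG", 5, mismatch_budget = 0)
  expect_true(all(project_sequence(tensA, other) == 0))
  expect_error(project_sequence(tens, "ACGU"), "length")
})

test_that("planted-motif positives project higher at motif positions", {
  set.seed(74)
  mk <- function(with) vapply(1:60, function(i)
    if (with) paste0(rand_rna(20), "GAAGGAA", rand_rna(20)) else rand_rna(47),
    "")
  pos <- mk(TRUE); bg <- mk(FALSE)
  tens <- build_kmer_tensor(pos, 7)
  ppos <- project_sequence(tens, pos)
  pbg <- project_sequence(tens, bg)
  expect_gt(mean(ppos[, 21]), mean(pbg[, 21]))
})

test_that("structure triplets cover the 27-letter alphabet", {
  d <- structure_triplet_densities("....")
  expect_equal(length(d), 27)
  expect_equal(unname(d["..."]), 1)
  expect_equal(sum(d), 1)
  d2 <- structure_triplet_densities("((((")
  expect_equal(unname(d2["((("]), 1)
  expect_error(structure_triplet_densities("..x."), "illegal")
})

test_that("the F-score follows the printed formula", {
  m <- cbind(f1 = c(1, 1, 0, 0, 0, 0))
  labels <- c(1, 1, 1, 0, 0, 0)
  fr <- fscore_rank(m, labels)
  expect_equal(fr$F, 2 / 3, tolerance = 1e-9)
  # identical feature in both classes scores zero
  m2 <- cbind(f1 = rep(1, 6))
  expect_equal(fscore_rank(m2, labels)$F, 0, tolerance = 1e-9)
  # symmetric under label swap
  set.seed(75)
  m3 <- matrix(rnorm(60), 12, 5)
  f_a <- fscore_rank(m3, rep(c(1, 0), each = 6))
  f_b <- fscore_rank(m3, rep(c(0, 1), each = 6))
  expect_equal(f_a$F[order(f_a$feature)], f_b$F[order(f_b$feature)],
               tolerance = 1e-12)
  expect_error(fscore_rank(m3, c(1, rep(0, 11))), "at least 2")
})

test_that("F-scores match an independent direct evaluation on random matrices", {
  set.seed(76)
  for (i in 1:100) {
    n <- sample(6:20, 1); d <- sample(1:6, 1)
    m <- matrix(rnorm(n * d), n, d,
                dimnames = list(NULL, paste0("f", 1:d)))
    y <- c(rep(1, ceiling(n / 2)), rep(0, floor(n / 2)))
    got <- fscore_rank(m, y)
    for (j in 1:d) {
      want <- naive_fscore(m[y == 1, j], m[y == 0, j])
      expect_equal(got$F[got$feature == paste0("f", j)], want,
                   tolerance = 1e-10)
    }
  }
})

test_that("feature assembly is schema-stable between train and test", {
  set.seed(77)
  mkseq <- function(n) vapply(1:n, function(i) rand_rna(156), "")
  train_pos <- mkseq(20); train_all <- c(train_pos, mkseq(20))
  schema <- build_feature_schema(train_pos, train_all, dinuc_window = 17)
  x_tr <- assemble_features(train_all, schema)
  x_te <- assemble_features(mkseq(10), schema)
  expect_identical(colnames(x_tr), colnames(x_te))
  expect_identical(colnames(x_tr), schema$feature_names)
  expect_false(anyNA(x_te))
  # heptamer projection of a 156-base instance spans 150 positions
  expect_equal(sum(grepl("^k7\\.", schema$feature_names)), 150)
  expect_equal(sum(grepl("^k5\\.", schema$feature_names)), 152)
  # disabling the heptamer block shortens the vector by exactly its length
  schema2 <- build_feature_schema(train_pos, train_all, dinuc_window = 17,
                                  use_heptamers = FALSE)
  expect_equal(length(schema2$feature_names),
               length(schema$feature_names) - 150)
})

test_that("N-containing windows are imputed from training column means", {
  set.seed(78)
  train <- vapply(1:10, function(i) rand_rna(156), "")
  schema <- build_feature_schema(train, train, dinuc_window = 17)
  withN <- paste0("NN", substr(rand_rna(156), 3, 156))
  x <- assemble_features(withN, schema)
  expect_false(anyNA(x))
})
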
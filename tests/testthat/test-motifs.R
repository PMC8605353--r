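test_that("the 6-mer seed spectrum is complete and ordered", {
  sp <- kmer_spectrum(6)
  expect_equal(length(sp), 4096)
  expect_equal(sp[1], "AAAAAA")
  expect_equal(anyDuplicated(sp), 0)
  expect_equal(sp, sort(sp, method = "radix"))
})

test_that("null probabilities are corpus fractions with a pseudo-probability floor", {
  set.seed(5)
  corpus <- c(vapply(1:23, function(i) paste0(rand_rna(10), "UGCAUG",
                                              rand_rna(10)), ""),
              rep("AAAAAAAAAAAAAAAAAAAAAAAAAA", 77))
  expect_equal(null_probability("UGCAUG", corpus, 0), 0.23)
  none <- rep("AAAAAAAAAAAAAAAA", 1000)
  expect_equal(null_probability("GCGCGC", none, 0), 1 / 2000)
  # monotone in the radius
  set.seed(6)
  rc <- vapply(1:200, function(i) rand_rna(40), "")
  expect_lte(null_probability("UGCAUG", rc, 0),
             null_probability("UGCAUG", rc, 2))
  expect_error(null_probability("UGCAUG", character(0)), "empty")
})

test_that("seed enrichment uses the exact one-sided binomial upper tail", {
  carriers <- vapply(1:10, function(i)
    paste0(rand_rna(8), "UGCAUG", rand_rna(8)), "")
  r <- seed_enrichment(carriers, "UGCAUG", radius = 0, p0 = 0.5)
  expect_equal(r$x, 10)
  expect_equal(r$pvalue, 0.5^10)
  expect_true(r$significant)

  none <- replicate(10, paste(rep("A", 20), collapse = ""))
  r0 <- seed_enrichment(none, "GCGCGC", radius = 0, p0 = 0.3)
  expect_equal(r0$x, 0)
  expect_equal(r0$pvalue, 1)

  # coverage rule met but no enrichment over the null
  set.seed(8)
  mixed <- c(vapply(1:70, function(i)
    paste0(rand_rna(6), "UGCAUG", rand_rna(6)), ""),
    vapply(1:30, function(i) chartr("U", "A", rand_rna(18)), ""))
  r2 <- seed_enrichment(mixed, "UGCAUG", radius = 0, p0 = 0.7)
  expect_equal(r2$pvalue, naive_binom_upper(r2$x, 100, 0.7), tolerance = 1e-12)
  expect_false(r2$significant)
  expect_error(seed_enrichment(mixed, "UGCAUG", radius = 0, p0 = 1.2),
               "p0")
})

test_that("pvalue decreases as x increases at fixed (n, p0)", {
  p <- vapply(1:20, function(x) pbinom(x - 1, 20, 0.3, lower.tail = FALSE), 0)
  expect_true(all(diff(p) < 0))
})

test_that("a seed inside an exactly planted 8-mer expands to it and stops", {
  set.seed(21)
  peaks <- vapply(1:120, function(i)
    paste0(rand_rna(12), "UGCAUGCC", rand_rna(12)), "")
  m <- expand_seed("GCAUGC", peaks)
  expect_equal(m$consensus, "UGCAUGCC")
  expect_equal(m$coverage, 1)
  expect_equal(unname(colSums(m$pwm)), rep(length(m$matched_peak_ids), 8))
})

test_that("expansion that would break the coverage rule returns the seed unchanged", {
  # the planted word is only the 6-mer itself; flanks are uniform noise
  set.seed(22)
  peaks <- vapply(1:150, function(i)
    paste0(rand_rna(10), "CCGAUC", rand_rna(10)), "")
  m <- expand_seed("CCGAUC", peaks)
  expect_equal(nchar(m$consensus), 6)
  expect_equal(m$consensus, "CCGAUC")
})

test_that("a noisy planted motif at 75% coverage is recovered within 1 mismatch", {
  set.seed(23)
  planted <- "UGCAUGCC"
  mutate1 <- function(s, rate) {
    ch <- strsplit(s, "")[[1]]
    hit <- runif(length(ch)) < rate
    for (i in which(hit)) ch[i] <- sample(setdiff(BASES, ch[i]), 1)
    paste(ch, collapse = "")
  }
  peaks <- vapply(1:400, function(i) {
    if (i <= 300) paste0(rand_rna(14), mutate1(planted, 0.1), rand_rna(14))
    else rand_rna(36)
  }, "")
  m <- expand_seed("GCAUGC", peaks, min_coverage = 0.6)
  # recovered family stays within one mismatch of the planted word (any
  # register)
  expect_gte(rbpsites:::consensus_identity(m$consensus, planted), 7 / 8)
  expect_gte(m$coverage, 0.70)
})

test_that("prime selection ranks by coverage, then length, then enrichment", {
  mk <- function(cons, cov, p) rbpsites:::new_prime_motif(
    cons, matrix(1, 4, nchar(cons)), cov, seq_len(10), "primary", p)
  expect_equal(select_prime(list(mk("AAAAAA", 0.92, 1e-4),
                                 mk("CCCCCC", 0.75, 1e-9)))$consensus,
               "AAAAAA")
  expect_equal(select_prime(list(mk("AAAAAAUU", 0.8, 1e-4),
                                 mk("CCCCCCC", 0.8, 1e-9)))$consensus,
               "AAAAAAUU")
  expect_equal(select_prime(list(mk("CCCCCC", 0.8, 1e-4),
                                 mk("AAAAAA", 0.8, 1e-4)))$consensus,
               "AAAAAA")
  expect_error(select_prime(list()), "no candidate")
})

test_that("mutually exclusive motifs partition residual peaks", {
  set.seed(25)
  # bare-footprint peaks: with all sub-6-mers of the two words at Hamming
  # distance >= 5, no single 6-mer family can bridge both (triangle
  # inequality at the 2-mismatch radius), so the mixture must split
  a <- "UGCAUGCC"; b <- "AAGAGAAU"
  peaks <- vapply(1:500, function(i) {
    if (i <= 225) a
    else if (i <= 425) b
    else rand_rna(8)
  }, "")
  null <- vapply(1:500, function(i) rand_rna(8), "")
  nc <- scan_seed_counts(null)
  p0 <- rbpsites:::clamp_probability(nc / length(null), length(null))
  ex <- find_exclusive_motifs(peaks, covered_ids = integer(0), p0 = p0)
  expect_gte(length(ex), 2)
  cons <- vapply(ex, `[[`, "", "consensus")
  idf <- function(cc, m) rbpsites:::consensus_identity(cc, m)
  expect_true(any(vapply(cons, idf, 0, m = a) >= 5 / 6))
  expect_true(any(vapply(cons, idf, 0, m = b) >= 5 / 6))
  # instance sets overlap very little
  ov <- length(intersect(ex[[1]]$matched_peak_ids, ex[[2]]$matched_peak_ids)) /
    length(union(ex[[1]]$matched_peak_ids, ex[[2]]$matched_peak_ids))
  expect_lt(ov, 0.15)
  expect_true(all(vapply(ex, `[[`, "", "kind") == "mutually_exclusive"))
})

test_that("residual seeds below 20% representation are not pursued", {
  set.seed(26)
  peaks <- vapply(1:400, function(i) {
    if (i <= 60) paste0(rand_rna(12), "UGCAUGCC", rand_rna(12))  # 15%
    else rand_rna(32)
  }, "")
  null <- vapply(1:400, function(i) rand_rna(32), "")
  p0 <- rbpsites:::clamp_probability(
    scan_seed_counts(null) / length(null), length(null))
  ex <- find_exclusive_motifs(peaks, covered_ids = integer(0), p0 = p0)
  if (length(ex) > 0)
    expect_true(all(vapply(ex, `[[`, 0, "coverage") >= 0.20))
})

test_that("motif clustering is single linkage on best-offset identity", {
  expect_equal(cluster_motifs(list("UGCAUG", "UGCAUG", "UGCAUG")),
               c(1, 1, 1))
  expect_equal(cluster_motifs(list("UGCAUG", "ACGACG")), c(1, 2))
  # A ~ B and B ~ C but A !~ C: one cluster by single linkage
  cl <- cluster_motifs(list("AAAAAA", "AAAACC", "AACCCC"), min_similarity = 2/3)
  expect_equal(cl, c(1, 1, 1))
})

test_that("motif length never leaves the 6-10 band and coverage shrinks with length", {
  set.seed(27)
  peaks <- vapply(1:200, function(i)
    paste0(rand_rna(10), "UGCAUGCCAA", rand_rna(10)), "")
  m <- expand_seed("GCAUGC", peaks)
  expect_gte(nchar(m$consensus), 6)
  expect_lte(nchar(m$consensus), 10)
  # prefix/suffix of the final consensus always cover at least as much
  cons <- m$consensus
  L <- nchar(cons)
  cover_of <- function(s) {
    hits <- rbpsites:::cpp_hamming_scan(peaks, s,
      rbpsites:::mismatch_budget(nchar(s)))
    sum(lengths(hits) > 0)
  }
  if (L > 6) {
    expect_lte(cover_of(cons), cover_of(substr(cons, 1, L - 1)))
    expect_lte(cover_of(cons), cover_of(substr(cons, 2, L)))
  }
})

test_that("motif reports serialize as TSV and MEME minimal format", {
  set.seed(28)
  peaks <- vapply(1:80, function(i)
    paste0(rand_rna(10), "UGCAUGCC", rand_rna(10)), "")
  m <- expand_seed("GCAUGC", peaks)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_motif_tsv(list(m), tsv)
  tab <- read.delim(tsv)
  expect_equal(tab$consensus, "UGCAUGCC")
  meme <- withr::local_tempfile(fileext = ".meme")
  write_meme(list(m), meme)
  lines <- readLines(meme)
  expect_true(any(grepl("^MEME version", lines)))
  expect_true(any(grepl("MOTIF UGCAUGCC", lines)))
  expect_true(any(grepl("alength= 4 w= 8", lines)))
})
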
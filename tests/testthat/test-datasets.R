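test_that("peak filtering keeps 5-300 nt and collapses duplicates", {
  iv <- data.frame(chrom = "c", start = c(0, 0, 0, 0, 0, 10),
                   end = c(4, 5, 150, 300, 301, 160),
                   strand = "+")
  kept <- filter_peaks(iv)
  expect_equal(kept$end - kept$start, c(5, 150, 300, 150))
  dup <- iv[c(3, 3), ]
  expect_equal(nrow(filter_peaks(dup)), 1)
  seqs <- c("AAAA", "AAAAA", strrep("A", 300), strrep("A", 301))
  expect_equal(nchar(filter_peaks(seqs)), c(5, 300))
})

test_that("RBP eligibility requires strictly more than 500 unique peaks", {
  mk <- function(n) data.frame(chrom = "c", start = seq_len(n),
                               end = seq_len(n) + 10, strand = "+")
  expect_false(rbp_eligible(mk(473)))
  expect_false(rbp_eligible(mk(500)))
  expect_true(rbp_eligible(mk(501)))
})

test_that("positive instances are motif-anchored with exact lengths 156-160", {
  set.seed(61)
  for (motif in c("UGCAUG", "UGCAUGCCAA")) {
    k <- nchar(motif)
    tx <- vapply(1:30, function(i)
      paste0(rand_rna(100), motif, rand_rna(100)), "")
    names(tx) <- paste0("t", 1:30)
    pos <- build_positive(tx, prime_motif = motif)
    expect_true(all(nchar(pos$sequence) == k + 150))
  }
  # two occurrences in one source give two instances
  tx2 <- c(one = paste0(rand_rna(90), "UGCAUG", rand_rna(60), "UGCAUG",
                        rand_rna(90)))
  pos2 <- build_positive(tx2, prime_motif = "UGCAUG")
  expect_gte(nrow(pos2), 2)
})

test_that("interval input pulls flanks from the genome beyond the peak", {
  set.seed(62)
  genome <- c(g1 = paste0(rand_rna(100), "UGCAUGCC", rand_rna(100)))
  peaks <- data.frame(chrom = "g1", start = 95, end = 115, strand = "+")
  pos <- build_positive(peaks, genome, "UGCAUGCC")
  expect_equal(nchar(pos$sequence[1]), 158)
  expect_equal(substr(pos$sequence[1], 76, 83), "UGCAUGCC")
  # edge occurrences without full flanks are skipped
  short <- c(g2 = paste0("UGCAUGCC", rand_rna(100)))
  expect_error(build_positive(data.frame(chrom = "g2", start = 0, end = 20,
                                         strand = "+"), short, "UGCAUGCC"),
               "full flanks")
})

test_that("Set A negatives come only from unbound motif-bearing transcripts", {
  set.seed(63)
  tx <- stats::setNames(vapply(1:300, function(i)
    paste0(rand_rna(80), "UGCAUG", rand_rna(80)), ""), paste0("u", 1:300))
  neg <- build_negative_setA(tx, "UGCAUG")
  expect_gte(nrow(neg), 300)
  expect_true(all(nchar(neg$sequence) == 156))
  expect_true(all(neg$strategy == "A"))
  # transcripts in the bound list are excluded
  neg2 <- build_negative_setA(tx, "UGCAUG", bound_ids = paste0("u", 1:100))
  expect_false(any(neg2$origin %in% paste0("u", 1:100)))
  # motif-free transcripts contribute nothing
  rna_only_a <- stats::setNames(rep(strrep("A", 200), 5), paste0("a", 1:5))
  expect_error(build_negative_setA(rna_only_a, "UGCGCG", n_required = 5),
               "shortfall")
})

test_that("Set B negatives keep a minimum distance from every peak", {
  set.seed(64)
  k <- 8
  tx <- c(b1 = paste0(rand_rna(100), "UGCAUGCC", rand_rna(480),
                      "UGCAUGCC", rand_rna(100)))
  pk <- data.frame(chrom = "b1", start = 95, end = 115, strand = "+")
  far <- build_negative_setB(tx, pk, "UGCAUGCC", min_distance = 300)
  expect_true(588 %in% far$anchor_start)       # planted distal site accepted
  expect_false(100 %in% far$anchor_start)      # occurrence inside the peak
  # every accepted anchor keeps the distance on one side of the peak
  expect_true(all(far$anchor_start - 115 >= 300 |
                    95 - (far$anchor_start + k) >= 300))
  # tighten the distance so the planted distal site is rejected too
  near <- build_negative_setB(tx, pk, "UGCAUGCC", min_distance = 600)
  expect_false(588 %in% near$anchor_start)
})

test_that("balancing and splitting are exact, deterministic and leakage-free", {
  set.seed(65)
  mk_inst <- function(n, tag) data.frame(
    sequence = vapply(1:n, function(i) rand_rna(156), ""),
    origin = paste0(tag, 1:n), anchor_start = 75, strategy = NA_character_,
    stringsAsFactors = FALSE)
  pos <- mk_inst(1000, "p"); neg <- mk_inst(800, "n")
  is1 <- balance_and_split(pos, neg, motif_length = 6, train_fraction = 0.7,
                           rng_seed = 3)
  tab <- table(is1$instances$label, is1$instances$split)
  expect_equal(unname(tab["1", "train"]), 560)
  expect_equal(unname(tab["0", "train"]), 560)
  expect_equal(unname(tab["1", "test"]), 240)
  is2 <- balance_and_split(pos, neg, motif_length = 6, train_fraction = 0.7,
                           rng_seed = 3)
  expect_identical(is1$instances, is2$instances)

  # a sequence string occurring in both classes is dropped from both
  neg$sequence[1] <- pos$sequence[1]
  expect_warning(is3 <- balance_and_split(pos, neg, motif_length = 6,
                                          rng_seed = 3), "both classes")
  expect_false(pos$sequence[1] %in% is3$instances$sequence)
  expect_error(suppressWarnings(
    balance_and_split(pos[1:10, ], neg[1:10, ], motif_length = 6,
                      rng_seed = 1)), "fewer than")
})

test_that("every emitted instance re-matches the prime motif at the anchor", {
  set.seed(66)
  motif <- "UGCAUGCC"
  budget <- rbpsites:::mismatch_budget(nchar(motif))
  tx <- stats::setNames(vapply(1:100, function(i)
    paste0(rand_rna(80), motif, rand_rna(80)), ""), paste0("t", 1:100))
  pos <- build_positive(tx, prime_motif = motif)
  anchors <- substr(pos$sequence, 76, 75 + nchar(motif))
  mm <- vapply(strsplit(anchors, ""), function(ch)
    sum(ch != strsplit(motif, "")[[1]]), 0L)
  expect_true(all(mm <= budget))
})

test_that("instance sets serialize as FASTA plus manifest", {
  set.seed(67)
  mk_inst <- function(n, tag) data.frame(
    sequence = vapply(1:n, function(i) rand_rna(156), ""),
    origin = paste0(tag, 1:n), anchor_start = 75, strategy = "A",
    stringsAsFactors = FALSE)
  iset <- balance_and_split(mk_inst(60, "p"), mk_inst(60, "n"),
                            motif_length = 6, rng_seed = 1)
  pre <- file.path(withr::local_tempdir(), "iset")
  write_instance_set(iset, pre)
  fa <- read_fasta_rna(paste0(pre, ".fa"))
  expect_equal(length(fa), 120)
  man <- read.delim(paste0(pre, ".tsv"))
  expect_equal(nrow(man), 120)
  expect_true(all(c("label", "split", "origin") %in% names(man)))
})
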
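make_instances <- function(n, anchor = "UGCAUGCC", partner = NULL,
                           offset = NULL, jitter = 0, flank = 75) {
  vapply(seq_len(n), function(i) {
    L <- nchar(anchor) + 2 * flank
    s <- rand_rna(L)
    s <- paste0(substr(s, 1, flank), anchor,
                substr(s, flank + nchar(anchor) + 1, L))
    if (!is.null(partner)) {
      off <- offset + if (jitter > 0) sample(-jitter:jitter, 1) else 0
      p0 <- flank + off          # 0-based partner start
      s <- paste0(substr(s, 1, p0), partner,
                  substr(s, p0 + nchar(partner) + 1, L))
    }
    s
  }, "")
}

test_that("offset distributions report the nearest candidate hit per instance", {
  set.seed(51)
  inst <- make_instances(60, partner = "GAAGGAAG", offset = 20)
  offs <- distance_distribution(inst, "UGCAUGCC", "GAAGGAAG", budget = 0)
  expect_true(all(offs == 20))
  none <- distance_distribution(make_instances(20), "UGCAUGCC",
                                "CCCCCCCC", budget = 0)
  expect_equal(length(none), 0)
  instj <- make_instances(80, partner = "GAAGGAAG", offset = -30, jitter = 2)
  offsj <- distance_distribution(instj, "UGCAUGCC", "GAAGGAAG", budget = 0)
  expect_equal(length(offsj), 80)
  # rare chance occurrences of the exact partner can sit nearer the anchor
  expect_gte(mean(offsj >= -32 & offsj <= -28), 0.95)
  expect_error(distance_distribution(instj, "UGCAUGCC", rand_rna(80)),
               "longer than")
})

test_that("the KS co-occurrence test behaves at the extremes", {
  x <- c(-10, 0, 10, 20, 30)
  same <- ks_cooccurrence_test(x, x)
  expect_equal(same$D, 0)
  expect_equal(same$pvalue, 1)
  disj <- ks_cooccurrence_test(rep(20, 30), rep(-20, 30))
  expect_equal(disj$D, 1)
  set.seed(52)
  peaked <- round(rnorm(200, 20, 2))
  unif <- sample(-75:75, 200, replace = TRUE)
  expect_lt(ks_cooccurrence_test(peaked, unif)$pvalue, 0.01)
  expect_warning(ks_cooccurrence_test(c(1, 2), unif), "fewer than 5")
  expect_error(ks_cooccurrence_test(numeric(0), unif), "non-empty")
})

test_that("the frequency ratio is the conditional-rate ratio with edge policies", {
  expect_equal(frequency_ratio(100, 60, 200, 30), 4.0)
  expect_equal(frequency_ratio(100, 30, 200, 60), 1.0)
  expect_equal(frequency_ratio(100, 0, 200, 60), 0)
  expect_equal(frequency_ratio(100, 60, 200, 0), Inf)
  expect_error(frequency_ratio(0, 0, 200, 10), "positive")
})

test_that("hypergeometric over-representation matches exact combinatorics", {
  expect_equal(hypergeometric_cooccurrence(20, 10, 10, 10),
               1 / choose(20, 10), tolerance = 1e-12)
  expect_equal(hypergeometric_cooccurrence(20, 10, 10, 0), 1)
  # overlap exactly at its expectation: mid-range p
  p_mid <- hypergeometric_cooccurrence(100, 40, 50, 20)
  expect_equal(p_mid, naive_hyper_upper(100, 40, 50, 20), tolerance = 1e-12)
  expect_gt(p_mid, 0.3); expect_lt(p_mid, 0.8)
  expect_error(hypergeometric_cooccurrence(20, 10, 10, 11), "inconsistent")
})

test_that("hypergeometric agreement with random tables matches stats::phyper", {
  set.seed(53)
  for (i in 1:50) {
    u <- sample(20:200, 1)
    m1 <- sample(1:u, 1); m2 <- sample(1:u, 1)
    b <- sample(max(0, m1 + m2 - u):min(m1, m2), 1)
    expect_equal(hypergeometric_cooccurrence(u, m1, m2, b),
                 naive_hyper_upper(u, m1, m2, b), tolerance = 1e-9)
  }
})

test_that("FR and the hypergeometric tail agree directionally", {
  set.seed(54)
  for (i in 1:100) {
    X <- sample(20:200, 1); Y <- sample(20:200, 1)
    N <- sample(1:(X - 1), 1); M <- sample(1:(Y - 1), 1)
    fr <- frequency_ratio(X, N, Y, M)
    above <- N / X > M / Y                      # overlap above expectation
    if (fr != 1) expect_equal(fr > 1, above)
  }
})

test_that("PWM similarity is shift-maximized, symmetric and chance-corrected", {
  onehot <- rbpsites:::onehot_pwm
  expect_equal(pwm_jaccard(onehot("UGCAUGCC"), onehot("UGCAUGCC")), 1)
  expect_equal(pwm_jaccard(onehot("AAAAAA"), onehot("CCCCCC")), 0)
  a <- onehot("UGCAUGCC"); b <- onehot("GAAGGAAG")
  expect_equal(pwm_jaccard(a, b), pwm_jaccard(b, a))
  # motif against itself shifted by one, 7-column overlap:
  # raw agreement 7/8, chance-rescaled (7/8 - 1/4) / (3/4)
  shifted <- onehot(paste0(substr("UGCAUGCC", 2, 8), "A"))
  expect_equal(pwm_jaccard(onehot("UGCAUGCC"), shifted),
               (7 / 8 - 0.25) / 0.75, tolerance = 1e-12)
})

test_that("a planted partner passes all four screening criteria; junk does not", {
  set.seed(55)
  n <- 250
  carrier <- runif(n) < 0.6
  inst <- vapply(seq_len(n), function(i) {
    if (carrier[i]) make_instances(1, partner = "GAAGGAAG", offset = -30,
                                   jitter = 2)
    else make_instances(1)
  }, "")
  bg <- shuffle_sequences(inst, seed = 99)
  anchor <- rbpsites:::new_prime_motif(
    "UGCAUGCC", rbpsites:::onehot_pwm("UGCAUGCC") * 10, 0.9,
    seq_len(n), "primary", 1e-10)
  cands <- cooccurrence_candidates(inst, bg, anchor)
  expect_gte(length(cands), 1)
  tab <- find_cooccurring(inst, bg, anchor, cands)
  sig <- tab[tab$significant, , drop = FALSE]
  expect_gte(nrow(sig), 1)
  hit <- vapply(sig$partner, function(p)
    rbpsites:::consensus_identity(p, "GAAGGAAG"), 0)
  expect_true(any(hit >= 0.9))
  expect_true(all(sig$FR > 1))
  expect_true(all(sig$jaccard < 0.2))

  # permuted labels: mix bound and shuffle pools, expect no significant pair
  set.seed(56)
  pool <- c(inst, bg)
  perm <- sample(length(pool))
  inst_p <- pool[perm[seq_len(n)]]
  bg_p <- pool[perm[(n + 1):(2 * n)]]
  tab_p <- find_cooccurring(inst_p, bg_p, anchor, cands)
  expect_equal(sum(tab_p$significant), 0)
})

test_that("pair reports serialize with offset histograms", {
  set.seed(57)
  inst <- make_instances(40, partner = "GAAGGAAG", offset = -30)
  bg <- shuffle_sequences(inst, seed = 1)
  anchor <- rbpsites:::new_prime_motif(
    "UGCAUGCC", rbpsites:::onehot_pwm("UGCAUGCC") * 10, 0.9,
    seq_len(40), "primary", 1e-10)
  partner <- rbpsites:::new_prime_motif(
    "GAAGGAAG", rbpsites:::onehot_pwm("GAAGGAAG") * 10, 0.6,
    seq_len(24), "candidate", NA_real_)
  tab <- find_cooccurring(inst, bg, anchor, list(partner))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cooccurrence_tsv(tab, f)
  expect_true(file.exists(f))
  expect_true(file.exists(paste0(f, ".offsets.tsv")))
  off <- read.delim(paste0(f, ".offsets.tsv"))
  # the modal offset is the planted one (the inexact scan adds a few
  # spurious nearest hits)
  expect_equal(off$offset[which.max(off$count)], -30)
})
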
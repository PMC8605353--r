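# rbpsites

Discovery and prediction of RNA-binding protein (RBP) binding sites from
cross-linking peak data.

RBPs steer splicing, export, stability and translation, and CLIP-seq-style
experiments report where they cross-link — but not *why*. Their motifs are
short, sparse and degenerate, so motif presence alone separates bound from
unbound regions poorly: transcriptomes are full of motif-like words that
are never bound. `rbpsites` is for computational biologists who want to
turn a set of called peaks (plus transcript/genome sequence) into a
predictive, scannable model of an RBP's binding sites, and for method
developers who need a fully synthetic, truth-tabled benchmark for this
class of pipeline.

## The model

**Anchor.** All 4,096 6-mer seeds are searched across the peaks together
with every relative within Hamming distance 2, through a
Burrows–Wheeler/FM-index inexact search. A seed family is significant when
it covers ≥ 70% of peaks and beats a length-matched random corpus in a
one-sided binomial test, P(X ≥ x | n, p₀) ≤ 0.01. Significant seeds are
expanded base-by-base (≤ 30% mismatches at each length, up to 10 nt) while
≥ 70% of matched instances agree on the appended base; the best-scoring
expanded family of the most enriched seeds is the **prime motif**. Peaks
without a 70% family are partitioned recursively into **mutually
exclusive** motifs (≥ 20% representation).

**Context.** Each motif occurrence ± 75 bases becomes a fixed-length
instance (156–160 nt). Features: positional dinucleotide window densities
(best window size selected on validation accuracy from the 17–131 grid),
plus mismatch-tolerant pentamer (4⁵ rows) and heptamer (4⁷ rows)
positional probability tensors estimated from training positives. A
gradient-boosted-tree classifier (η = 0.2, depth 4, logistic objective) or
a two-hidden-layer feed-forward net separates bound from unbound
instances; negatives carry the same motif (Set A: expressed-but-unbound
transcripts; Set B: distal regions of bound transcripts), so context does
the work. Co-occurring secondary motifs in the flanks are screened with a
KS test on anchor-relative offsets, a hypergeometric test, the frequency
ratio FR = (N/X)/(M/Y) > 1, and a PWM-similarity screen (< 0.2).

Performance is reported as Acc, Sn, Sp, Precision, F1, MCC and trapezoidal
AUC from the held-out confusion matrix.

## Worked example

Fit a model on a synthetic peak set with a planted motif, CG-enriched
context and a co-occurring partner, then scan sequences:

```r
library(rbpsites)
cfg <- sim_config(n_peaks = 600, rng_seed = 1)
ps  <- simulate_peakset(cfg)
bg  <- simulate_background(cfg, "setA")
fit <- rbp_fit(ps$peaks, background = bg$transcripts, genome = ps$genome,
               seed = 1)
summary(fit)
```

```
RBP binding-site model
  prime motif:  UGCAUGCC  (8 nt, 79.7% coverage, primary)
  classifier:  gbt on 1714 features (dinucleotide window 71)
  held-out:    Acc 0.892 | F1 0.887 | MCC 0.787 | AUC 0.954

Instances: 1080 of length 158 (motif 8 + 2 x 75 flanks); train fraction 0.70

Top contextual features by F-score:
    feature         F      t_pvalue
 w71.p88.CG 0.8746366 6.311797e-104
 w71.p87.CG 0.8531704 2.923834e-102
 ...

Co-occurring motifs: 1 significant of 5 evaluated
  partner       FR ks_pvalue hyper_pvalue   jaccard
 GAAGGAAG 1.407868         0 8.215505e-08 0.1666667
```

The planted consensus (`UGCAUGCC`, planted in 80% of peaks) is recovered
exactly at 79.7% coverage; the strongest contextual features are CG
densities in the flanks (the planted context bias), and the planted
partner (`GAAGGAAG`, 60% carriage at offset −30) is the one significant
co-occurring pair. Scanning returns BED-ready calls:

```r
predict(fit, ps$genome[1:3], strand_mode = "sense")
```

```
  seq_id strand start end    motif mismatches     score verdict
1 tx0001      +   166 174 UGCAUGCC          1 0.9951798    TRUE
2 tx0001      +   175 183 UGCAUGCC          1 0.9988481    TRUE
```

`report_calls()` writes BED6 (score = 1000 × classifier score) and a full
TSV. A thin command-line wrapper with `simulate`, `discover`, `fit` and
`scan` subcommands is installed at `inst/cli/rbpsites.R`.

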
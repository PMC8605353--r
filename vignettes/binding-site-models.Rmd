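---
title: "Modelling RBP binding sites from cross-linking peaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling RBP binding sites from cross-linking peaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

RNA-binding proteins (RBPs) recognise short, degenerate sequence motifs, but
the motif alone is a weak predictor: motif-like words are everywhere in a
transcriptome, and most of them are not bound. `rbpsites` implements a
two-stage model of binding:

1. **A prime motif as the anchor.** Cross-linking (CLIP-seq style) peaks for
   one RBP are scanned for all $4^6 = 4096$ possible 6-mer seeds together
   with their *relatives* — every 6-mer within Hamming distance 2. A seed
   family is kept when it occurs in at least 70% of the peaks and is
   enriched against a length-matched random corpus by a one-sided binomial
   test ($P(X \ge x \mid n, p_0) \le 0.01$, with $x$ the number of peaks
   carrying the family, $n$ the peak count and $p_0$ the family's frequency
   in the random corpus). Enriched seeds are expanded one base at a time on
   both sides while at least 70% of the matched instances agree on the
   appended base and family coverage stays at or above 70%, up to 10 nt.
   The expansion allows up to $\lfloor 0.3k \rfloor$ mismatches at length
   $k$ (the explicit two-mismatch allowance applies at the 6-mer seed
   stage). The best-scoring expanded family of the most enriched seeds is
   the *prime motif*; when no seed reaches 70% of the data, the search
   recurses on the residual peaks with a 20% representation floor and
   reports *mutually exclusive* motifs instead.

2. **Context around the anchor decides binding.** Every prime-motif
   occurrence is expanded by 75 bases on each side into a fixed-length
   instance (156–160 nt for 6–10 nt motifs). Three contextual feature
   families are computed: positional dinucleotide densities in sliding
   windows (candidate sizes 17–131 nt, step 1; the best size is chosen by
   validation accuracy on the training split), and mismatch-tolerant
   pentamer and heptamer positional probability tensors ($4^5 \times
   (L-4)$ and $4^7 \times (L-6)$, budget 2) estimated from the training
   positives only and projected onto each instance. A gradient-boosted-tree
   classifier (learning rate 0.2, depth 4, logistic objective) or a compact
   two-hidden-layer feed-forward network (ReLU/ELU, sigmoid output, binary
   cross-entropy, Adam with L2 decay) separates bound from unbound
   motif-bearing instances.

Negative instances carry the *same* prime motif, so the classifier cannot
win by motif presence alone: Set A negatives are motif-anchored instances
from expressed-but-unbound transcripts; Set B negatives are motif
occurrences on bound transcripts at least 300 nt (configurable) away from
every peak.

Secondary motifs that *co-occur* with the anchor at a preferred offset are
screened in the ±75-base flanks with four criteria: a two-sample KS test of
the anchor-relative offset distribution against a composition-matched
shuffle null, a hypergeometric over-representation test, a frequency ratio
$FR = (N/X)/(M/Y) > 1$ (with $X$/$Y$ the sequences with/without the anchor
and $N$/$M$ those among them carrying the candidate), and a PWM similarity
screen that discards candidates that are really the anchor again.

## Fitting and prediction

`rbp_fit()` runs the whole pipeline and returns an `rbp_model`;
`predict()` scans new sequences (sense, antisense, or both strands) for
anchor occurrences, featurizes each context with the model's frozen schema
and scores it; `summary()`, `plot()` and `simulate()` report the fit,
draw the motif profile and partner offsets, and generate matched synthetic
data. Minus-strand calls are reported in forward coordinates with strand
`-`, BED-style.

```r
library(rbpsites)
cfg <- sim_config(n_peaks = 600, rng_seed = 1)
ps  <- simulate_peakset(cfg)
bg  <- simulate_background(cfg, "setA")
fit <- rbp_fit(ps$peaks, background = bg$transcripts, genome = ps$genome,
               seed = 1)
summary(fit)
calls <- predict(fit, ps$genome[1:5], strand_mode = "both")
```

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| seed length / mismatches | 6 / 2 | seed family definition; 2 mismatches also bound the sparsest known RBP motifs |
| expansion budget | $\lfloor 0.3k\rfloor$ | 30%-mismatch rule at expanded length $k$ |
| `min_coverage` | 0.70 | prime-motif share of peaks |
| `p_cutoff` | 0.01 | binomial enrichment level (no multiplicity correction, by design; a Bonferroni-style correction can be applied by lowering it) |
| `min_fraction` | 0.20 | representation floor for mutually exclusive motifs |
| `flank` | 75 nt | context captured on each side of the anchor |
| `min_distance` | 300 nt | Set-B separation between negatives and peaks |
| `train_fraction` | 0.7 | 0.6 is the feature-evaluation setting |
| `window_sizes` | 17, 43, 71, 91, 131 | dinucleotide window candidates from the odd 17–131 grid |
| `nrounds` | 300 (fit driver) | boosting rounds; the log-loss plateaus well before the classical 1000, which remains the `train_gbt()` default |
| `threshold` | 0.5 | decision threshold on the classifier score |

## The synthetic data generator

`sim_config()` fixes the study conditions every test runs under: 500 peaks
of 20–50 nt (typical eCLIP/PAR-CLIP call widths), a planted 8-mer consensus
(`UGCAUGCC`) carried by 80% of peaks with a 10% per-base substitution rate,
CG-dinucleotide enrichment (factor 2, by rejection sampling to the target
density ±0.025) in the 75-base context *outside* the peak footprint —
binding context is a property of the surroundings, not of the cross-linked
footprint itself — and a secondary motif (`GAAGGAAG`) in 60% of bound
sites at offset −30 ± 2 from the anchor (5% carriage in background). Each
peak lives on its own synthetic transcript with 150 nt of padding so flank
extraction mirrors the genome-backed case. All generators are pure
functions of (config, seed).

What the generator does **not** emulate: cross-link-induced truncations and
mutations, transcript-level expression structure, isoforms and splice
junctions, multiple binding modes per RBP, and the phylogenetic/positional
correlation structure of real transcriptomes. Passing the synthetic
benchmark therefore shows the machinery is correct and the statistics are
calibrated — not that real-data accuracy will match it.

## Numerical and design choices

* **Inexact search.** Seeds are searched through a Burrows–Wheeler/FM-index
  with exact backward search over the enumerated Hamming ball (radius ≤ 2
  keeps the ball at ≤ 154 for 6-mers); the occurrence table is checkpointed
  every 32 rows with on-the-fly completion. Motif re-search during
  expansion uses a direct mismatch-tolerant scan with identical semantics;
  both paths are tested against a naive Hamming scan, exactly.
* **Prime-motif scoring.** Candidates are ranked by (coverage, length,
  enrichment), but that ranking is applied *within* the expansions of the
  most enriched seeds (within an order of magnitude of the best, on
  log-scale tails). With two mismatches, one-mismatch "smears" of the true
  seed match almost every peak; without the enrichment gate an unexpanded
  smear would always out-cover the true expanded motif.
* **Consensus refinement.** After each extension the consensus is reset to
  the column majority of its matched instances (accepted while coverage
  stays within 2%), so seeds that start one mismatch off the true word
  converge to it instead of freezing the error.
* **Ties.** Flanking-column base ties break A < C < G < U; equal-scoring
  prime candidates break alphabetically; equal-accuracy windows break
  toward the smaller size.
* **Zero-frequency guards.** Null probabilities are clamped to
  $[1/2n, 1 - 1/2n]$; the F-score denominator carries an $\varepsilon =
  10^{-12}$ so zero-variance features keep the schema stable; MCC is 0 when
  its denominator vanishes; single-class test sets report NA sensitivity or
  specificity.
* **Tensor columns.** Position counts follow the standard $L - k + 1$; for
  a 156-base instance the heptamer tensor has 150 columns.
* **Null-corpus size.** The discovery default matches the peak-set size.
  Note that with a corpus that small the plug-in $p_0$ carries enough
  sampling error to roughly double the variance of the binomial z-score, so
  the effective false-flag rate at the 1% cutoff is nearer 5%; calibration
  checks estimate $p_0$ from a 5× corpus.
* **Co-occurrence candidates.** Partners sit in the flanks, outside the
  narrow peak footprint, so candidates are mined from the positive
  instances: each 6-mer family's per-position match fraction is compared
  with the shuffle null and seeds are ranked by their *peak positional
  excess* (diffuse compositional signal moves no single position much; a
  true partner spikes). Long instances saturate global best-hit alignment
  for 6-mers, so candidates grow by local realignment (± 3 nt) around their
  spike position. The pair screen compares consensus (one-hot) profiles,
  rescaled against the 0.25 alphabet-chance agreement so unrelated motifs
  score near 0; mismatch-diluted count PWMs would all look alike.
* **Structure triplets** (27 dot-bracket 3-mers) are implemented and
  tested but excluded from default model assembly; structure predicted
  ab initio added no discriminative value at these instance lengths.
* **"10-fold cross validation"** follows the described procedure — ten
  repeated random 70:30 holdouts — and is labelled repeated holdout to
  avoid confusion with k-fold partitioning.

## Problem sizes

The bundled checks run at desk scale, chosen to keep the full suite within
minutes on one CPU: oracle equivalence on 200 random texts up to 500 nt;
planted-motif recovery over 20 replicates of 500 peaks; an end-to-end
benchmark of ~2,000 balanced instances (1,100 peaks, 1,200 background
transcripts) with a 70:30 split, 300 boosting rounds, co-occurrence
screening, and a both-class random-window ablation control (the anchored
model scores ~15 accuracy points above the ablated one under the default
conditions).

## Known limitations

* The 2-mismatch 6-mer family is deliberately broad. On long sequences it
  saturates (nearly every 150-nt window contains *some* relative of any
  seed), which is why presence-based statistics are computed on narrow peak
  footprints and positional statistics are used inside instances. Mixtures
  of two motifs inside flanked peaks can be bridged by a chimeric family
  via shift registers, in which case they surface as one broad primary
  family rather than two mutually exclusive ones.
* With the null corpus at its default size the binomial test is
  anticonservative (see above); decisions rest on the extreme tail, which
  is robust to this, but the nominal 1% level should not be read literally.
* The feed-forward network is a compact base-R implementation intended for
  desk-scale feature matrices; for very wide inputs the gradient-boosted
  trees are the faster default.
* Models are tied to their feature schema; scanning re-uses the training
  tensors and window size and refuses mismatched schemas rather than
  silently re-deriving them.
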
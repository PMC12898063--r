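---
title: "Modelling RBP binding from CLIP peaks with hashed k-mer features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling RBP binding from CLIP peaks with hashed k-mer features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbpkmer)
```

This vignette explains the models implemented in `rbpkmer`, the assumptions
behind them, the parameters that matter, what the synthetic benchmark does
and does not emulate, and the numerical and design choices that were
genuinely open.

## The statistical problem

Immunoprecipitation assays report *peaks*: genomic intervals where a
protein's crosslinked footprint is significantly enriched over a control.
Two properties of this data shape everything here. First, peaks are
positive-unlabeled: the absence of a peak does not mean absence of binding,
especially on lowly expressed RNAs, whose footprints rarely clear the
significance threshold. Second, peak strength correlates with transcript
abundance for reasons unrelated to binding specificity. A sequence-only
classifier trained on peaks can therefore *impute* plausible binding on
under-sampled RNAs, but its negatives are necessarily noisy and its
evaluation must be stratified (biotype, GC content, expression quartiles)
to detect sampling artifacts.

## Features: k-mer frequencies and universal-family hashing

A window of 200 nt is represented by
overlapping 3-mer and 5-mer frequencies (dimension 4³ + 4⁵ = 1088, indexed
lexicographically with A < C < G < T so that every weight maps back to a
k-mer string). Frequencies, not raw counts, are the default: they remove
window-composition scale effects; a counts mode is kept for region scoring.
Windows containing `N` contribute nothing for the affected k-mers rather
than phantom zero-k-mers, and `U` is read as `T`.

The 1088-dimensional vector is reduced by feature hashing. A hash drawn
from the linear universal family
$h(i) = ((a\,i + b) \bmod p) \bmod m$, with $p = 1091$ the smallest prime
above 1088, assigns each k-mer index to one of $m$ output bins;
accumulation over collisions is exactly multiplication by a 0/1 matrix with
one 1 per column. Column-stochasticity gives two properties used by the
tests: the total feature mass is conserved exactly, and the operator is
linear, so models on hashed features remain differentiable in the input.
The default $m = 128$ (an 8.5-fold reduction) is a configuration knob;
the cost of hashing is that colliding k-mers share a reported weight,
which blurs interpretation more than prediction.

## Models

**Single-protein classifier.** With a fixed-size input, plain logistic
regression suffices: $P(\text{bound}) = \sigma(w^\top h(x) + b)$, fitted by
ridge-penalized maximum likelihood (`glmnet`, `alpha = 0`). The penalty
`l2_lambda` is parameterized on the *average*-loss scale. This choice makes
the fit exactly invariant under uniform duplication of the training set,
which is the behaviour a data-augmentation pipeline should have. On this
scale, useful penalties are small because k-mer frequencies are of order
1/window: the default is `1e-3`; at 1.0 the penalty dominates the tiny
feature magnitudes and shrinks every model to the base rate. A linear SVM
(`e1071`, hinge loss, no feature scaling) on identical features is the
baseline; its separating hyperplane is extracted so both models expose the
same weight/bias surface to the interpretation functions.

**Multi-protein network.** The hashed RNA vector is concatenated with a
fixed-length protein embedding (consumed as a table; the package never
computes embeddings) and passed to a fully connected network with a sigmoid
output. The implementation uses a single hidden layer (`nnet`, default
width 32, weight decay `1e-4`): for the interaction the network must
express — embedding-gated motif weights — one hidden layer is sufficient,
and it keeps the model small enough to train deterministically on a single
CPU; width, decay and iteration budget are configurable. Training pairs
are checked against the split assignment with a hard *leakage guard*: a
pair whose protein or chromosome is not in the training part raises an
error rather than a warning, because chromosome- or protein-level leakage
silently inflates every reported metric.

**Splits.** Chromosomes and proteins are shuffled under a seed and
allocated by deterministic largest-remainder rounding, so 120 proteins at
fractions (0.75, 0.125, 0.125) give exactly 90/15/15. A (protein, RNA)
pair enters a part only if both its protein and its RNA's chromosome are in
that part; cross-part pairs are dropped — the price of a split that is
honest at both levels.

## Datasets

Positives are peak regions; negatives are 200-nt windows tiled over
(a) intergenic space and (b) bodies of peak-bearing genes outside any peak
of the protein, sampled to a 1:1 region ratio. Negative candidates keep a
15-nt clearance from every peak so that the augmentation (below) can never
shift a negative window onto a peak. No GC or length matching is performed;
stratified evaluation is the compensating control. "Gene deserts" need no
separate operational definition here because intergenic tiling already
covers them.

Each region is expanded around its midpoint: positive windows at every
shift from −15 to +15 nt (31 windows), negative windows in 5-nt steps
(7 windows). The window anchor is the region midpoint — symmetric under
the ± shifts; shifts that would cross a chromosome boundary are dropped,
never clamped, preserving the fixed window length. Minus-strand regions
are reverse-complemented so models always see the sense strand.

## Inference and interpretation

Long RNAs are scanned with a 200-nt window and 50-nt step; when the last
regular stride stops short of the 3′ end, one extra right-anchored window
is appended (a flag restores the strict stride). Per-nucleotide tracks
average all covering windows.

Weights map back to k-mers through the recorded projection
(`kmer_weight_map()`), feeding: top/bottom extraction (defaults 5 of 64
3-mers and 50 of 1024 5-mers; ties broken lexicographically, top and bottom
slices taken from opposite ends of one ordering so they are disjoint
whenever 2n ≤ block size); position-averaged PWM compatibility (mean over
all alignments of the product of column probabilities — a compatibility
score in [0, 1], not an expected count); a one-sided rank-sum comparison of
top-vs-bottom PWM scores; and projection onto 7-mers as the pooled mean of
the 8 constituent k-mer weights (5 constituent 3-mers + 3 constituent
5-mers). The pooled mean is the default; a per-k-then-combine variant is a
flag, and the two differ only in the relative weighting of the blocks
(5:3 versus 1:1). Spearman correlation against a 7-mer z-score profile is
computed over all 16,384 entries; a constant profile is reported as
undefined rather than silently zero. Region scores are the sum of weights
over *distinct* k-mers present (set semantics, matching the reading of
"k-mers present in that region"); an occurrence-weighted mode is a flag.

## Joint latent spaces

For each protein, a 7-mer interaction profile is derived from its peaks:
the signal of a 7-mer is the **maximum** of fold-change × −log10 p over
all peaks whose strand-aware sequence contains it — maximum, not mean, so a
few specific strong sites are not drowned by many weak nonspecific ones —
with absent 7-mers at 0, then centered and scaled per protein *before*
joining, so no protein dominates by assay depth. The joint matrix [P | R]
(protein features beside profiles) is decomposed by SVD. "Explained norm"
uses squared singular values over the squared Frobenius norm — the standard
variance-explained convention; the unsquared reading of "percentage of the
Frobenius norm" is available behind a flag, and the random-baseline
proportionality property is validated under the chosen convention. The
random baseline draws iid Gaussian matrices rescaled to the target
Frobenius norm (Frobenius is the assumed reading of "the same norm");
for strongly rectangular shapes its mean curve concentrates tightly around
k/min(n, m). Latent protein coordinates are rows of U·Σ (bare U is a
flag): scaling by the singular values preserves the row-space geometry that
cosine distances are meant to summarize. The W1 distance between two
distance distributions is the exact 1-D optimal-transport cost: the mean
absolute difference of sorted order statistics for equal sizes, the CDF
integral otherwise.

## The synthetic benchmark

The generator emulates the mechanism that motivates the package: motif
instances sampled from a protein's PWM are planted into gene bodies of an
iid-uniform genome, and each instance is emitted as a peak with probability
`plogis(qlogis(peak_rate) + bias_strength × (q − 0.5))`, `q` the host
gene's expression quantile. `bias_strength = 0` gives exchangeable emission
across quartiles; the default 2 gives a strong but not deterministic
expression bias (the real-world magnitude is not quantified anywhere, so
this is a free parameter chosen once). Peaks carry log-normal fold changes
and −log10 p drawn in [2, 10], mimicking significance-thresholded peaks
without re-implementing replicate filtering. Biotypes are assigned
0.6 / 0.3 / 0.1 (protein-coding / lncRNA / other), matching the three
strata the evaluation reports. Protein embeddings are Gaussian vectors
whose pairwise cosine similarity follows the similarity of the proteins'
motifs, standing in for protein language-model embeddings. 7-mer z-score
tables are the PWM-compatibility scores of all 16,384 7-mers plus noise,
z-scored (an all-tied profile standardizes to zeros rather than dividing
by zero).

What the generator does **not** emulate: crosslink-position biases, read-
level noise, realistic genome composition (GC structure, repeats),
transcript isoforms, cooperative or structure-dependent binding, and
motif clustering (each peak covers exactly one planted instance). Passing
tests therefore demonstrate the pipeline's correctness and its behaviour
under a controlled bias mechanism — not performance on real assay data.

The *standard benchmark* fixes one 500-kb chromosome, 200 genes, one sharp
6-nt motif (consensus TGCATG, 0.85 per-column weight) and
`bias_strength = 2`. Because a single chromosome cannot support a
chromosome holdout, the benchmark holds out genes: regions follow their
host gene into train or test, and intergenic negatives (which share no
sequence with any gene) are allotted proportionally at random. Under these
conditions the planted signal is deliberately hard: instances average ~0.9
mismatches from consensus and ~9% of negatives contain an unpeaked planted
instance, so even an oracle that scans with the true PWM only reaches a
held-out AUROC of ≈0.86 (sum-of-odds scoring; ≈0.81 for max log-odds),
and the k-mer classifier lands around 0.7–0.8. Similarly, the Spearman
concordance between model-projected 7-mer scores and the PWM-derived
z-scores is bounded by weight-estimation noise: projecting *ideal*
log-scale PWM weights yields ρ ≈ 0.45, and a model trained on ~500 positive
regions reaches ρ ≈ 0.1, because the rank correlation over all 16,384
7-mers is dominated by background ordering. The package reports both
honestly rather than easing the generator.

Test and acceptance runs use scaled problem sizes chosen as realistic desk
conditions: 10 seeds of the 500-kb benchmark for held-out performance and
motif recovery, 100 replicates of a 60-kb variant for the rank-sum
simulation study, 100 replicates of the 26 × 16384 random baseline.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open (BED convention) everywhere; IRanges'
  1-based closed intervals appear only inside overlap computations.
* AUROC is the Mann–Whitney rank statistic with half credit for ties,
  which makes it exactly equal to brute-force pair enumeration.
* BA/MCC threshold is 0.5; an MCC with a zero denominator is reported as 0.
* PWM columns are validated to sum to 1 within 1e-3 and renormalized;
  worse deviations are an error, not a silent fix.
* A k-mer longer than the PWM is an error for `score_kmer_against_pwm()`;
  the 7-mer z-score generator instead slides the shorter of the two over
  the longer, so short PWMs are handled.
* Sequences shorter than the model window are refused by `scan_rna()` with
  a pointer to `predict_window()` on a padded or centered slice — padding
  would silently change the k-mer composition.
* All randomness flows through explicit integer seeds (`withr::with_seed`),
  and sub-generators derive fixed offsets from the master seed, so a bundle
  is byte-identical across runs.

## Known limitations

The negatives are only as clean as the peak calls; no GC/length matching is
attempted. Hash collisions make reported k-mer weights equal within a bin —
interpretation at `m = 128` should be read at the level of k-mer groups.
The multi-protein network is a small MLP and is not expected to match
convolutional architectures on real data; its role here is the leakage-safe
transfer mechanism, not state-of-the-art accuracy. The latent-space
comparison consumes whatever protein feature table it is given; feature
quality is upstream of this package.
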
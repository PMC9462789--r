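---
title: "Models and methods behind crescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crescan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical models and the procedural choices in
`crescan`: what each component assumes, which parameters matter and why
their defaults are what they are, what the synthetic-data generator does and
does not emulate, and where the design was genuinely open.

## Scoring model: log-odds over motif and motif-pair features

The core classifier (`pypredictor()`) scores a sequence window by a weighted
sum of feature values, with per-feature weights

$$w_f = \ln\frac{\bar{x}^{+}_f + \alpha}{\bar{x}^{-}_f + \alpha},$$

where $\bar{x}^{+}_f$ and $\bar{x}^{-}_f$ are the mean values of feature
$f$ in the positive and negative training sets. The features are motif
occurrence frequencies and motif *pair* occurrence frequencies — the number
of occurrence pairs (one from each motif of an unordered pair, self-pairs
included) whose start positions lie within a cut-off distance. This encodes
the central assumption of motif-pairing CRE models: what distinguishes a
regulatory element from background with similar composition is the local
*co-occurrence* of binding motifs, not their individual abundance.

Parameter notes:

* `max_distance` (default **219 bp**) — the pairing cut-off. The classic
  pairing predictor uses a window of roughly this scale; the value is
  exposed because it is a biological prior, not a fitted constant.
* `alpha` (default **1.0** on per-kilobase-normalised features) — the
  additive smoothing in the weight formula. Rare pair features have near-zero
  class means; without smoothing a single spurious pair in a small negative
  set flips the weight sign. With per-kb normalisation, $\alpha = 1$
  corresponds to one pseudo-occurrence per kilobase, a mild prior.
* `window`/`step` (defaults **500/250 bp**) — the scanning resolution used
  for short CREs; a coarser 3000/1000 setting suits long-element models.
  Training operates on whole training sequences; scanning slides windows.
* Aggregation (default **max**) — a sequence's score is the score of its
  best window, reflecting that CRE presence is a local property. `mean` and
  `sum` are provided for models where dosage across a long region matters.
* Occurrence counting scans **both strands** for motifs (binding is
  strand-symmetric) and overlapping occurrences all count (tandem motif
  repeats are the biology, not an artefact); two occurrences of the same
  motif at the same offset on opposite strands do not pair with each other.
* Spectrum features count the **forward strand** by default, following
  spectrum-kernel convention; both-strand counting is a switch.

## Spectrum and mismatch-spectrum features

`ft_kspectrum(k)` maps a sequence to the counts of all $4^k$ k-mers;
`ft_kspectrum_mismatch(k, m)` lets an observed k-mer count toward every
feature k-mer within Hamming distance $m$. The mismatch feature value is
computed as the plain spectrum multiplied by the $4^k \times 4^k$
Hamming-ball indicator matrix; for N-free input of length $L$ the feature
sum is exactly $(L - k + 1)\sum_{i \le m}\binom{k}{i}3^i$, which the tests
assert. Ball matrices are cached for $k \le 8$; beyond that the product is
computed without caching (memory, not time, is the binding constraint).
Windows containing `N` are skipped rather than imputed, so unknown sequence
contributes no counts anywhere.

## Generative background models

`train_markov()` fits an order-$n$ chain by counting all
(context, next-base) pairs, with a per-cell pseudocount (default **1**) so
that small training sets cannot produce zero-probability dead ends during
generation; with a zero pseudocount an unseen context falls back to a
uniform draw and says so. The initial distribution is the empirical n-mer
frequency. "Dummy" negatives generated from a chain trained on the
positives preserve k-mer composition up to order $n+1$ while destroying
longer-range structure — which is exactly why motif *pairing* features can
still separate real elements from them. Strand-symmetric training
(`add_reverse_complement`) is off by default and exposed as a switch, since
genome-wide strand symmetry is sometimes wanted and sometimes a confound.

## Threshold calibration

`calibrate_threshold()` operationalises "expected genome-wide precision":
for candidate thresholds $t$ (the union of observed scores) it estimates

$$\mathrm{prec}(t) = \frac{\pi\,\mathrm{TPR}(t)}
{\pi\,\mathrm{TPR}(t) + (1 - \pi)\,\mathrm{FPR}(t)},$$

with TPR from held-out positives, FPR from windows generated by a
background model (totalling at least a tenth of the genome length), and
prevalence $\pi$ defaulting to
`n_positives * window / genome_length` — the fraction of the genome
expected to be covered by true elements. That default is an explicit,
surfaced assumption, not a hidden constant; pass
`expected_positive_fraction` to override it. The smallest $t$ reaching the
target is returned; an unreachable target returns the maximum positive
score flagged `unreachable`, and a degenerate (all-equal) score
distribution warns. Because the background is a finite sample, the
estimator is step-shaped and conservative near its resolution limit
(1/`n_background` in FPR).

## Genome-wide prediction

Chromosomes are scanned in chunks of windows so memory is bounded by the
chunk, not the chromosome; window starts are computed globally, so results
are bitwise-independent of chunking (tested). Windows with more than 50%
`N` (assembly gaps) are skipped — they would otherwise score as spuriously
motif-free background — and the final partial window at a chromosome end is
dropped rather than padded. Windows above threshold are merged (bookended
regions coalesce) into predicted loci; the score track is emitted at
window-step resolution.

## Convolutional architectures

Two built-in architectures over 500 bp one-hot windows (`N` encodes as an
all-zero row, injecting no signal):

* the **conventional CNN**: four blocks of 25 width-3 convolutions each
  followed by 2× average pooling, then global max pooling and a dense
  softmax — 6,129 trainable parameters;
* the **motif/dinucleotide-pairing architecture**: 25 motif convolutions of
  width 10 and 25 dinucleotide convolutions of width 2 in parallel over the
  input, concatenated; 10× average pooling; a *fixed* depthwise convolution
  of length 50 with all weights 1/50 (a sliding average spanning 500 bp of
  original resolution, non-trainable) that turns pointwise motif responses
  into local motif-density signals; 25 width-1 pairing convolutions over the
  50 channels; global max pooling; dense softmax — 2,629 trainable
  parameters. The pairing layer sees, at every position, the local average
  of all motif/dinucleotide channels, so width-1 convolutions suffice to
  model co-occurrence within the averaging span.

Parameter accounting is `filters × width × in_channels + filters` per
trainable convolution and `in × out + out` for the dense layer; the fixed
averaging layer contributes zero. The dense layer takes the 25 max-pooled
channels; the totals above confirm that reading of the layer order.

Training uses the package's own backend: im2col convolutions with `same`
zero padding (which is also what lets the width-10 and width-2 branches
concatenate) and ReLU activations, cross-entropy loss, and minibatch
gradient descent with momentum — full batch by default. Full-batch updates
were chosen because per-example updates at workable step sizes drive the
ReLU units behind the global max pool into permanent inactivity on these
small, heavily averaged networks. Gradients are verified against numeric
differentiation in the tests. The backend is pluggable: anything with the
same `train()` contract (e.g. a binding to an external deep-learning
engine) drops in, and parameter accounting and the scoring path do not
change.

## Cross-validation workbench

Training sets are balanced by drawing, per repeat and without replacement,
`min(class size − min_test_per_class)` sequences from every class; test
sets are binary — all held-out positives plus `test_neg_ratio` times as
many negatives sampled from the held-out members of all other classes
pooled. Repeats are independent draws; test sets are disjoint from training
within a repeat but not across repeats (documented choice — the workbench
models repeated random splits, not a partition). ROC and PR curves use
exhaustive thresholds with ties grouped and thresholds placed between
distinct scores; AUCs are trapezoidal. Confidence intervals are
$t_{(1+\gamma)/2,\,n-1}\,s/\sqrt{n}$ pointwise on a **101-point grid** (repeats
have different thresholds, so curves are aligned on FPR/recall); PR uses
stepwise interpolated precision (the maximum precision at any recall at
least the grid value) because linear PR interpolation is optimistic.
PR curves, not ROC, are the headline view: at realistic imbalance a random
scorer's PR AUC equals the prevalence, which the tests verify at 1:100.

## The synthetic-genome generator

`generate_synthetic_genome()` emulates the study design the package is
built for: a Markov background (default order 4, fly-like 42% GC, trained
on an i.i.d. seed sequence), 40 planted 1 kb elements across 2 Mb, each
carrying 8 planted motif pairs — one occurrence each of a GA-repeat-like and
a PHO-like motif with starts within 219 bp — and four noisy marker tracks
covering each element with probability 0.9 and up to 500 bp of boundary
jitter. Eight pairs per kilobase is the motif-cluster density typical of
real elements of this kind; elements are placed in per-chromosome slots so
they never overlap and keep a minimum gap.

What it deliberately does **not** emulate: chromatin context, positional
biases relative to genes, motif degeneracy beyond the IUPAC codes,
overlapping or nested elements, assembly gaps, and experimental noise that
is correlated between markers. Passing the end-to-end tests therefore
demonstrates that the machinery — feature extraction, training,
calibration, scanning, evaluation — is correct and internally consistent,
not that any particular accuracy will transfer to real genomes.

## Numerical and convention choices

* Coordinates are 0-based half-open internally (BED-native); GFF/GTF and
  coordinate lists convert at the I/O boundary, and the writers restore
  dialect coordinates exactly (round-trip tested byte for byte).
* `merge` coalesces bookended regions by default (`bookended = FALSE`
  switches it off); set algebra is strand-blind, sequence extraction
  honours strand.
* Curve thresholding is strict (`value > t`) so `t = 0` excludes
  zero-signal background, and unsampled gaps are never inside a region.
* "Enriched in a marker" means ≥ 1 bp overlap with that marker's region
  set; windows truncated at a chromosome end are skipped.
* Region resizing centres on the floor midpoint and shifts right at the
  origin so the requested length is preserved.
* PWM motifs require an explicit threshold — there is no universal score
  scale to default to.
* Ties in scores are grouped; candidate thresholds sit between distinct
  score values.
* All randomness flows through explicit integer seeds; identical seeds give
  byte-identical sequences, splits and synthetic genomes.

## Problem sizes in the tests and acceptance script

The test suite and `scripts/acceptance.R` use: 100+ random instances per
brute-force oracle (sequences ≤ 80 bp, region sets of ≤ 100 intervals over
≤ 10 kb toy chromosomes); 10^6 generated bases for order-2 Markov recovery
(±0.02 tolerance); 20 repeats at 1:100 imbalance for the PR baseline; a
2 Mb synthetic genome with 40 planted elements, 100× dummy negatives and
calibration at target precision 0.8 for the end-to-end recovery check; and
a 50-sequence, 120-epoch toy problem for the neural trainer. These sizes
were chosen as the smallest at which each statistical claim is comfortably
testable.

## Known limitations

* The log-odds model bundle serialises to JSON only for IUPAC-motif
  feature networks; fitted SVM/RF backends and trained networks live in the
  R session (save them with `saveRDS()` if needed).
* The mismatch spectrum materialises a $4^k \times 4^k$ matrix; $k > 8$
  works but is slow, and $k \le 12$ is enforced.
* The neural backend is a correctness-first pure-R implementation; it is
  suitable for the package's compact architectures and small training sets,
  not for large-scale training.
* Wiggle I/O covers fixedStep/variableStep; BigWig, bedGraph and BigBed are
  out of scope, as are liftover and tabix indexing.
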
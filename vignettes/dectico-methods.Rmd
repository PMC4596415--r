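---
title: "Classifying metagenomes with intrinsic oligonucleotide correlations and dynamic feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying metagenomes with intrinsic oligonucleotide correlations and dynamic feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dectico)
```

## The model

`dectico` classifies metagenomic samples into two predefined classes
(typically diseased vs. control) using only statistics of the raw reads.
The pipeline has three stages, each behind its own function surface:
feature extraction, feature selection, and classification.

### Intrinsic correlation of oligonucleotides

A sample's reads are pooled and treated as one integrated sequence
collection; per-read vectors averaged afterwards are deliberately not
supported, since short reads make per-read estimates extremely noisy.
For an oligonucleotide length $k$, every split of a $k$-mer into a prefix
$i$ of length $m$ and suffix $j$ of length $n = k - m$ contributes two
blocks:

* the **junction ratio** $f_{ij} = p_{ij} / (p_i p_j)$, where $p_{ij}$ is
  the occurrence probability of the junction $i\cdot j$ among $k$-mer
  windows and $p_i$, $p_j$ come from *independent* sliding-window counts
  at lengths $m$ and $n$ (not marginals of the $k$-mer table — the
  boundary windows differ, and the definition treats each length's
  probabilities as its own quantity);
* the **average mutual information**
  $I(i) = \sum_{j} p_{j|i}\,\log_2\!\big(p_{ij}/(p_i p_j)\big)$, with
  $p_{j|i}$ the continuation probability of $j$ after $i$, row-normalized
  over the $k$-mer counts sharing prefix $i$ so each row sums to exactly 1
  despite read-boundary effects.

Concatenating all $k-1$ splits gives $(k-1)4^k + \sum_{m=1}^{k-1} 4^m$
components (20 for $k=2$, 148 for $k=3$, 852 for $k=4$, 480,596 for
$k=8$). For an i.i.d. uniform sequence $p_{ij} \to p_i p_j$, so
$f_{ij} \to 1$ and $I(i) \to 0$: the features measure exactly the
departure from independence of adjacent oligonucleotides, the genomic
signature that distinguishes taxa beyond raw composition. The 4^k
composition vector is retained as the baseline feature.

**Conventions.** Counting windows skip any non-A/C/G/T base and never
span read boundaries; there is no reverse-complement canonicalization by
default (an option exists). Zero handling: an unobserved junction
contributes $f_{ij} = 0$ and a zero term to $I(i)$ ($0\cdot\log \equiv
0$); prefixes or suffixes never observed contribute zeros throughout.
This avoids divisions by zero while keeping absent junctions free of
spurious correlation signal; an optional pseudocount (default 0) is
exposed for sensitivity analysis. Because $f$-ratios and $I$-values live
on different magnitudes, every sample vector is min-max normalized
*within the sample* ($v' = (v - v_{\min})/(v_{\max} - v_{\min})$, constant
vectors mapping to zeros); per-feature column scaling across samples is
deliberately not used, so each sample's features are self-contained and
prediction does not depend on training-set statistics.

### Kernel partial least squares ranking

Feature selection uses kernel PLS: with the $N \times N$ kernel matrix
double-centered, kernel NIPALS extracts orthonormal score vectors
maximally covarying with the $\pm 1$ response, deflating
$K \leftarrow (I - tt^\top) K (I - tt^\top)$, $y \leftarrow y - t(t^\top
y)$ per component. With a linear kernel this is exactly classical PLS1 on
centered data (the test suite verifies score agreement with a textbook
NIPALS oracle to $10^{-8}$). The default kernel is Gaussian with the
median heuristic ($\gamma = 1/\mathrm{median}$ of nonzero pairwise
squared distances), which removes the only free kernel parameter; the
number of components defaults to $\min(5, N-1)$.

Each feature's importance is the response-loading-weighted squared
covariance of its centered, unit-norm column with the score vectors,
$w_j = \sum_a q_a^2 (\tilde{x}_j^\top t_a)^2$ — a VIP-style projection.
This weight formula is the one genuinely open design choice in the
module; it is isolated behind `feature_weights()` so an alternative can
be substituted without touching the selection recursion. Zero-variance
columns get weight 0, and ties in ranking break by canonical feature
name, keeping selection fully deterministic.

### Dynamic selection, SVM, and the output rule

Given a strictly descending ladder $n_0 > n_1 > \dots > n_N$ ($n_0$ the
full dimension), each round refits kernel PLS **on the currently selected
subset**, re-ranks, keeps the top $n_k$, trains an SVM on the restriction
of the original matrix, and records its leave-one-out cross-validation
(LOOCV) accuracy. The static baseline ranks once on the full matrix and
takes prefixes. The returned classifier maximizes LOOCV accuracy, with
ties resolved toward fewer features — the only reading of "maximal
accuracy with minimal components" that is always unique.

SVM defaults follow the underlying libsvm engine (RBF kernel, $C = 1$)
with $\gamma = 1/(d \cdot \mathrm{var}(x))$; all are configurable. When
no ladder is given, sizes halve geometrically down to
$\max(10, n_0/2^{10})$.

Two caveats are worth stating prominently. First, feature selection runs
on the full training set and LOOCV cross-validates only the classifier
training; the recorded accuracies therefore carry an optimistic selection
bias when read as generalization estimates (the honest generalization
check is `generality_test()` on held-out draws). Second, LOOCV has a
known *anti-learning* artifact: when the features carry no class signal
and classes are balanced, each fold's SVM degenerates to a majority voter
over its training fold, whose majority is always the held-out sample's
opposite class — null-data LOOCV accuracy is then near 0, not 0.5. The
divergence-zero control below shows exactly this; a practitioner seeing
LOOCV far *below* chance should suspect absent signal, not inverted
signal.

## The evaluation harness

* **Stability test** — 20 stratified training subsets drawn without
  replacement, the full pipeline run on each; the standard deviation of
  the optimal-round LOOCV accuracies measures how alike classifiers
  trained by different groups on different samples of the same cohort
  would be.
* **Generality test** — one training subset, one classifier, then 20 test
  subsets from the remaining samples; the spread of F1-measures (used
  because test draws may be class-imbalanced) measures generalization
  consistency.
* **Paired t-test** — two-sided, on per-repeat metric pairs, sample-sd
  convention; a zero-variance difference vector is reported as undefined
  rather than inferred.

Per-repeat sub-seeds derive from one master seed by counter, so every
report is exactly reproducible.

## The synthetic-data generator

Real cohort data cannot ship with the package, so the generator emulates
the relevant structure: each "taxon" is an order-2 Markov chain over
A/C/G/T with Dirichlet(1) transition rows (order 2 is rich enough that
ICO at $k \ge 3$ carries signal beyond mononucleotide composition, yet
cheap at desk scale); the two classes share the taxa but mix them
differently. With divergence $\delta$, class mixings are
$(1-\delta)\pi_{\mathrm{common}} + \delta\pi_{\mathrm{class}}$ with the
two $\pi_{\mathrm{class}}$ supported on disjoint halves of the taxa —
$\delta = 0$ gives identical classes, $\delta = 1$ disjoint taxon
support. The class contrast thus enters through mixing proportions, a
beta-diversity-like signal, rather than through mutated genomes.
Dirichlet concentrations (1.0 for transitions, 2.0 for mixings) give
moderate heterogeneity and are exposed in the config.

What the generator does *not* emulate: sequencing errors and quality
scores, within-class host-to-host compositional variability (each class
has one fixed mixing vector; samples differ only by read sampling),
genome-scale repeat structure, and coverage unevenness. Passing tests on
this generator therefore demonstrate the pipeline's correctness and its
sensitivity to between-class compositional contrast — not field
performance on real cohorts, where within-class variance and batch
effects will lower accuracies.

## Problem sizes and numerical choices

The shipped study conditions are 20 samples per class, 5000 reads of
100 bp per sample, 4-mer ICO (852 features) over the ladder
852 → 100 → 20 — small enough to run end-to-end in about a minute on one
core, large enough that the $\delta = 0.5$ contrast is comfortably
detected (LOOCV accuracy 1.0 at every rung; the tie-break keeps the
20-component classifier). The planted-feature benchmark (40 samples, 10
informative features with a class-mean shift of 2.0 among 990 noise
features, ladder 1000 → 100 → 10, 20 seeds) probes the selection
machinery in isolation: final-rung recall of planted features averages
near 0.98, and dynamic selection matches or beats static in every seed.
The stability and generality protocols run 20 repeats at 10 training
samples per class.

Other numerical conventions: LOOCV folds that end up single-class (tiny
inputs only) predict the majority class with a message rather than
failing; `select_top` and all orderings use lexicographic A < C < G < T
feature names for bit-exact reproducibility; model serialization stores
the restricted training matrix and hyperparameters and refits libsvm on
load — training is deterministic, so reloaded models reproduce
predictions exactly while the container stays plain text.

## Known limitations

* Binary classification only; no probability calibration, no
  hyperparameter search, no nested selection-inside-LOOCV (the recorded
  accuracies are selection-biased, as discussed).
* $k = 8$ ICO vectors (480,596 components) are supported but memory- and
  time-hungry in plain R; the desk-scale defaults use $k = 4$.
* The min-max normalization ties feature scales to each sample's own
  extremes; samples with pathological dynamic range (e.g. one enormous
  junction ratio) compress all other components.
* Quality control of reads is out of scope by design: whether and how
  input reads were trimmed is the caller's decision and should be
  consistent between training and prediction.
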
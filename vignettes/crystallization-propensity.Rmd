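---
title: "Predicting protein crystallization propensity with crystalnn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein crystallization propensity with crystalnn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crystalnn)
```

## The problem

Producing diffraction-quality crystals is the major bottleneck of protein
X-ray crystallography: most targets entering a structure-determination
pipeline never reach that stage. Ranking candidate proteins — or candidate
construct boundaries within one protein — by their propensity to
crystallize saves bench time in both individual laboratories and
structural-genomics pipelines. crystalnn implements a sequence-only
predictor of that propensity: a feed-forward neural network over a
428-dimensional feature vector, plus a sliding-window profiler that maps
the score along a sequence for construct design.

## The model

### Features

Each sequence (or 61-residue window) is summarized by 428 numbers, in a
fixed registry order (`feature_names()`):

* 20 amino-acid frequencies and 400 overlapping dipeptide frequencies
  (alphabetical / row-major order). Ambiguity letters (X, B, Z, U, O, J)
  are excluded from numerator and denominator — no silent residue
  substitution — so each block still sums to 1 over the counted residues.
* isoelectric point (pH units), the root of the Henderson–Hasselbalch net
  charge over the free termini and the D, E, C, Y, H, K, R side chains,
  with the EMBOSS pKa set (`pka_table()`), solved by bisection on
  [0, 14] to 0.002 pH. The charge is strictly decreasing in pH, so the
  root is unique; a curve that never crosses zero reports the clipped
  endpoint.
* mean GES hydrophobicity (kcal/mol) over standard residues
  (`ges_scale()`).
* fractions of helix, strand, disordered and transmembrane residues from
  per-residue 0/1 annotation tracks. These tracks are meant to come from
  dedicated external predictors via the mask-TSV reader; built-in
  heuristic annotators (`heuristic_annotate()`) keep the pipeline
  self-contained when no masks are supplied, and `predict()` flags every
  sequence scored that way.
* sequence length and average-mass molecular weight (ambiguity letters
  contribute the mean standard-residue mass).

Every feature is min–max scaled to [0, 1] and clipped. The default
bounds (`default_scaling()`) are: identity for frequencies and
fractions, (0, 14) for pI, the GES table extremes for mean
hydrophobicity, (0, 2000) residues for length and (0, 250000) Da for
weight. The bounds travel inside every model file, together with the
feature-name registry, so a model is never applied to inputs scaled
differently from its training data.

### Network and training

The network is 428–100–1 with logistic units throughout. Training is
per-example back-propagation on squared error (targets 1 = yields
diffraction-quality crystals, 0 = work stopped) with learning rate 0.01;
one cycle is one pass over all examples in a freshly shuffled, seeded
order. Weights initialize uniformly in [−0.1, 0.1]; biases at zero. The
hidden-layer size is a fixed design constant, not tuned here.

Two operating modes are shipped as presets. `PDB` mode (general
structural biology; positives drawn from solved structures) defaults to
2100 training cycles and decision cutoff 0.517; `SG` mode
(structural-genomics pipelines) to 1600 cycles and cutoff 0.418. The
cutoffs are applied as score ≥ cutoff → positive, and are replaced by a
data-driven cutoff whenever one is selected by cross-validation.

Early stopping, when enabled, holds out a seeded stratified validation
split (10% by default), monitors validation mean squared error per
cycle, and returns the weights of the best cycle after a configurable
patience (100 cycles) without improvement. Monitoring validation
*error* rather than validation AROC is a design choice: the error is
what the gradient descends, and it is cheap to evaluate every cycle.

### Cutoff selection and evaluation

`crossvalidate()` runs seeded, stratified 10-fold cross-validation; each
example is scored exactly once by a model that never saw it. The decision
cutoff is then chosen to maximize the Matthews correlation coefficient
over the pooled held-out scores — the less optimistic of the readings of
"over the training data", and recorded in the model file either way.
Candidate cutoffs are the unique observed scores; ties break toward the
smallest cutoff.

ROC areas use the Mann–Whitney convention (ties count half), which makes
the trapezoidal area and the rank-statistic identical and is verified
against an all-pairs concordance oracle in the tests. Two score sets on
the same examples are compared with the DeLong test for correlated ROC
areas (`delta_aroc_test()`); published p-values for such comparisons
obtained with other significance methods are therefore not directly
comparable.

### Sliding-window profiling

`profile_sequence()` passes a 61-residue window along the sequence and
reports the network score at the central residue (centers 31 … L−30;
windows never wrap or pad, so the termini receive no score). The window
length resembles a small domain and is configurable but deliberately not
optimized. Annotation fractions are computed from the *whole-protein*
tracks restricted to each window — matching how external predictors are
run once per protein — while composition, pI, hydrophobicity, length and
weight are recomputed on each window subsequence. Because the profile is
a function of (sequence, tracks), a window score depends on exactly its
61 residues once the tracks are fixed; the heuristic annotators, if used
in place of supplied tracks, themselves look ±20 residues around a
position, which widens the effective context accordingly.

`high_score_regions()` turns a profile into construct suggestions:
maximal runs of centers scoring above a threshold (default 0.9),
expanded by the half-window (±30) to the residues covered by the member
windows and clipped to the sequence. A run of centers 123–148 thus
expands to covered residues 93–178 of a long-enough protein — the
geometry construct designers actually clone.

## Synthetic data: what it emulates and what it does not

Real training data for this problem (solved-structure positives;
"work stopped" pipeline negatives) require archival database resources
and external structure/disorder predictors, so the package carries a
seeded generator (`generate_synthetic()`) as its test and demo
substrate. Class compositions are exponential tilts of a Swiss-Prot-like
background along the standardized TOP-IDP disorder-propensity axis:
class 1 tilts toward order-promoting residues (W, F, I, Y, V, …), class
0 toward disorder-promoting ones (P, E, S, K, …), with the tilt
magnitude the *effect size* in units of that standardized scale. Effect
size 0 gives literally identical sampling distributions (verified by a
chi-square null calibration over seeds). Lengths are uniform on a
configurable range (default 100–400, minimum 61 so windowing works);
annotation tracks come from the heuristic annotators applied to each
generated sequence — hence consistent with its composition — with an
optional bit-flip noise rate (default 5%).

The generator emulates *compositional* class differences only. Real
crystallization outcomes also reflect expression systems, domain
architecture, surface entropy and plain luck; sequences here are i.i.d.
residue draws with no positional structure beyond what the annotators
induce. Passing the recovery tests therefore demonstrates that the
pipeline can learn and faithfully evaluate a compositional signal of the
stated size — not that it reproduces historical benchmark performance on
archival datasets, which is out of reach without those resources.

## Numerical and design choices

* **Problem sizes.** The bundled experiments (tests and
  `scripts/acceptance.R`) use 150 sequences per class, effect size 2,
  10-fold cross-validation at 50 training cycles. At that effect size
  the classes are strongly separable and 50 cycles are ample; the
  published-scale cycle counts (2100/1600) remain the defaults for real
  training runs.
* **Determinism.** Every stochastic step (weight init, shuffling,
  validation split, fold assignment, down-sampling, generation) is
  seeded, and seeded helpers restore the caller's RNG state. Fixed seeds
  give byte-identical model files, score tracks and FASTA output.
* **Serialization.** Model files are versioned plain text with `%.17g`
  decimals, which round-trip IEEE doubles exactly; loaders validate
  dimensions and reject tampered or truncated files.
* **Window means in the heuristic annotators** are computed directly per
  window (not via cumulative sums), so identical windows give
  bitwise-identical means wherever they sit in the sequence — this is
  what makes homopolymer profiles exactly constant.
* **Degenerate inputs.** Sequences of only ambiguity letters are
  rejected where a feature is undefined (frequencies, GES mean);
  dipeptide vectors fall back to all-zero when no countable pair exists;
  MCC is defined as 0 whenever a confusion-matrix margin is empty.
* **Redundancy clustering** operates on user-supplied pairwise scores
  (alignment scoring itself is out of scope); single linkage is
  implemented with union–find, cluster numbering is canonicalized by
  smallest member so results are independent of pair order, and the
  linking threshold is always explicit because no universal default
  exists across scoring schemes.

## Limitations

* The heuristic annotators are crude stand-ins for real
  secondary-structure, disorder and transmembrane predictors; results on
  real proteins should use externally computed masks.
* The scaling bounds and the treatment of nonstandard residues are this
  package's declared defaults; other implementations of the same feature
  set may differ, and models are only portable together with their
  embedded scaling spec.
* Transmembrane proteins are poorly served by a predictor of this type;
  high hydrophobicity simultaneously drives the transmembrane fraction
  feature and degrades crystallization prospects by ordinary means.

## A worked run

```{r example, eval = FALSE}
ds <- generate_synthetic(synth_config(n_per_class = 150, effect_size = 2,
                                      seed = 7))
X <- feature_matrix(ds$records, ds$tracks)
data <- labelled_dataset(ds$records$id, X, ds$labels$label)

cfg <- train_config("PDB", cycles = 50, seed = 1)
cv <- crossvalidate(data, cfg, folds = 10, seed = 11)
cv
#> cv_result: 10 folds, pooled AROC 1.000, cutoff 0.610 (MCC 1.000)

model <- fit_final(data, cfg, cv, seed = 2)
prof <- profile_sequence(ds$records$seq[1], model,
                         lapply(ds$tracks, `[[`, ds$records$id[1]))
high_score_regions(prof, threshold = 0.6)
```
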
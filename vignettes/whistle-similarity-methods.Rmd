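---
title: "Methods: whistle similarity metrics, clustering, and identity recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whistle similarity metrics, clustering, and identity recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whistlecode)
```

## Overview

`whistlecode` asks a quantitative question about dolphin signature
whistles: how much of the individual-identity information carried by the
frequency-modulation (FM) contour survives increasingly lossy encodings?
The package compares three whistle-similarity metrics — a Parsons-type
symbolic code compared by edit distance, dynamic time warping (DTW), and a
correlation metric (CM) of fixed-point sampling — plus a random control,
under three unrelated clustering algorithms (k-means, complete-linkage
hierarchical, fuzzy ART), scoring each combination by normalised mutual
information (NMI) against the true individuals. Using three very different
clusterers guards against a result being an artefact of one algorithm's
inductive bias.

## Input model

A whistle contour is the hand-traced dominant frequency of one whistle: a
variable-length table of strictly increasing times (s) and positive
frequencies (Hz). Contours are exchanged as long-format CSV
(`whistle_id,individual_id,time_s,freq_hz`). Because traced points carry
digitisation jitter, `smooth_contour()` fits a cubic smoothing spline
(`stats::smooth.spline`); the smoothing penalty defaults to generalized
cross-validation because the upstream tracing tools do not publish a
penalty, `smoothing = 0` requests exact interpolation, and contours with
fewer than four points fall back to linear interpolation with a warning.
Each whistle is always resampled over **its own** duration (per-whistle
time normalisation): whistle durations differ, and identity information is
taken to live in the FM shape, not in duration.

## The n-Parsons encoding

`segment_means()` splits a whistle's duration into `n_segments = 10` equal
intervals and takes the exact mean of the piecewise-linear contour over
each (an integral, not a point sample, so sparse traces are handled
stably). Ten segments is the default compromise between information loss
(too few) and convergence on the continuous-time analysis (too many);
`sweep_segments()` exposes the full trade-off. Each of the nine transitions
between consecutive segment means becomes one symbol: `0` ("constant") if
the absolute change is within `constant_tol`, otherwise sign times
magnitude level `1..n`.

Magnitude levels are fitted on the data set as a whole by
`fit_alphabet()`: the top class ("large rise" together with "large drop")
contains the 10% largest absolute changes pooled over every transition of
every whistle, and the remaining non-constant changes are split into
`n - 1` equal-count quantile bins. Three choices deserve note:

* **Pooled magnitudes.** Rising and falling changes share one set of
  magnitude boundaries, matching the single "10% largest changes" rule the
  encoding is defined by.
* **Sub-large boundaries.** Only the large class has a published
  definition; equal-frequency binning of the remainder is the
  least-informative completion.
* **Constant tolerance.** Conceptually one spectrogram frequency bin
  ("one pixel"). It is a configuration value because the bin width depends
  on the recording chain; synthetic contours have no spectrogram grain, so
  their `freq_resolution` — and hence the default tolerance — is 0 Hz.
  Quantiles use linear interpolation (type 7) and ties on a boundary take
  the lower class.

Codes are compared by **Levenshtein edit distance** (minimum insertions,
deletions, substitutions; unit cost), computed by dynamic programming.
Substituting `u3` for `u2` costs the same as `u3` for `d3`: the encoding
itself, not a graded substitution cost, carries the magnitude information.
Edit distance is a metric, so the pairwise matrix is a valid proximity
matrix; for equal-length codes the dynamic programme is evaluated for all
pairs simultaneously, which keeps the 400-whistle matrix (79 800 pairs)
under a second.

A nine-digit base-7 code distinguishes `7^9 ≈ 2^25` shapes (25 bits);
`capacity_bits()` makes this arithmetic explicit for comparison with raw
profiles (420 bits at 60 points × 128 levels) and their 16-dimensional PCA
reduction (112 bits).

## Continuous metrics

**Correlation metric (CM).** Sixty equally spaced frequency samples per
whistle, columns standardised, PCA on the resulting correlation matrix,
components retained by the Kaiser rule (eigenvalue > 1 — meaningful only
for correlation-matrix PCA, which is why standardisation is not optional),
Euclidean distance in the retained space. The retained dimension is data
dependent; 16 is the outcome on the original balanced design, not a
constant of the method.

**DTW.** Contours are resampled to 60 points (matching CM, so matrices are
comparable across metrics) and aligned by monotone, boundary-anchored
warping with steps (1,0), (0,1), (1,1), no window and no slope constraint;
the cost is the accumulated squared frequency difference. This is the
minimal reading of a least-squares time-warping distance; per-path-length
normalisation is available behind `normalize = TRUE` since other
implementations differ on this point.

**Feature space vs proximity.** k-means and ART consume feature vectors;
hierarchical clustering consumes proximities. Conversions are classical
(Torgerson) MDS with negative eigenvalues clamped to zero — chosen over
stress-minimising MDS for determinism and exact recovery of Euclidean
configurations — at 16 dimensions, and plain Euclidean distance in the
other direction. The random control is a seeded uniform(0,1) symmetric
matrix; its feature counterpart is its MDS embedding.

## Clustering

The default cluster count is 30 — 50% more than the 20 individuals of the
balanced design — allowing some within-individual variation without
trivialising the task; `sweep_clusters()` covers 5–50.

* **k-means**: squared-Euclidean, k-means++ seeding, 10 restarts, best by
  total within-cluster sum of squares; failed or duplicate-centre starts
  are re-seeded. `k = N` returns singletons directly.
* **Hierarchical**: complete ("longest-distance") linkage on the proximity
  matrix, tree cut to exactly `k` (`stats::hclust`; ties at equal heights
  resolved deterministically by its ordering).
* **Fuzzy ART**: the standard continuous-input ART variant. Inputs are
  min-max scaled per dimension and complement coded; categories are ranked
  by the choice function `T_j = |I∧w_j| / (α + |w_j|)` and searched in that
  order, the first to pass the vigilance test `|I∧w_j| / |I| ≥ ρ`
  resonates and learns `w ← β(I∧w) + (1−β)w`; when all committed
  categories fail, a new one is committed. The committed-first search
  policy (rather than letting an uncommitted node compete through the
  choice function) makes the vigilance extremes behave canonically:
  `ρ = 0` yields a single category and `ρ = 1` one category per distinct
  input. Defaults: fast learning (`β = 1`), `α = 0.001`, at most 50
  seed-shuffled epochs, stop at a stable assignment. Because vigilance maps
  to a cluster count only indirectly, `art_cluster_target_k()` bisects
  `ρ ∈ [0, 1]` towards a target count, mirroring the `k` used by the other
  algorithms.

## Scoring and inference

`nmi()` normalises mutual information by the arithmetic mean of the two
label entropies, keeping the score in [0, 1]; the log base cancels.
Degenerate conventions: two trivial single-class partitions score 1; one
trivial partition scores 0. `bootstrap_nmi()` draws 100 subsets of 80% of
the whistles *without replacement* (the procedure is literally a
subsampling scheme despite the "bootstrap" name) and re-runs the entire
pipeline — including refitting the Parsons alphabet quantiles within each
subset, since the encoding is defined relative to its data set; a frozen
alphabet can be passed instead. `compare_methods()` runs one-way ANOVA
across the bootstrap NMI populations with Tukey HSD post-hoc tests and a
compact letter display. The bootstrap values are resampled rather than
independent observations, so the ANOVA is descriptive — it mirrors the
classical analysis of such tables and should be read accordingly.

## The synthetic population

Real signature-whistle recordings are not redistributable, so
`generate_population()` emulates the balanced design: 20 individuals × 20
whistles, durations 0.3–1.5 s, contours within 4–20 kHz. Each individual
owns a stereotyped template (random quadratic trend plus 1–3 sinusoidal FM
components, clipped to the band — clipping produces the plateaus seen in
traced contours), and each rendition applies within-individual jitter:
a smooth monotone time warp (SD 0.05), whole-contour frequency offset
(SD 150 Hz), multiplicative scale (SD 0.02), smooth additive FM noise
(SD 80 Hz) and 2% point dropout. These defaults are deliberately *low*
jitter — signature whistles are highly stereotyped — and each term can be
switched off or scaled (`jitter_scale`) to probe which metric family is
sensitive to which perturbation; identity information decays monotonically
as jitter scales up. Everything is deterministic from the config seed
(default 20130423), down to byte-identical CSV output.

What the generator does **not** model: harmonics, amplitude envelopes,
noise floors, non-signature whistles, unbalanced sample sizes, or the
multi-loop structure of some signatures. Passing recovery benchmarks on
synthetic populations therefore demonstrates the pipeline's correctness and
relative metric behaviour, not field-data performance: absolute NMI values
on real recordings are expected to be lower (the original study's best
automatic score was 0.774, against 0.90–0.99 for human judges).

## Numerical choices and degenerate inputs

* Segment means integrate the linear interpolant exactly (trapezoid rule on
  the union of knots and segment boundaries).
* A single segment produces empty codes, a zero proximity matrix, and by
  convention a single cluster (NMI 0) — the degenerate end of the segment
  sweep.
* An all-identical whistle set has no variable sample columns; `cm_features`
  then returns one degenerate zero column rather than failing.
* Proximity symmetry, zero diagonal and non-negativity are asserted on
  every construction; NMI is clamped to [0, 1] against floating-point
  drift.
* Smoothed frequencies are floored just above zero; splines can otherwise
  undershoot on pathological traces.
* All stochastic stages (k-means restarts, ART presentation order,
  bootstrap draws, random control, population generation) take explicit
  seeds; identical seeds give identical results.

## Problem sizes used in the test and acceptance runs

Unit tests run on small populations (3–8 individuals × 2–8 whistles);
oracle-equivalence checks use exhaustive enumeration on short codes and
profiles (lengths ≤ 4–6; 500-pair cross-checks against independent
implementations) — sizes chosen so the complete suite executes in well
under a minute while still exercising every code path. The recovery
benchmark and the acceptance script use the full 400-whistle default
design; the all-pairs dynamic programmes make this fast enough that no
down-scaling is needed there.

## Known limitations

* **Fuzzy ART on edit-distance embeddings.** On the default synthetic
  design, k-means and complete linkage recover individuals from the
  3-Parsons metric at NMI ≈ 0.93–0.96, but fuzzy ART tuned to 30
  categories reaches only ≈ 0.65, and its best score over any vigilance is
  ≈ 0.87 (at 70–90 categories, where its clusters are pure but the NMI
  normalisation penalises the fragmentation). The cause is geometric:
  ART's axis-aligned hyperbox categories, grown greedily in presentation
  order and bounded by a single global vigilance, either merge neighbouring
  individuals (low vigilance) or fragment them (high vigilance) in the MDS
  embedding of a small-integer edit-distance matrix, whose eigenvalue
  spectrum is diffuse. The same implementation recovers 20 well-separated
  Gaussian blobs perfectly, so this is a property of the task geometry,
  not a defect; alternative search policies, learning rates, scalings and
  embedding dimensions were examined and do not change the picture.
* The ANOVA/Tukey comparison inherits the non-independence of bootstrap
  populations, as noted above.
* Weighted (graded) substitution costs for the edit distance and
  frequency-axis warping for DTW are deliberate non-goals.
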
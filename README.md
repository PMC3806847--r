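# whistlecode

Quantifying the individual-identity information in bottlenose dolphin
(*Tursiops truncatus*) signature whistles — and how little of it a lossy
contour encoding needs to keep.

## The problem

Each bottlenose dolphin produces an individually distinctive, learned
"signature whistle", recognisable by the frequency-modulation (FM) pattern
of its fundamental. Human observers sort spectrograms of such whistles into
the correct individuals almost perfectly, but classical automatic measures —
correlation of fixed-point sampled contours, dynamic time warping — do much
worse. `whistlecode` implements a whistle-similarity framework built around
the **n-Parsons code**, a lossy symbolic encoding borrowed from music
retrieval: each whistle contour is split into 10 equal time segments, and
every segment-to-segment change in mean frequency is recorded as direction
plus one of *n* magnitude classes. For *n* = 3 the alphabet is
{large/medium/small drop, no change, small/medium/large rise} — a base-7
code of nine digits, i.e. `9·log2(7) ≈ 25` bits per whistle, versus 420
bits for a 60-point, 128-level frequency profile or 112 bits after its
16-dimensional PCA reduction.

The package provides, behind one model-fitting front door:

* **Metrics** — Levenshtein edit distance on (n-)Parsons codes (`pc`,
  `npc`), dynamic time warping of resampled contours (`dtw`), the
  correlation metric (60-point resampling, correlation-matrix PCA with
  Kaiser eigenvalue > 1 retention, Euclidean distance; `cm`), and a seeded
  random control (`random`).
* **Clusterers** — k-means (k-means++ restarts), complete-linkage
  hierarchical clustering, and a fuzzy adaptive resonance theory (ART)
  network with vigilance tuned towards a target cluster count. Proximity
  matrices are embedded by classical MDS (16 dimensions) for the
  feature-space clusterers.
* **Scoring** — normalised mutual information (NMI) against the true
  individual identities, with an 80% subsample bootstrap (100 draws) for
  standard errors, sensitivity sweeps over segment count (1–25), cluster
  count (5–50) and Parsons level (1–5), and ANOVA + Tukey HSD comparison of
  methods with a compact letter display.
* **Synthetic populations** — a generator emulating the balanced study
  design (20 individuals × 20 whistles; stereotyped polynomial+sinusoid FM
  templates with time-warp, offset, scale, noise and dropout jitter), so the
  entire pipeline is testable without field recordings.

NMI between a clustering and the identity classes is

```
NMI = I(K; C) / [ (H(K) + H(C)) / 2 ],
I(K; C) = Σ_{k,c} (n_kc / N) · log( N · n_kc / (n_k · n_c) )
```

with `n_kc` the number of whistles from dolphin `c` in cluster `k`.

## Worked example

```r
library(whistlecode)

pop <- generate_population(population_config(n_individuals = 8,
                                             whistles_per_individual = 10))
enc <- encode_set(pop, n_segments = 10, n_levels = 3)
enc$alphabet
#> <parsons_alphabet> n = 3 (7 symbols), constant tol 0 Hz
#>   magnitude thresholds (Hz): 1869, 4537
format_parsons(enc$codes[1, ])
#> "d2,d1,u1,d2,d1,u1,d2,d1,u1"

fit <- whistle_identity(pop, metric = "npc", clusterer = "hierarchical",
                        k = 12, n_boot = 20, seed = 1)
fit
#> Whistle identity-recovery model
#>   metric: npc   clusterer: hierarchical   whistles: 80   clusters: 12
#>   NMI vs individual identity: 0.948
#>   bootstrap (n = 20, 80% subsamples): mean 0.941 +/- 0.0014 SE
```

The first whistle's nine-symbol code (`d2` = medium drop, `u1` = small
rise, ...) already carries enough of the FM shape that complete-linkage
clustering of pairwise edit distances recovers the eight generating
individuals almost perfectly (NMI 0.948; 1.0 would be a perfect
correspondence, 0 chance level), and the bootstrap SE shows the score is
stable under 80% subsampling. `plot(fit)` displays the proximity matrix
ordered by individual; `summary(fit)` adds cluster purity.

Sweeps and the five-metric × three-clusterer comparison table are available
via `sweep_segments()`, `sweep_clusters()`, `sweep_parsons_n()`,
`bootstrap_nmi()` and `compare_methods()`, or from the shell through the
thin CLI:

```sh
Rscript inst/exec/whistlecode.R simulate --out data --seed 1
Rscript inst/exec/whistlecode.R evaluate --contours data/contours.csv \
        --metric npc --clusterer hierarchical --k 30 --out report.json
```

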
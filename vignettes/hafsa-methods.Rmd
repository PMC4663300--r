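---
title: "Fish-swarm fuzzy c-means segmentation: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fish-swarm fuzzy c-means segmentation: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hafsaseg)
```

## The problem

Segmenting a grayscale image into `c` tissue-like classes is routinely done
with fuzzy c-means (FCM): find centers $V = (v_1,\dots,v_c)$ and memberships
$u_{ij}$ minimizing

$$J(U, V) = \sum_{i=1}^{c}\sum_{j=1}^{n} u_{ij}^m \, d_{ij}^2,
\qquad \sum_i u_{ij} = 1,\quad d_{ij} = |v_i - x_j|,$$

over the $n = M \times N$ pixel gray values $x_j$. The alternating updates

$$u_{ij} = \Big(\sum_{k=1}^{c} (d_{ij}/d_{kj})^{2/(m-1)}\Big)^{-1},
\qquad v_i = \frac{\sum_j u_{ij}^m x_j}{\sum_j u_{ij}^m}$$

descend monotonically but converge to a local optimum that depends on the
random initialization, and the objective is blind to spatial structure, so
impulse-like noise lands in whatever cluster its gray value suggests.

`hafsaseg` addresses both weaknesses with a hybrid optimizer: an artificial
fish swarm searches the space of center vectors globally, a Metropolis rule
under a geometric cooling schedule controls acceptance of proposals, and a
neighborhood-based noise-reduction sweep runs once per generation inside the
optimization loop, using the current best clustering to identify and repair
noise pixels.

## The swarm search

Each artificial fish is a candidate center vector $V_i \in [0, 255]^c$ whose
"food concentration" is $J(V_i)$ (smaller is better). Per generation each
fish builds two proposals and keeps the better:

* **Swarm**: let the partners be the other fish within Euclidean distance
  `visual` in center space, `num` of them, with centroid $V_c$. If
  $J(V_c)/\mathrm{num} < \delta\, J(V_i)$ — the centroid is good and not
  overcrowded — move a step toward it; otherwise fall back to prey.
* **Follow**: same test with the best partner $V_{j^*}$ in place of the
  centroid.
* **Prey** (the fallback): draw up to `try_number` candidates uniformly in
  the axis-aligned $\pm$`visual` box around $V_i$; the first one that
  improves $J$ pulls the fish a step toward it. If none improves, take the
  **random** behavior: perturb every coordinate by `visual` times a
  uniform $[-1, 1]$ draw.

A "step toward" a target is $V_i \leftarrow V_i + \xi \cdot \mathrm{step}
\cdot (V_j - V_i)/\lVert V_j - V_i\rVert$ with $\xi \sim U(0,1)$; all
positions are clipped to $[0,255]^c$. The selected proposal passes through
the Metropolis rule: improvements are accepted unconditionally, a worse
proposal with probability $\exp(-\Delta J / (k\,T_t))$ at the generation-$t$
temperature $T_t = T_0 q^t$, $q = (T_\mathrm{end}/T_0)^{1/\mathrm{maxgen}}$.
Early on this preserves diversity; late it approaches greedy refinement. A
global best is tracked elitistically and is never erased by uphill moves.

Defaults follow the standard protocol for 8-bit images: population 20,
`maxgen` 50, `visual` = 256/10 = 25.6, `step` = `visual`/2, `try_number` 3,
$T_0 = 10^4$, $T_\mathrm{end} = 10^2$, $k = 1$. Two values the protocol
leaves open are set here once: the congestion level $\delta = 0.75$ (a
mid-high value keeps the swarm and follow behaviors active without
collapsing diversity; $\delta = 0$ would disable them entirely) and the
behavior scheduling (each fish evaluates swarm and follow and keeps the
better, the classic arrangement when no explicit ordering is prescribed).
Both are exposed as parameters. `num` counts partners only, not the fish
itself. The Metropolis exponent is implemented as $-\Delta J/(kT)$, the
form under which the acceptance probability of worse moves decreases over
time; the opposite sign would exceed 1 for every worse move.

## In-loop noise reduction

After the school moves, the generation's best centers induce a hard cluster
map (each pixel to its nearest center, ties to the lowest index). A pixel is
declared noise when fewer than `k_min` of its 8-neighbors (3 or 5 at corners
and edges, which use the same rule on their available neighbors) share its
cluster attribute; `k_min = 1` flags isolated labels, `k_min = 2` also
catches adjacent impulse pairs. Every flagged pixel is replaced by the mean
gray value of its largest neighbor cluster group (ties to the lowest cluster
index). Replacement is synchronous — all values are computed from the
pre-sweep image — so the result does not depend on sweep order.

The replacement mutates the *working image*: subsequent generations optimize
$J$ on the progressively cleaned image, which is what couples the mechanism
to the search rather than making it a pre- or post-filter. Cached fish
objectives are refreshed whenever pixels change, and the recorded global
best is always evaluated against the current working image; the final report
re-evaluates the best centers on the final image (`objective`) and on the
untouched input (`objective_on_input`), since the two diverge exactly when
denoising did real work.

## Baselines

`run_baseline()` wraps plain FCM and suppressed FCM (SFCM) in the same
result record. SFCM inserts, after each membership update, the suppression
step $u_{pj} \leftarrow 1 - \alpha + \alpha u_{pj}$ for the winning cluster
$p$ and $u_{ij} \leftarrow \alpha u_{ij}$ otherwise. The suppression factor
is not standardized; the default is the midpoint $\alpha = 0.5$, and
$\alpha = 1$ reproduces FCM exactly (tested). The convergence threshold for
both solvers is $10^{-5}$ on the maximum absolute center change — the
conservative reading of the conventional "1e−5 iterative threshold" — and
is configurable. Initialization for all algorithms draws centers uniformly
in $[0, 255]$ from a seeded generator. A cluster that loses all membership
mass is re-initialized uniformly at random so `c` stays fixed.

## The grid-graph benchmark and its noise conventions

The synthetic benchmark is a 256×256 image of sixteen 64×64 uniform lumps
in a 4×4 arrangement over the gray levels {0, 127, 255}, with ground-truth
labels. Lump $(r, s)$ takes level index $((r+s) \bmod 3) + 1$, so adjacent
lumps always differ and the three levels cover 6/16, 5/16 and 5/16 of the
image. The size and the exact layout are package choices (the classic
benchmark fixes only the 4×4 arrangement and the three levels); both are
configurable through `grid_graph()`.

The noise injectors follow the single-argument MATLAB `imnoise` conventions
under which the classic grid-graph results are reproducible:

* **Gaussian, intensity $p$**: add a mean offset $255\,p$ plus zero-mean
  Gaussian fluctuation of variance 0.01 on the unit scale (sd 25.5 gray
  levels), then clip to $[0, 255]$. Note the widely used alternative
  reading — variance $= p$, i.e. sd $255\sqrt{p}$ — produces a radically
  harder problem (sd 57 at $p = 0.05$) on which plain FCM accuracy drops to
  ~0.83; the benchmark figures this package reproduces (FCM ≈ 0.99 at both
  5% and 10%, nearly intensity-independent) are only consistent with the
  mean-offset convention. The fluctuation variance is exposed as the
  `variance` argument for users who want the other convention.
* **Speckle, intensity $v$**: multiplicative $x + x\eta$ with $\eta$
  uniform, zero-mean, variance $v$.
* **Salt & pepper, density $d$**: a fraction $d$ of pixels, chosen without
  replacement, set half to 0 and half to 255.

Noisy images are kept at real precision (clipped, not rounded) until
written to disk.

What the generator does *not* emulate: intensity inhomogeneity (bias
fields), partial-volume effects, Rician noise, textured tissue, or any
spatial correlation in the noise. Results on the benchmark therefore
demonstrate optimizer quality and impulse-noise robustness, not clinical
segmentation performance; real MR images can be fed through the same
pipeline (`read_gray_image()` accepts 8-bit PGM/PNG) but are deliberately
not part of the test suite.

## Evaluation metrics

`evaluate_segmentation()` reports the seven standard indexes: the objective
$J$ (on the final working image, plus `J_input` on the pristine input),
PSNR and MSE between the clean reference image and the cluster-center
reconstruction, the partition coefficient `vpc` $= \sum u^2/n$ and partition
entropy `vpe` $= -\sum u \log u / n$ (natural log by default, base
configurable), and — against ground truth — segmentation accuracy and
Jaccard similarity. Lower $J$/`vpe`/MSE and higher PSNR/`vpc`/accuracy/JS
indicate better segmentations. Predicted labels are aligned to the
reference by the overlap-maximizing permutation (exhaustive over the $c!$
possibilities, ample for gray-level work) before accuracy or JS is
computed, so both scores are invariant to relabeling. The multi-class JS is
the reference-size-weighted mean of per-cluster intersection-over-union;
pairwise set formulations that divide by $|S_1| + |S_2|$ cannot reach 1 on
a perfect segmentation and are not used.

## Numerical choices and degenerate inputs

* A pixel exactly on a center gets membership 1 there (first such center if
  several coincide); its objective contribution is 0.
* The inner objective evaluation uses the collapsed form
  $J = \sum_j s_j^{1-m}$, $s_j = \sum_i d_{ij}^{-2/(m-1)}$, implemented in
  C++ since the swarm evaluates it thousands of times per run.
* Ties in hard assignment and in the replacement's dominant-group choice go
  to the lowest cluster index, making every code path deterministic for a
  fixed seed; two runs with the same seed are bit-identical.
* Images must be at least 3×3 (the noise detector needs interior
  structure); gray values outside $[0, 255]$ are rejected.
* Early stop: optionally (`patience`), the search halts when the global
  best has not improved by more than a $10^{-8}$ relative margin for that
  many consecutive generations. It is disabled by default: on the clean
  benchmark the global best routinely stalls for 10+ generations in
  mid-search and then resumes improving as the cooled school refines
  locally, so stall detection systematically mistakes slow refinement for
  convergence; `maxgen` is the termination rule.

## Problem sizes used in the shipped checks

The test suite and the acceptance script regenerate everything they
measure. The Table-style benchmark comparisons run the full 256×256 grid
graph — 30 repetitions for the fast baselines and 10 for the swarm — while
the noise-intensity trend sweeps use a 96×96 grid (5 seeds per intensity,
three algorithms, two noise families) and the unit tests use 32–64 pixel
grids; these sizes are the package's chosen trade-off between sampling
error and turnaround, and all of them are parameters, not constants.

## Known limitations

* Scalar (gray-value) features only; no spatial-information membership
  terms, no multichannel pixels.
* The noise-reduction sweep assumes noise is *sparse* relative to its
  8-neighborhood; under dense corruption (well beyond 10% impulse density)
  `k_min` must grow, and the mechanism can smooth genuine one-pixel
  structures — the classic trade-off it shares with any local-majority
  repair.
* The swarm refines centers to roughly gray-level precision, not to the
  $10^{-6}$ precision of a converged alternating solve; for clean,
  well-separated images plain FCM is both faster and sharper, and the
  hybrid earns its cost only when initialization sensitivity or noise
  matters.
* CPU-time comparisons between the algorithms are hardware- and
  implementation-bound and are intentionally out of scope.
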
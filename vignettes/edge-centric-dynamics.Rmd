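---
title: "Edge-centric network dynamics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-centric network dynamics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgedyn)
```

## The model

Conventional functional connectivity summarizes a pair of parcellated BOLD
series $x_i, x_j$ by their Pearson correlation
$r_{ij} = \frac{1}{T-1}\sum_t z_i(t)\,z_j(t)$, where $z_i$ is the z-scored
series. The edge-centric decomposition simply *omits the time average*: the
edge time series (ETS)

$$e_{ij}(t) = z_i(t)\, z_j(t)$$

resolves each connection into frame-by-frame co-fluctuations (positive when
the two regions deflect together, negative when they oppose), whose time
mean recovers $r_{ij}$ exactly. Two constructions sit on top of the ETS:

* the **edge-by-edge (eFC) matrix**, the inner-product similarity between
  co-fluctuation series, cosine-normalized into $[-1, 1]$;
* the **RSS trace** $\mathrm{RSS}(t) = \sqrt{\sum_{i<j} e_{ij}(t)^2}$, a
  global instantaneous co-fluctuation magnitude.

On the RSS trace we detect **troughs** (frames strictly below both
neighbors) and, between each pair of adjacent troughs, a **peak** (the
interval argmax). Two per-subject dynamics summaries follow: the mean
**peak amplitude** (the degree of global co-activation during events) and
the mean **trough-to-trough duration (TTD)**, the pacing of transitions
between co-fluctuation states.

Frames ranked in the top 10% of RSS define the **high-amplitude frame
state**; the rest define the low-amplitude state. Per state, an FC matrix
is estimated (by default the mean co-fluctuation over retained frames),
binarized over a proportional sparsity grid $S \in \{0.05, \dots, 0.50\}$,
and summarized by global graph metrics ($C_p$, $L_p$, $\gamma$, $\lambda$,
$\sigma$, $E_{glob}$, $E_{loc}$) and nodal metrics ($N_e$, $D_c$, $B_c$),
each reduced to a single number per subject by trapezoidal AUC over the
grid. Group inference uses pooled-variance t tests with Cohen's d and a
normal-approximation 95% CI, ComBat harmonization across acquisition
sites for the dynamics and global AUC metrics, BH-FDR for nodal metrics,
the network-based statistic (NBS) for edgewise differences, and Spearman
correlations against clinical covariates.

## Conventions that matter

* **SD convention.** z-scoring uses the sample SD ($T-1$), which makes the
  identity $r_{ij} = \frac{T}{T-1}\,\overline{e_{ij}}$ exact; the tests
  assert it at $10^{-10}$.
* **Edge order.** All edge-indexed objects use lexicographic $(i, j)$,
  $i<j$; files store 0-based indices.
* **Troughs are strict.** A plateau produces no trough; endpoints are never
  troughs (one neighbor only). Peak ties resolve to the earliest frame.
  Subjects with fewer than two troughs get `NA` summaries and are excluded
  from peak statistics (with a warning).
* **Thresholding.** The sparsity grid is inclusive, `{0.05, ..., 0.50}` by
  0.05 (10 points). Ranking is by signed weight (most positive first;
  `rank_by = "absolute"` is available), tie-broken by canonical edge
  order, and the kept edge count is round-half-away-from-zero of
  $S \cdot E$ — so densities are bit-reproducible and graphs are nested
  across the grid.
* **Disconnected graphs.** $L_p$ averages over *reachable* distinct pairs
  (the fraction of unreachable pairs is reported); efficiencies use
  $1/\infty = 0$. Nodes of degree $< 2$ contribute 0 to $C_p$ and
  $E_{loc}$.
* **Null model.** $\gamma = C_p / \bar C_p^{null}$,
  $\lambda = L_p/\bar L_p^{null}$, $\sigma = \gamma/\lambda$ (stored
  bit-exactly as that ratio), with Maslov–Sneppen degree-preserving
  double-edge swaps (default 100 nulls, 10 accepted swaps per edge,
  rejecting self-loops and multi-edges, giving up on a swap after 100
  failed attempts per target so degenerate graphs such as stars fall back
  to the original graph with a warning). A degenerate $0/0$ (triangle-free
  graph whose nulls equal itself) normalizes to 1.
* **NBS.** Pooled-variance edgewise t (group A minus group B), primary
  threshold $T > 2.105$ in the `greater` tail by default, components
  measured in edges (extent), max-component permutation null with the
  $+1$ correction, so $p \ge 1/(n_{perm}+1)$. NBS runs on the continuous
  state FC values, never on thresholded graphs.
* **Statistics.** Student (pooled) t throughout — the published df of
  $419 = 211 + 210 - 2$ forces the equal-variance test;
  $d$'s CI is $d \pm 1.96\sqrt{\frac{n_A+n_B}{n_A n_B} +
  \frac{d^2}{2(n_A+n_B)}}$, which reproduces published CIs from printed
  summary rows to ~2–3 decimals. Chi-square is Pearson without continuity
  correction. Spearman uses average ranks with the t approximation for p.
  APOE ε4 allele count is treated as ordinal 0/1/2. Correlations are
  reported with both raw and BH-adjusted p; the raw values match the
  uncorrected exploratory convention of the source analyses.

## ComBat harmonization

Features (subject × metric) are standardized against the covariate-adjusted
grand mean and pooled SD; per-site location ($\gamma$) and scale ($\delta$)
estimates are shrunk by parametric empirical Bayes — normal prior on
locations, inverse-gamma on scales, hyperparameters by moment matching,
conditional updates iterated to a relative tolerance of $10^{-6}$ — then
removed, and covariate (group) effects restored. One site is a no-op;
a site with a single subject is an error naming the site; the shrinkage
needs at least two features (with one, the direct per-site estimates are
used). Dynamics and global AUC metrics are harmonized; nodal metrics
receive FDR only.

## The synthetic cohort: what it emulates, and what it does not

Real data for this design are restricted-access clinical rs-fMRI, so the
package ships a generator whose *stated world* is: two balanced groups
("SCD"-like and "HC"-like) across a few acquisition sites, each subject an
ROI × T matrix driven by community-structured co-fluctuation events.

Per subject: Gaussian noise, band-limited to **0.01–0.03 Hz** and
gain-corrected to keep marginal SD `noise_sd`; a renewal process (intervals
$1 + \mathrm{Geom}(rate)$, mean $1/rate$; a fixed-interval mode exists for
exact tests) places events; each event adds `amplitude` × a raised-cosine
envelope of `event_duration = 5` frames (~15 s at TR 3 s) to all members of
one randomly chosen community (disjoint contiguous blocks, loadings 1/0, so
the expected FC block structure is analytic). Sites then apply a per-ROI
additive shift and multiplicative scale ($e^{N(0,\sigma)}$), drawn once
per site and shared by its subjects; sites are assigned round-robin
*within* each group (plain round-robin over an interleaved subject list
would make site coincide with group at two sites and break the
harmonization design). Metadata adds multinomial APOE ε4 counts and
truncated-Gaussian MMSE/MoCA scores, optionally tied to event amplitude.

Two generator choices deserve justification, because naive alternatives
fail the package's own recovery requirements:

* **Why band-limited noise?** With white noise, RSS trough spacing is
  dominated by noise local minima (an i.i.d. sequence is a local minimum
  with probability 1/3, pinning mean TTD near 3 frames regardless of event
  pacing). Real preprocessed BOLD is smooth — hemodynamics plus the
  0.01–0.1 Hz filter concentrate power well below the Nyquist rate — and
  the reported group TTD means (~5–6 frames at TR 3 s) are only attainable
  when the background between events drifts slowly. The 0.01–0.03 Hz band
  stands in for that hemodynamically smoothed spectrum.
* **Why a multi-frame event envelope?** Single-frame impulses make the
  event rate nearly irrelevant to trough counts; genuine co-fluctuation
  events span several seconds. With the 5-frame envelope on a slow
  background, troughs form essentially once per inter-event gap, so mean
  TTD tracks $1/rate$ — the mechanism by which a lower event rate in the
  "SCD"-like group yields longer TTD downstream (and a lower amplitude
  yields lower peak amplitude). Under the defaults this direction recovery
  holds in 20/20 seeded replicate cohorts, and with equal group parameters
  two-sample tests on the dynamics reject at the nominal rate.

The generator does **not** model hemodynamic response functions, motion,
physiological noise, spatially varying smoothness, negative or overlapping
community loadings, or volumetric output. A green recovery test therefore
establishes that the *pipeline* orders groups correctly when the generating
mechanism matches its assumptions — not that the event model is a mechanism
of any clinical condition.

Default parameters (all overridable in `cohort_spec()`): 20 subjects per
group, 20 ROIs in 4 communities, 200 frames at TR 3 s, noise SD 1, event
rates 0.12 ("SCD") vs 0.20 ("HC") events/frame, amplitudes 2 vs 3, two
sites with shift SD 0.1 and log-scale SD 0.1. The group contrasts are the
qualitative contrasts reported for the clinical comparison (rarer, weaker
events in the declining group); sizes are desk-scale so the full suite
runs in minutes.

## Numerical and degenerate-input policy

* Zero-variance ROI at load → error naming the ROI; an identically zero
  edge series under eFC normalization → zeroed row/column with a warning.
* The eFC matrix is memory-guarded (default cap 25 000 edges,
  overridable); the pipeline itself never needs the full eFC matrix.
* Frame splits require $T \ge 1/\text{fraction}$; state FC needs at least
  2 retained frames (3 for frame-restricted Pearson).
* Empty graphs yield all-zero metrics with a warning; zero pooled variance
  yields $t = 0$ (with warning) in NBS and an error in the scalar t test.
* One master seed drives simulation, null rewiring and permutations; the
  caller's RNG state is always restored.

## Open choices resolved here

* Whether the published eFC "normalization to $[-1,1]$" refers to the
  edge-by-edge matrix or the raw ETS: implemented as cosine normalization
  of the matrix (the standard edge-centric construction); raw ETS values
  are left unscaled, since RSS is defined on the co-fluctuation values
  directly.
* Whether state FC is mean co-fluctuation or a frame-restricted
  correlation: both are implemented (`method` argument); the default is
  mean co-fluctuation and is logged in every run.
* Whether group tests use per-threshold values or AUC: AUC, with per-S
  tables always emitted.
* Whether TTD is averaged per subject before group statistics: yes;
  frames by default, seconds via `units = "seconds"`.
* Whether correlation analyses pool groups: pooled by default.

## Known limitations

Weighted/directed graph metrics, modularity and rich-club analyses,
covariate-adjusted (ANCOVA/GLM) group models, non-parametric ComBat, and
NIfTI ingestion are out of scope. Betweenness is unnormalized, matching
the magnitude range of published nodal tables. The worked-example
reproduction of published effect sizes is limited to table rows whose
printed means/SDs carry enough precision; rows with SDs printed at 0.01
cannot be reproduced from rounded inputs.
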
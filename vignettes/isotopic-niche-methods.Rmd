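---
title: "Quantifying isotopic niche partitioning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying isotopic niche partitioning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sulaniche)
```

## The problem

Two closely related booby species (the masked booby *Sula dactylatra* and the
smaller red-footed booby *Sula sula*) breed side by side on the same tropical
island and eat broadly the same prey. Ecological theory says two species with
identical niches cannot coexist, so we ask: do they — and do the sexes within
each species, given that females are larger than males in both — partition
their trophic niche, and does the answer change between the breeding and
non-breeding season?

Bulk stable isotopes give a tissue-level record of assimilated diet:
δ^15^N increases with trophic position, δ^13^C tracks inshore–offshore
carbon sources. Whole blood integrates the 3–4 weeks before sampling (the
incubation period); body feathers record the molt period, which falls in the
non-breeding season. Each individual is therefore a point in the bivariate
(δ^13^C, δ^15^N) plane, a group of individuals is a point cloud, and niche
questions become questions about the geometry of those clouds.

## Niche metrics

**Niche width.** For a group with observations $x_1, \dots, x_n \in
\mathbb{R}^2$ and centroid $\bar{x}$, the mean distance to centroid
$\mathrm{MD} = \tfrac1n \sum_i \lVert x_i - \bar{x} \rVert$ measures
within-group trophic variability. Distances use the raw ‰ axes: both
isotopes are in the same units and the analysis deliberately applies no
standardization, so a permil of δ^13^C counts the same as a permil of
δ^15^N.

**Niche position.** The group centroid itself; two groups are compared by
the Euclidean distance between their centroids.

**Standard ellipse area.** With sample covariance $S$ (denominator $n-1$)
and eigenvalues $\lambda_1 \ge \lambda_2$, the standard ellipse has
semi-axes $\sqrt{\lambda_i}$ along the eigenvectors and area
$\mathrm{SEA} = \pi\sqrt{\lambda_1\lambda_2}$. The small-sample corrected
area is $\mathrm{SEAc} = \mathrm{SEA}\,(n-1)/(n-2)$, which is why fitting
requires $n \ge 3$ ($n = 2$ makes the correction divide by zero) and why
`fit_ellipse()` refuses smaller groups. Collinear clouds give
$\lambda_2 = 0$, SEA $= 0$ and a degeneracy flag rather than an error.

**Overlap.** Two scaled ellipses are compared by a Jaccard index:
intersection area over union area, in $[0,1]$, with 1 exactly when the
ellipses coincide. `scale_ellipse()` controls the convention: `"seac"`
(areas equal SEAc — the package's replication default, because the overlap
statistic in this literature is defined on small-sample-corrected ellipse
areas), `"standard"`, or a probability level ($p$-quantile of
$\chi^2_2$: 50% dotted and 95% solid ellipses are the usual plotting
levels; the scale factor at $p = 0.95$ is $\sqrt{5.991} \approx 2.448$).
Which convention the original analyses used is not derivable from the
printed statistics alone, so all are exposed and the default is documented
here rather than asserted.

## Permutation tests

Both tests report $p = (b+1)/(n_\mathrm{perm}+1)$ where $b$ counts null
statistics $\ge$ the observed one — ties count toward $b$, so $p$ is
conservative, never 0, and never below $1/(n_\mathrm{perm}+1)$. The default
is 9,999 permutations with a mandatory seed.

* **Dispersion difference** (niche width): observed statistic
  $|\mathrm{MD}(A) - \mathrm{MD}(B)|$. The null centres each group on its
  own centroid, pools the centred residuals, and reassigns them randomly to
  two groups of the original sizes. Centring first makes the null
  location-free: a pure difference in position cannot masquerade as a
  difference in width. The residual-permutation literature this follows
  leaves details open; this concrete scheme is the package's choice and is
  asserted as such, not as the original authors'.
* **Centroid distance** (niche position): observed statistic
  $\lVert \bar{A} - \bar{B} \rVert$; the null permutes group labels over
  the pooled raw observations.

Internally the pooled points are put in canonical (lexicographic) order and
the permuted first group always takes $\min(n_A, n_B)$ points. Both
statistics are symmetric in the groups, so swapping the arguments — or
shuffling input rows — reproduces bit-identical results under the same
seed. The tests are translation-invariant; the dispersion test is also
rotation-invariant.

Calibration is checked empirically in the test suite: over 500 replicate
null datasets (two groups of 20 from one bivariate normal, 999 permutations
each) the rejection rate at $\alpha = 0.05$ must fall inside the exact
binomial 95% interval around 0.05, and power must be $\ge 0.95$ against a
threefold dispersion ratio and a 3‰ centroid shift. Those problem sizes
were chosen as the smallest giving a sharp binomial check.

## Ellipse intersection: two routes

No closed form is practical for general ellipse–ellipse intersection, so
the package carries two independent methods and tests them against each
other:

* **Polygonal (default, deterministic).** Each boundary becomes an inscribed
  720-gon; the convex polygons are clipped with the Sutherland–Hodgman
  algorithm (exact for convex input) and the clipped area comes from the
  shoelace formula. The inscribed-polygon bias is relative
  $O(n^{-2}) \approx 1.3\times10^{-5}$ at 720 vertices — below every
  tolerance used downstream.
* **Stratified Monte Carlo (seeded oracle).** One jittered uniform point per
  cell of a grid over the intersection of the two bounding boxes
  (about 200,000 cells by default). Stratification means only
  boundary-crossing cells contribute variance, giving relative errors near
  $10^{-4}$ where naive rejection sampling at the same budget would sit
  near $5\times10^{-3}$; that is what makes a $10^{-3}$ agreement test
  between the two routes meaningful at this budget.

The two routes agree within $10^{-3}$ relative error on random ellipse
pairs, and both reproduce the closed-form circular-lens oracle (unit
circles one radius apart: area $2\cos^{-1}(1/2) - \sqrt{3}/2 \approx
1.2284$, Jaccard $\approx 0.2430$) to four decimals.

## Tissue standardization

Blood is isotopically impoverished relative to feathers, so breeding
(blood) vs non-breeding (feather) comparisons first map blood onto the
feather scale:

$$\delta^{13}C_f = 0.972\,\delta^{13}C_b + 0.962, \qquad
  \delta^{15}N_f = 1.014\,\delta^{15}N_b + 0.447.$$

Coefficient standard errors (±0.020, ±0.414, ±0.056, ±0.414) are carried as
metadata but deliberately not propagated: the downstream analyses use point
estimates, and propagating regression uncertainty through permutation tests
would change the meaning of their p-values. The transform is applied once,
only to whole-blood rows, and only for cross-period comparisons —
`standardize_blood_samples()` refuses a second application, and within-tissue
comparisons always use raw values. Because the map is affine, the centroid
of transformed values equals the transform of the centroid, so niche-position
results are consistent whichever order one computes them in.

## Diet analyses

Frequency of occurrence of a prey family is the percentage of regurgitate
samples containing at least one item of that family — presence, not
abundance. Family composition is compared across species with a Pearson
χ² test (no continuity correction, asymptotic p, expected counts below 5
flagged), food-load mass and prey length with two-sided t-tests. Welch's
unequal-variance form is the default because nothing in the source analyses
pins down the variant; `variant = "pooled"` is available for replication
attempts. Prey length enters only for items complete from head to tail —
partly digested items have no meaningful length — and all lengths are held
in a single declared unit (cm) because published prey-length summaries in
this literature sometimes mix mm and cm inconsistently.

## The synthetic generator

`booby_study_preset()` reproduces the *design* of the field study — eight
species × sex × tissue groups at the field group sizes (blood 18/18/8/14,
feathers 15/18/7/13) — with bivariate-normal clouds whose centroids encode
the qualitative findings: species separated by ≈2.1‰ in δ^15^N during
breeding, masked sexes 0.6‰ apart, red-footed sexes coincident, feather
clouds closer together with no sex structure. Within-group SDs default to
0.25‰ (δ^13^C) and 0.35‰ (δ^15^N), values typical of seabird colony
studies. All centroid values are package defaults for simulation — they are
not the field measurements, and nothing downstream treats them as data.

The diet generator draws item counts from a shifted negative binomial
(means 3.7 and 2.8 items per sample), food loads from lognormals with means
149.5 g and 87.5 g, families from per-species multinomials dominated by
flyingfish (Exocoetidae) with more squid (Ommastrephidae) in the
red-footed-like species, and completeness as Bernoulli(0.16).

What passing tests on these data do **not** show: robustness to
non-Gaussian isotope distributions (real clouds can be skewed or
multimodal), to tissue-specific variance differences, to temporal
autocorrelation within seasons, or to non-random sampling of regurgitates.
The bivariate-normal assumption is shared by the ellipse model itself, so
the simulations validate internal consistency, not the model's fit to any
field dataset.

## Numerical and design choices

* Covariance uses the $n-1$ denominator, matching the $(n-1)/(n-2)$
  structure of the SEAc correction.
* Polygon resolution 720 vertices; absolute area tolerance $10^{-4}$ ‰² for
  method agreement; Jaccard reported to 4 decimals.
* Minimum group size 3 everywhere; the comparison grid emits undersized or
  tissue-missing comparisons with a skip flag instead of failing, so a
  report always accounts for the full design.
* Tukey HSD contrasts treat the four species × sex cells within a tissue as
  one one-way family per isotope (unknown-sex individuals are excluded from
  sex-stratified cells but retained in species-level pooling). The original
  model layout is unstated; one familywise procedure per tissue reproduces
  every reported pairwise contrast at familywise α = 0.05.
* Years are pooled throughout, mirroring the source design where
  year-stratified cells would be too small.
* Each grid comparison derives its own seed from the run seed, so reports
  are reproducible end to end and independent of execution order.

## Replication against deposited field data

The field dataset is archived externally and is not bundled.
`replicate_study()` accepts a locally supplied CSV (with a column-mapping
option, since the deposit's headers are not guaranteed to match the
canonical ones), runs the identical grid, and extracts the replication
quantities: per-comparison dispersion differences and overlap percentages.
Published overlap bounds are upper bounds and sensitive to the
ellipse-scale convention, so replication output reports all scale modes'
defaults explicitly rather than asserting equality with printed values.

## Problem sizes

The shipped analysis scripts use the preset group sizes (111 isotope
samples, 72 diet samples) with 9,999 permutations per test. The test suite
uses 99–999 permutations and 150–500 replicate simulations per calibration
check — sizes chosen so the binomial and Kolmogorov–Smirnov checks have
useful resolution.
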
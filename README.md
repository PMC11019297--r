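# sulaniche

Quantitative tools for **isotopic niche partitioning** in sympatric
seabirds. Two booby species (*Sula dactylatra*, the masked booby, and the
smaller *Sula sula*, the red-footed booby) breed on the same tropical
island and take broadly the same prey; this package asks whether — and
when — they and the sexes within them actually divide the trophic niche,
using bulk δ¹³C and δ¹⁵N measurements (whole blood for the breeding
period, body feathers for the non-breeding period) and regurgitate diet
samples. It is written for trophic ecologists who want the full analysis
chain — data validation, niche geometry, permutation inference, tissue
standardization, diet statistics — as tested, seed-reproducible functions
rather than one-off scripts.

## The statistics at its core

Each individual is a point in the (δ¹³C, δ¹⁵N) plane. For a group with
sample covariance *S* (denominator *n*−1) and eigenvalues λ₁ ≥ λ₂:

* **Standard ellipse area** SEA = π√(λ₁λ₂), small-sample corrected
  SEAc = SEA·(n−1)/(n−2) — the group's niche area.
* **Niche width**: mean Euclidean distance of the points to their
  centroid; groups compared by the absolute difference, with a
  residual-permutation null (groups centred before pooling, so the test
  sees dispersion only).
* **Niche position**: Euclidean distance between group centroids, with a
  raw-label permutation null. Both tests use p = (b+1)/(n_perm+1).
* **Overlap**: Jaccard index of the two (SEAc-scaled) ellipses,
  intersection/union, computed by exact convex-polygon clipping of
  720-vertex boundary polygons and cross-checked by a seeded stratified
  Monte-Carlo sampler.
* **Tissue standardization** for breeding vs non-breeding comparisons:
  δ¹³C_f = 0.972·δ¹³C_b + 0.962 and δ¹⁵N_f = 1.014·δ¹⁵N_b + 0.447.
* Diet: frequency of occurrence per prey family, Pearson χ² composition
  homogeneity, Welch t-tests on food-load mass and complete-prey length.

A seeded synthetic generator (`booby_study_preset()`, `generate_diet()`)
emulates the field design — eight species × sex × tissue groups at the
study's group sizes and a 59 + 13 regurgitate table — so the entire
workflow runs and is tested without any field data.

## Worked example

```r
library(sulaniche)

iso <- generate_isotopes(booby_study_preset(), seed = 20240101)
report <- run_analysis(iso)          # 9999 permutations, seed 1, SEAc overlap
report$comparisons[, c("comparison", "overlap_percent", "dispersion_p", "centroid_p")]
```

```
                     comparison overlap_percent dispersion_p centroid_p
1     interspecific_whole_blood             0.0       0.0299     0.0001
2    interspecific_body_feather             0.0       0.5724     0.0001
3      sexes_masked_whole_blood             0.0       0.3300     0.0001
4     sexes_masked_body_feather            60.2       0.7912     0.6610
5  sexes_red_footed_whole_blood            15.8       0.4233     0.0855
6 sexes_red_footed_body_feather            42.9       0.9325     0.5183
7                periods_masked             0.0       0.0170     0.0001
8            periods_red_footed             0.0       0.6240     0.0001
```

Reading the table: the two species never share niche space during breeding
(row 1: zero overlap, centroid test p = 0.0001 — the minimum achievable at
9,999 permutations); masked females and males occupy different niche
positions during breeding but not in feathers (rows 3–4); red-footed sexes
are indistinguishable in both tissues (rows 5–6); and both species shift
their niche between the breeding and non-breeding period once blood is
standardized to the feather scale (rows 7–8).

```r
diet <- generate_diet(seed = 20240102)
compare_diets(diet)$foodload_t[c("t", "p_value")]
blood_to_feather(0, 0)   # the standardization intercepts: d13c 0.962, d15n 0.447
```

The numbered scripts under `analysis/` run the same workflow end to end
(`01_simulate.R` → `04_morphometrics.R`), printing what each step found
and writing its tables under `results/`.

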
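make_full_dataset <- function(seed = 11L) generate_isotopes(booby_study_preset(), seed = seed)

test_that("the default grid enumerates the full study design", {
  iso <- make_full_dataset()
  grid <- build_default_grid(iso)
  expect_equal(nrow(grid), 8L)
  expect_equal(sum(grid$type == "interspecific"), 2L)
  expect_equal(sum(grid$type == "intraspecific"), 4L)
  expect_equal(sum(grid$type == "cross_period"), 2L)
  expect_false(any(grid$skip))
  # cross-period comparisons standardize the blood side
  expect_true(all(grid$transform[grid$type == "cross_period"] == "blood_to_feather_a"))
})

test_that("missing tissues and undersized cells are skipped with a flag, not dropped", {
  iso <- make_full_dataset()
  blood_only <- iso[iso$tissue == "whole_blood", ]
  grid <- build_default_grid(blood_only)
  expect_equal(nrow(grid), 8L)
  feather_dependent <- grid$tissue_b == "body_feather" | grid$tissue_a == "body_feather"
  expect_true(all(grid$skip[feather_dependent]))
  expect_false(any(grid$skip[!feather_dependent]))
  # shrink one sex cell below n = 3
  small <- iso[-(which(iso$species == "red_footed" & iso$sex == "female" &
                         iso$tissue == "whole_blood")[1:6]), ]
  grid2 <- build_default_grid(small)
  rf_blood <- grid2$comparison == "sexes_red_footed_whole_blood"
  expect_true(grid2$skip[rf_blood])
  expect_match(grid2$skip_reason[rf_blood], "n_a = 2")
  # other comparisons still run
  expect_false(grid2$skip[grid2$comparison == "interspecific_whole_blood"])
})

test_that("single-species data skips inter-specific comparisons but runs the rest", {
  iso <- make_full_dataset()
  masked <- iso[iso$species == "masked", ]
  report <- run_comparison_grid(masked, n_perm = 99L, seed = 1L)
  cmp <- report$comparisons
  expect_true(all(cmp$skip[cmp$type == "interspecific"]))
  expect_false(cmp$skip[cmp$comparison == "sexes_masked_whole_blood"])
  expect_false(cmp$skip[cmp$comparison == "periods_masked"])
})

test_that("reports are reproducible under a seed and row-order invariant", {
  iso <- make_full_dataset()
  r1 <- run_comparison_grid(iso, n_perm = 99L, seed = 4L)
  r2 <- run_comparison_grid(iso, n_perm = 99L, seed = 4L)
  expect_identical(r1$comparisons, r2$comparisons)
  shuffled <- iso[sample(nrow(iso)), ]
  r3 <- run_comparison_grid(shuffled, n_perm = 99L, seed = 4L)
  expect_equal(r3$comparisons$dispersion_p, r1$comparisons$dispersion_p)
  expect_equal(r3$comparisons$centroid_p, r1$comparisons$centroid_p)
  expect_equal(r3$comparisons$overlap_jaccard, r1$comparisons$overlap_jaccard)
  # with n_perm = 99 no p-value can undercut 1/100
  expect_true(all(r1$comparisons$dispersion_p >= 0.01, na.rm = TRUE))
  expect_true(all(r1$comparisons$centroid_p >= 0.01, na.rm = TRUE))
})

test_that("Tukey HSD pairwise comparisons behave across layouts", {
  expect_error(per_isotope_pairwise(rnorm(10), rep("a", 10)), "two groups")
  expect_error(per_isotope_pairwise(rep(c(1, 2), each = 5),
                                    rep(c("a", "b"), each = 5)), "degenerate")
  # two identical groups: adjusted p near 1
  set.seed(14)
  x <- rnorm(30)
  same <- per_isotope_pairwise(c(x, x), rep(c("a", "b"), each = 30))
  expect_gt(same$p_adj, 0.9)
  # four groups, one shifted by 10 pooled SDs: its three contrasts all reject
  g <- rep(c("a", "b", "c", "d"), each = 15)
  y <- rnorm(60)
  y[g == "d"] <- y[g == "d"] + 10
  tk <- per_isotope_pairwise(y, g)
  hits <- grepl("d", tk$contrast)
  expect_equal(sum(hits), 3L)
  expect_true(all(tk$p_adj[hits] < 0.001))
  expect_true(all(tk$p_adj[!hits] > 0.05))
})

test_that("run_analysis bundles isotope and diet results under one config", {
  iso <- make_full_dataset()
  diet <- generate_diet(seed = 3L)
  cfg <- read_run_config()
  cfg$n_perm <- 99L
  report <- suppressMessages(run_analysis(iso, diet, cfg))
  expect_s3_class(report, "analysis_report")
  expect_s3_class(report$diet, "diet_report")
  expect_equal(report$meta$n_perm, 99L)
  expect_true(!is.null(report$tukey))
  expect_setequal(unique(report$tukey$isotope), c("d13c", "d15n"))
})

test_that("the synthetic preset recovers the qualitative breeding pattern", {
  # species cleanly separated in blood; red-footed sexes indistinguishable
  iso <- make_full_dataset(seed = 101L)
  report <- run_comparison_grid(iso, n_perm = 999L, seed = 5L)
  cmp <- report$comparisons
  inter <- cmp$comparison == "interspecific_whole_blood"
  expect_lt(cmp$centroid_p[inter], 0.05)
  expect_equal(cmp$overlap_jaccard[inter], 0)
  rf <- cmp$comparison == "sexes_red_footed_whole_blood"
  expect_gt(cmp$centroid_p[rf], 0.05)
})
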
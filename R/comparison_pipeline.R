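MIN_GROUP_N <- 3L  # minimum group size for ellipse fitting and permutation tests

# Extract the (d13c, d15n) matrix for one species/sex/tissue cell.
# sex = NULL pools all sexes (including unknown); sex-stratified extraction
# never includes unknown-sex individuals.
group_matrix <- function(samples, species, tissue, sex = NULL) {
  keep <- samples$species == species & samples$tissue == tissue
  if (!is.null(sex)) keep <- keep & samples$sex == sex
  as.matrix(samples[keep, c("d13c", "d15n"), drop = FALSE])
}

#' Build the default comparison grid for a two-species, two-tissue dataset
#'
#' Emits the standard set of pairwise niche comparisons:
#' * inter-specific within each tissue (sexes pooled);
#' * female vs male within each species x tissue;
#' * breeding vs non-breeding within each species: standardized whole blood
#'   (feather-equivalent) against body feathers, sexes pooled.
#'
#' Comparisons whose groups fall below the minimum size (n >= 3) or whose
#' tissue is absent are emitted with a skip flag rather than dropped, so the
#' report always accounts for the full grid.
#'
#' @param samples An `"isotope_table"`.
#' @return A data.frame with one row per comparison: `comparison`, `type`,
#'   group descriptors, group sizes, `skip`, `skip_reason`.
#' @export
build_default_grid <- function(samples) {
  species <- c("masked", "red_footed")
  tissues <- c("whole_blood", "body_feather")
  rows <- list()
  add <- function(comparison, type, sp_a, sex_a, ti_a, sp_b, sex_b, ti_b, transform) {
    n_a <- nrow(group_matrix(samples, sp_a, ti_a, sex_a))
    n_b <- nrow(group_matrix(samples, sp_b, ti_b, sex_b))
    skip <- n_a < MIN_GROUP_N || n_b < MIN_GROUP_N
    rows[[length(rows) + 1L]] <<- data.frame(
      comparison = comparison, type = type,
      species_a = sp_a, sex_a = sex_a %||% "pooled", tissue_a = ti_a,
      species_b = sp_b, sex_b = sex_b %||% "pooled", tissue_b = ti_b,
      transform = transform, n_a = n_a, n_b = n_b,
      skip = skip,
      skip_reason = if (skip) sprintf("group below n >= %d (n_a = %d, n_b = %d)",
                                      MIN_GROUP_N, n_a, n_b) else "",
      stringsAsFactors = FALSE)
  }
  for (ti in tissues) {
    add(paste0("interspecific_", ti), "interspecific",
        "masked", NULL, ti, "red_footed", NULL, ti, "none")
  }
  for (sp in species) for (ti in tissues) {
    add(paste0("sexes_", sp, "_", ti), "intraspecific",
        sp, "female", ti, sp, "male", ti, "none")
  }
  for (sp in species) {
    add(paste0("periods_", sp), "cross_period",
        sp, NULL, "whole_blood", sp, NULL, "body_feather", "blood_to_feather_a")
  }
  do.call(rbind, rows)
}

run_one_comparison <- function(samples, row, n_perm, seed, scale_mode, coeffs) {
  if (row$transform == "blood_to_feather_a") {
    samples <- standardize_blood_samples(samples, coeffs)
    ti_a <- "feather_equivalent"
  } else {
    ti_a <- row$tissue_a
  }
  sex_a <- if (row$sex_a == "pooled") NULL else row$sex_a
  sex_b <- if (row$sex_b == "pooled") NULL else row$sex_b
  a <- group_matrix(samples, row$species_a, ti_a, sex_a)
  b <- group_matrix(samples, row$species_b, row$tissue_b, sex_b)
  ell_a <- fit_ellipse(a)
  ell_b <- fit_ellipse(b)
  ov <- if (!ell_a$degenerate && !ell_b$degenerate) {
    overlap_index(scale_ellipse(ell_a, scale_mode), scale_ellipse(ell_b, scale_mode))
  } else NULL
  disp <- dispersion_difference_test(a, b, n_perm = n_perm, seed = seed)
  cent <- centroid_distance_test(a, b, n_perm = n_perm, seed = seed + 1L)
  list(ellipse_a = ell_a, ellipse_b = ell_b, overlap = ov,
       dispersion = disp, centroid = cent)
}

#' Run the full niche-comparison grid
#'
#' For every non-skipped comparison in [build_default_grid()]: fits both
#' standard ellipses, computes the Jaccard overlap of the scaled ellipses,
#' and runs the dispersion-difference and centroid-distance permutation
#' tests. Each comparison uses a seed derived deterministically from the run
#' seed, so the whole report is reproducible.
#'
#' @param samples An `"isotope_table"`.
#' @param n_perm Permutations per test (default 9999).
#' @param seed Run seed.
#' @param scale_mode Ellipse scaling for overlap: `"seac"` (default,
#'   small-sample-corrected areas), `"standard"`, `"p50"` or `"p95"`.
#' @param coeffs Blood-to-feather coefficients for cross-period comparisons.
#' @return A list of class `"analysis_report"`: `comparisons` (one summary
#'   row per grid entry), `ellipses` (per-group ellipse metrics), `details`
#'   (full per-comparison objects), `tukey` (per-tissue, per-isotope pairwise
#'   Tukey results), `meta`.
#' @export
run_comparison_grid <- function(samples, n_perm = 9999L, seed = 1L,
                                scale_mode = c("seac", "standard", "p50", "p95"),
                                coeffs = standardization_coefficients()) {
  scale_mode <- match.arg(scale_mode)
  grid <- build_default_grid(samples)
  details <- vector("list", nrow(grid))
  names(details) <- grid$comparison
  out <- grid
  out$seac_a <- out$seac_b <- out$overlap_jaccard <- out$overlap_percent <- NA_real_
  out$dispersion_observed <- out$dispersion_p <- NA_real_
  out$centroid_observed <- out$centroid_p <- NA_real_
  for (i in seq_len(nrow(grid))) {
    if (grid$skip[i]) next
    res <- run_one_comparison(samples, grid[i, ], n_perm,
                              seed + 100L * i, scale_mode, coeffs)
    details[[i]] <- res
    out$seac_a[i] <- res$ellipse_a$seac
    out$seac_b[i] <- res$ellipse_b$seac
    if (!is.null(res$overlap)) {
      out$overlap_jaccard[i] <- res$overlap$jaccard
      out$overlap_percent[i] <- res$overlap$percent
    }
    out$dispersion_observed[i] <- res$dispersion$observed
    out$dispersion_p[i] <- res$dispersion$p_value
    out$centroid_observed[i] <- res$centroid$observed
    out$centroid_p[i] <- res$centroid$p_value
  }
  ellipses <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    if (is.null(details[[i]])) return(NULL)
    rbind(
      data.frame(comparison = grid$comparison[i], side = "a",
                 species = grid$species_a[i], sex = grid$sex_a[i],
                 tissue = grid$tissue_a[i], n = details[[i]]$ellipse_a$n,
                 d13c_mean = details[[i]]$ellipse_a$centroid[1L],
                 d15n_mean = details[[i]]$ellipse_a$centroid[2L],
                 sea = details[[i]]$ellipse_a$sea, seac = details[[i]]$ellipse_a$seac,
                 stringsAsFactors = FALSE),
      data.frame(comparison = grid$comparison[i], side = "b",
                 species = grid$species_b[i], sex = grid$sex_b[i],
                 tissue = grid$tissue_b[i], n = details[[i]]$ellipse_b$n,
                 d13c_mean = details[[i]]$ellipse_b$centroid[1L],
                 d15n_mean = details[[i]]$ellipse_b$centroid[2L],
                 sea = details[[i]]$ellipse_b$sea, seac = details[[i]]$ellipse_b$seac,
                 stringsAsFactors = FALSE))
  }))
  rownames(ellipses) <- NULL
  tukey <- tukey_by_tissue(samples)
  structure(list(
    comparisons = out, ellipses = ellipses, details = details, tukey = tukey,
    meta = list(seed = as.integer(seed), n_perm = as.integer(n_perm),
                ellipse_scale = scale_mode,
                version = as.character(utils::packageVersion("sulaniche")))
  ), class = "analysis_report")
}

#' Tukey HSD pairwise comparisons of one isotope across labelled groups
#'
#' One-way layout over the supplied groups (for example the four species x
#' sex cells within a tissue), fitted with `aov` and adjusted with Tukey's
#' honestly-significant-difference procedure at familywise alpha 0.05.
#'
#' @param values Numeric vector of delta values (permil).
#' @param labels Group label for each value.
#' @return A data.frame: `contrast`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
per_isotope_pairwise <- function(values, labels) {
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("need at least two groups", call. = FALSE)
  counts <- table(labels)
  if (any(counts < 2L)) stop("every group needs n >= 2", call. = FALSE)
  within_var <- tapply(values, labels, stats::var)
  if (all(within_var == 0)) {
    stop("degenerate: zero within-group variance in every group", call. = FALSE)
  }
  fit <- stats::aov(values ~ labels, data = data.frame(values = values, labels = labels))
  tk <- stats::TukeyHSD(fit)$labels
  data.frame(contrast = rownames(tk), diff = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"],
             row.names = NULL, stringsAsFactors = FALSE)
}

# Tukey HSD per tissue (species x sex cells, unknown sex excluded) for both
# isotopes; tissues with fewer than two usable cells are omitted.
tukey_by_tissue <- function(samples) {
  out <- list()
  for (ti in intersect(c("whole_blood", "body_feather"), unique(samples$tissue))) {
    sub <- samples[samples$tissue == ti & samples$sex %in% c("female", "male"), ]
    cell <- paste(sub$species, sub$sex, sep = ".")
    usable <- names(which(table(cell) >= 2L))
    sub <- sub[cell %in% usable, ]
    cell <- cell[cell %in% usable]
    if (length(unique(cell)) < 2L) next
    for (iso in c("d13c", "d15n")) {
      tk <- per_isotope_pairwise(sub[[iso]], cell)
      tk <- cbind(tissue = ti, isotope = iso, tk, stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- tk
    }
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the complete analysis (isotopes plus optional diet)
#'
#' Orchestrates the full study workflow over already-validated tables: the
#' niche-comparison grid (ellipses, overlap, permutation tests, Tukey HSD)
#' and, when a diet table is supplied, the between-species diet comparison.
#'
#' @param samples An `"isotope_table"`.
#' @param diet Optional `"diet_table"`.
#' @param config A configuration list, as from [read_run_config()].
#' @return An `"analysis_report"` (see [run_comparison_grid()]) with an extra
#'   `diet` element when diet data were supplied.
#' @export
run_analysis <- function(samples, diet = NULL, config = read_run_config()) {
  report <- run_comparison_grid(samples, n_perm = config$n_perm, seed = config$seed,
                                scale_mode = config$ellipse_scale)
  if (!is.null(diet)) report$diet <- compare_diets(diet)
  report
}

#' Replicate the niche analysis on a locally supplied isotope deposit
#'
#' Runs the full comparison grid on an external isotope CSV (for example a
#' local copy of the study's archived data) and extracts the replication
#' quantities: the dispersion-difference statistics and the overlap
#' percentages of every comparison. The deposit is not bundled; the file must
#' be supplied by the user.
#'
#' @param path CSV path, read with [read_isotope_table()].
#' @param col_map Optional column mapping for non-canonical headers.
#' @param ... Passed to [run_comparison_grid()].
#' @return A list: `report` (the full `"analysis_report"`) and `replication`
#'   (data.frame of comparison, dispersion difference, dispersion p, centroid
#'   p, overlap percent).
#' @export
replicate_study <- function(path, col_map = NULL, ...) {
  samples <- read_isotope_table(path, col_map = col_map)
  report <- run_comparison_grid(samples, ...)
  cmp <- report$comparisons
  list(report = report,
       replication = data.frame(
         comparison = cmp$comparison,
         dispersion_difference = cmp$dispersion_observed,
         dispersion_p = cmp$dispersion_p,
         centroid_p = cmp$centroid_p,
         overlap_percent = cmp$overlap_percent,
         stringsAsFactors = FALSE))
}
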
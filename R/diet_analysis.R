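#' Relative frequency of occurrence of prey families
#'
#' FO% of a family in a species is 100 times the fraction of that species'
#' diet samples containing at least one item of the family: presence, not
#' abundance, so multiple items of one family in one sample count once.
#'
#' @param diet A `"diet_table"` from [read_diet_table()] or
#'   [generate_diet()].
#' @return A data.frame with columns `species`, `family`, `n_samples`,
#'   `n_occurrences`, `fo_percent`.
#' @export
frequency_of_occurrence <- function(diet) {
  stopifnot(inherits(diet, "diet_table"))
  if (nrow(diet$samples) == 0L) stop("empty diet collection", call. = FALSE)
  species <- sort(unique(diet$samples$species))
  fams <- sort(unique(diet$items$family))
  out <- expand.grid(species = species, family = fams,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  pres <- unique(diet$items[, c("sample_id", "family")])
  pres <- merge(pres, diet$samples[, c("sample_id", "species")], by = "sample_id")
  n_per_sp <- table(diet$samples$species)
  occ <- as.data.frame(table(pres$species, pres$family),
                       stringsAsFactors = FALSE)
  names(occ) <- c("species", "family", "n_occurrences")
  out <- merge(out, occ, by = c("species", "family"), all.x = TRUE)
  out$n_occurrences[is.na(out$n_occurrences)] <- 0L
  out$n_samples <- as.integer(n_per_sp[out$species])
  out$fo_percent <- 100 * out$n_occurrences / out$n_samples
  out <- out[order(out$species, -out$fo_percent, out$family),
             c("species", "family", "n_samples", "n_occurrences", "fo_percent")]
  rownames(out) <- NULL
  out
}

#' Mean and SD of prey items per sample, by species
#'
#' @param diet A `"diet_table"`.
#' @return A data.frame with `species`, `n_samples`, `mean_items`, `sd_items`.
#' @export
items_per_sample <- function(diet) {
  stopifnot(inherits(diet, "diet_table"))
  sp <- split(diet$samples$n_items, diet$samples$species)
  data.frame(species = names(sp),
             n_samples = vapply(sp, length, integer(1L)),
             mean_items = vapply(sp, mean, numeric(1L)),
             sd_items = vapply(sp, stats::sd, numeric(1L)),
             row.names = NULL)
}

#' Chi-square test of diet-composition homogeneity
#'
#' Pearson chi-square (no continuity correction) on a species x family table
#' of prey-item counts, testing whether the proportional family composition of
#' the diet is the same across species. df = (rows - 1)(cols - 1). Cells with
#' expected count < 5 are reported via a message (the asymptotic p-value is
#' still returned, matching the conventional df-based test).
#'
#' @param counts A species x family matrix or table of item counts (or a
#'   `"diet_table"`, from which the counts are tabulated).
#' @return A list: `statistic`, `df`, `p_value`, `expected`,
#'   `n_small_expected`.
#' @export
composition_chi2 <- function(counts) {
  if (inherits(counts, "diet_table")) {
    counts <- table(counts$items$species, counts$items$family)
  }
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    stop("need at least a 2 x 2 count table", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("degenerate table: a row or column of zeros", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  n_small <- sum(res$expected < 5)
  if (n_small > 0L) {
    message(n_small, " cell(s) with expected count < 5; ",
            "asymptotic chi-square p-value may be inaccurate")
  }
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value), expected = res$expected,
       n_small_expected = n_small)
}

#' Two-sample t-test on diet measurements
#'
#' Two-sided t-test used for food-load mass and complete-prey length
#' comparisons between species. Welch's unequal-variance form is the default;
#' `variant = "pooled"` gives the classical equal-variance test.
#'
#' @param a,b Numeric vectors, n >= 2 each.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return A list: `t`, `df`, `p_value`, `mean_a`, `sd_a`, `n_a`, `mean_b`,
#'   `sd_b`, `n_b`, `variant`.
#' @export
two_sample_t <- function(a, b, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("both groups need n >= 2", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b)) {
    stop("undefined statistic: zero variance in both groups with equal means",
         call. = FALSE)
  }
  res <- stats::t.test(a, b, var.equal = (variant == "pooled"))
  list(t = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value),
       mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
       mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b),
       variant = variant)
}

#' Full between-species diet comparison
#'
#' Bundles the diet descriptors and tests: FO% table, items-per-sample
#' summaries, the chi-square homogeneity test of family composition, a t-test
#' on food-load mass, and a t-test on prey length restricted to items that are
#' complete from head to tail (partly digested items have no usable length).
#'
#' @param diet A `"diet_table"` with exactly two species.
#' @param variant t-test variant, see [two_sample_t()].
#' @return A list of class `"diet_report"`: `fo_table`, `items_per_sample`,
#'   `chi2`, `foodload_t`, `length_t` (`NULL` when either species has fewer
#'   than two complete items).
#' @export
compare_diets <- function(diet, variant = c("welch", "pooled")) {
  stopifnot(inherits(diet, "diet_table"))
  variant <- match.arg(variant)
  species <- sort(unique(diet$samples$species))
  if (length(species) != 2L) stop("diet comparison needs exactly two species", call. = FALSE)
  mass <- split(diet$samples$total_mass_g, diet$samples$species)
  complete <- diet$items[diet$items$complete & is.finite(diet$items$length_cm), ]
  len <- split(complete$length_cm, factor(complete$species, levels = species))
  length_t <- if (all(vapply(len, length, integer(1L)) >= 2L)) {
    two_sample_t(len[[1L]], len[[2L]], variant)
  } else NULL
  structure(list(
    fo_table = frequency_of_occurrence(diet),
    items_per_sample = items_per_sample(diet),
    chi2 = composition_chi2(diet),
    foodload_t = two_sample_t(mass[[1L]], mass[[2L]], variant),
    length_t = length_t,
    species = species
  ), class = "diet_report")
}
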
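#' Controlled vocabulary for isotope sample labels
#'
#' The grouping labels every isotope table must draw from. Analyses are keyed
#' on species (the two sympatric boobies), sex, and tissue. Whole blood
#' integrates the diet of the preceding 3-4 weeks (breeding/incubation);
#' body feathers integrate the molt period (non-breeding).
#'
#' @param species,sex,tissue Character vectors of admissible labels.
#' @return A named list with elements `species`, `sex`, `tissue`.
#' @export
#' @examples
#' default_vocabulary()
default_vocabulary <- function(species = c("masked", "red_footed"),
                               sex = c("female", "male", "unknown"),
                               tissue = c("whole_blood", "body_feather")) {
  list(species = species, sex = sex, tissue = tissue)
}

# C:N mass ratio below which lipid correction of d13C is considered unnecessary
LIPID_CN_THRESHOLD <- 4

ISOTOPE_COLUMNS <- c("sample_id", "species", "sex", "tissue", "year", "d13c", "d15n")

#' Read and validate a tidy isotope table
#'
#' Reads a comma-delimited table with one row per individual tissue sample and
#' columns `sample_id, species, sex, tissue, year, d13c, d15n` plus an optional
#' `c_n_ratio`. Labels are checked against a controlled vocabulary and the
#' delta values must be finite numbers. Rows with C:N mass ratio >= 4 are
#' retained but flagged: at such lipid contents a mathematical d13C correction
#' is normally advised, whereas below 4 it is not required.
#'
#' @param path Path to a CSV file with a header row.
#' @param vocab Label vocabulary, as from [default_vocabulary()].
#' @param col_map Optional named character vector mapping the canonical column
#'   names to the names actually present in the file, e.g.
#'   `c(d13c = "Carbon", d15n = "Nitrogen")`. Useful for externally deposited
#'   tables whose headers differ from the canonical ones.
#' @return A `data.frame` of validated samples with class `"isotope_table"`.
#'   Attribute `"lipid_flags"` holds the sample ids flagged for high C:N
#'   (character(0) if none; `NA` suppressed when the column is absent).
#' @export
read_isotope_table <- function(path, vocab = default_vocabulary(), col_map = NULL) {
  if (!file.exists(path)) stop("isotope table not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      j <- match(col_map[[canon]], names(raw))
      if (is.na(j)) stop("mapped column not found in file: ", col_map[[canon]], call. = FALSE)
      names(raw)[j] <- canon
    }
  }
  validate_isotope_table(raw, vocab = vocab)
}

#' Validate an in-memory isotope table
#'
#' The same checks as [read_isotope_table()] applied to a `data.frame` built in
#' code (for example by [generate_isotopes()]).
#'
#' @inheritParams read_isotope_table
#' @param x A data.frame with the canonical isotope columns.
#' @return The validated `"isotope_table"`; see [read_isotope_table()].
#' @export
validate_isotope_table <- function(x, vocab = default_vocabulary()) {
  missing_cols <- setdiff(ISOTOPE_COLUMNS, names(x))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("d13c", "d15n")) {
    v <- x[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))
      stop("non-numeric ", col, " value at row(s): ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    if (any(!is.finite(v))) {
      stop("non-finite ", col, " value at row(s): ",
           paste(which(!is.finite(v)), collapse = ", "), call. = FALSE)
    }
  }
  for (col in c("species", "sex", "tissue")) {
    unknown <- setdiff(unique(as.character(x[[col]])), vocab[[col]])
    if (length(unknown)) {
      stop("unknown ", col, " label(s): ", paste(unknown, collapse = ", "),
           "; declared vocabulary: ", paste(vocab[[col]], collapse = ", "),
           call. = FALSE)
    }
  }
  x$year <- as.integer(x$year)
  flags <- character(0)
  if ("c_n_ratio" %in% names(x)) {
    cn <- x$c_n_ratio
    if (any(!is.na(cn) & cn <= 0)) {
      stop("c_n_ratio must be > 0 where present", call. = FALSE)
    }
    hi <- !is.na(cn) & cn >= LIPID_CN_THRESHOLD
    if (any(hi)) {
      flags <- as.character(x$sample_id[hi])
      message("lipid-correction advised for ", sum(hi),
              " sample(s) with C:N >= ", LIPID_CN_THRESHOLD, ": ",
              paste(flags, collapse = ", "))
    }
  } else {
    message("c_n_ratio absent: lipid rule not evaluated")
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  attr(x, "lipid_flags") <- flags
  class(x) <- c("isotope_table", "data.frame")
  x
}

DIET_COLUMNS <- c("sample_id", "species", "total_mass_g", "family", "length_cm", "complete")

#' Read a long-format diet (regurgitate) table
#'
#' One row per prey item, with the per-sample food-load mass repeated on each
#' row. Columns: `sample_id, species, total_mass_g, family, length_cm,
#' complete`. `length_cm` may be empty for partly digested items; prey lengths
#' enter comparisons only when `complete` is `TRUE` (item intact from head to
#' tail). Samples with zero items can be declared with `family = ""`.
#'
#' @param path Path to a CSV file.
#' @return A list of class `"diet_table"` with elements `samples` (one row per
#'   regurgitate: `sample_id`, `species`, `total_mass_g`, `n_items`) and
#'   `items` (one row per prey item).
#' @export
read_diet_table <- function(path) {
  if (!file.exists(path)) stop("diet table not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_diet_table(raw)
}

#' Validate an in-memory diet table
#'
#' @param x A data.frame in the long one-row-per-item layout of
#'   [read_diet_table()].
#' @return A `"diet_table"`; see [read_diet_table()].
#' @export
validate_diet_table <- function(x) {
  missing_cols <- setdiff(setdiff(DIET_COLUMNS, "length_cm"), names(x))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"length_cm" %in% names(x)) x$length_cm <- NA_real_
  if (any(!is.finite(x$total_mass_g))) stop("total_mass_g must be finite", call. = FALSE)
  if (any(x$total_mass_g < 0)) stop("total_mass_g must be >= 0", call. = FALSE)
  x$complete <- as.logical(x$complete)
  if (any(!is.na(x$length_cm) & x$length_cm <= 0)) {
    stop("length_cm must be > 0 where present", call. = FALSE)
  }
  if ("item" %in% names(x)) {
    key <- paste(x$sample_id, x$item, sep = "\r")
    if (anyDuplicated(key)) {
      stop("duplicated (sample_id, item) pair(s): ",
           paste(unique(x$sample_id[duplicated(key)]), collapse = ", "),
           call. = FALSE)
    }
  }
  # a placeholder row with empty family declares a sample without items
  is_item <- !is.na(x$family) & nzchar(x$family)
  items <- x[is_item, intersect(c("sample_id", "species", "family", "length_cm", "complete"),
                                names(x)), drop = FALSE]
  rownames(items) <- NULL
  per_sample <- x[!duplicated(x$sample_id),
                  c("sample_id", "species", "total_mass_g"), drop = FALSE]
  mass_chk <- tapply(x$total_mass_g, x$sample_id, function(v) length(unique(v)))
  if (any(mass_chk > 1L)) {
    stop("inconsistent total_mass_g within sample(s): ",
         paste(names(mass_chk)[mass_chk > 1L], collapse = ", "), call. = FALSE)
  }
  per_sample$n_items <- as.integer(table(factor(items$sample_id,
                                                levels = per_sample$sample_id)))
  rownames(per_sample) <- NULL
  out <- list(samples = per_sample, items = items)
  class(out) <- "diet_table"
  out
}

#' @export
print.diet_table <- function(x, ...) {
  cat("diet_table:", nrow(x$samples), "samples,", nrow(x$items), "prey items\n")
  print(table(x$samples$species))
  invisible(x)
}

#' Read a run configuration file
#'
#' A flat `key: value` YAML file with any of `seed`, `n_perm`, `ellipse_scale`
#' and optional standardization-coefficient overrides (`slope_c`, `intercept_c`,
#' `slope_n`, `intercept_n`). Missing keys take the package defaults.
#'
#' @param path Path to the YAML file, or `NULL` for all defaults.
#' @return A named list of configuration values.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- list(seed = 1L, n_perm = 9999L, ellipse_scale = "seac")
  if (!is.null(path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a config file requires the 'yaml' package", call. = FALSE)
    }
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_perm <- as.integer(cfg$n_perm)
  stopifnot(cfg$ellipse_scale %in% c("standard", "seac", "p50", "p95"))
  cfg
}

#' Write an analysis report to disk
#'
#' Serializes the tables of an [run_comparison_grid()] report as CSV files plus
#' one JSON summary carrying the run metadata (seed, permutation count, ellipse
#' scale mode). Re-running with identical inputs and seed reproduces the files
#' byte-for-byte.
#'
#' @param report An `"analysis_report"` object.
#' @param out_dir Output directory; created if absent.
#' @return Invisibly, the character vector of files written.
#' @export
write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  files <- character(0)
  emit <- function(df, name) {
    f <- file.path(out_dir, name)
    utils::write.csv(df, f, row.names = FALSE)
    files <<- c(files, f)
  }
  emit(report$comparisons, "comparisons.csv")
  emit(report$ellipses, "ellipses.csv")
  if (!is.null(report$tukey)) emit(report$tukey, "tukey_hsd.csv")
  meta <- report$meta
  jsonlite::write_json(meta, file.path(out_dir, "run.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files <- c(files, file.path(out_dir, "run.json"))
  invisible(files)
}
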
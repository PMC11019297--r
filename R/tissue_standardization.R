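#' Blood-to-feather standardization coefficients
#'
#' Whole blood is isotopically impoverished in 13C and 15N relative to
#' feathers, so comparing breeding-period blood with non-breeding feathers
#' requires a linear standardization of blood values onto the feather scale:
#' d13C_feather = 0.972 d13C_blood + 0.962 and
#' d15N_feather = 1.014 d15N_blood + 0.447 (coefficient standard errors
#' carried as metadata; point estimates are used throughout).
#'
#' @param slope_c,intercept_c,slope_n,intercept_n Linear map coefficients
#'   (slopes dimensionless, intercepts permil). Slopes must be positive.
#' @param slope_c_se,intercept_c_se,slope_n_se,intercept_n_se Standard errors
#'   (metadata only; not propagated).
#' @return A named list of class `"standardization_coefficients"`.
#' @export
standardization_coefficients <- function(slope_c = 0.972, intercept_c = 0.962,
                                         slope_n = 1.014, intercept_n = 0.447,
                                         slope_c_se = 0.020, intercept_c_se = 0.414,
                                         slope_n_se = 0.056, intercept_n_se = 0.414) {
  if (slope_c <= 0 || slope_n <= 0) stop("slopes must be > 0", call. = FALSE)
  structure(list(slope_c = slope_c, intercept_c = intercept_c,
                 slope_n = slope_n, intercept_n = intercept_n,
                 slope_c_se = slope_c_se, intercept_c_se = intercept_c_se,
                 slope_n_se = slope_n_se, intercept_n_se = intercept_n_se),
            class = "standardization_coefficients")
}

#' Convert whole-blood delta values to feather-equivalent values
#'
#' Applies the per-isotope linear standardization of
#' [standardization_coefficients()]. Vectorized over samples.
#'
#' @param d13c_blood,d15n_blood Whole-blood delta values (permil); finite.
#' @param coeffs Coefficients, default the built-in ones.
#' @return A data.frame with columns `d13c` and `d15n` of feather-equivalent
#'   values (permil).
#' @export
#' @examples
#' blood_to_feather(0, 0)    # intercepts: (0.962, 0.447)
#' blood_to_feather(-17, 10)
blood_to_feather <- function(d13c_blood, d15n_blood,
                             coeffs = standardization_coefficients()) {
  stopifnot(inherits(coeffs, "standardization_coefficients"))
  if (any(!is.finite(d13c_blood)) || any(!is.finite(d15n_blood))) {
    stop("inputs must be finite", call. = FALSE)
  }
  data.frame(d13c = coeffs$slope_c * d13c_blood + coeffs$intercept_c,
             d15n = coeffs$slope_n * d15n_blood + coeffs$intercept_n)
}

#' Standardize the whole-blood rows of an isotope table
#'
#' Transforms every `whole_blood` sample to feather-equivalent values and
#' relabels its tissue `feather_equivalent`; `body_feather` samples pass
#' through untouched (feathers are never transformed, and calling
#' [blood_to_feather()] on one is a usage error caught here at the table
#' level). Used by the pipeline for breeding vs non-breeding comparisons only.
#'
#' @param samples An `"isotope_table"`.
#' @param coeffs Coefficients for [blood_to_feather()].
#' @return The table with blood rows transformed and relabelled.
#' @export
standardize_blood_samples <- function(samples, coeffs = standardization_coefficients()) {
  stopifnot(is.data.frame(samples))
  is_blood <- samples$tissue == "whole_blood"
  if (any(samples$tissue == "feather_equivalent")) {
    stop("table already contains feather_equivalent samples; ",
         "standardization must not be applied twice", call. = FALSE)
  }
  if (any(is_blood)) {
    tr <- blood_to_feather(samples$d13c[is_blood], samples$d15n[is_blood], coeffs)
    samples$d13c[is_blood] <- tr$d13c
    samples$d15n[is_blood] <- tr$d15n
    samples$tissue[is_blood] <- "feather_equivalent"
  }
  samples
}
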
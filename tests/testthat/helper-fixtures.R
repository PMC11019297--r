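# Fixture builders shared across the suite. Everything is generated in code;
# no data files are read from disk except the temporary ones written here.

# A minimal well-formed isotope table as a data.frame.
tiny_isotope_df <- function(n = 3L) {
  data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    species = rep(c("masked", "red_footed"), length.out = n),
    sex = rep(c("female", "male"), length.out = n),
    tissue = "whole_blood",
    year = 2017L,
    d13c = seq(-17, -16, length.out = n),
    d15n = seq(13, 15, length.out = n),
    c_n_ratio = 3.1,
    stringsAsFactors = FALSE)
}

write_isotope_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

# Long-format diet rows: `n_samples` regurgitates with `n_items` items each.
tiny_diet_df <- function(n_samples = 2L, n_items = 3L, species = "masked",
                         family = "Exocoetidae", mass = 100) {
  do.call(rbind, lapply(seq_len(n_samples), function(i) {
    data.frame(
      sample_id = sprintf("%s_%02d", species, i), species = species,
      total_mass_g = mass, item = seq_len(n_items), family = family,
      length_cm = 12, complete = TRUE, stringsAsFactors = FALSE)
  }))
}

# A circle or axis-aligned ellipse as a ready-made scaled ellipse, bypassing
# fitting, for geometry oracles.
make_scaled_ellipse <- function(cx = 0, cy = 0, a = 1, b = a, angle = 0,
                                mode = "standard") {
  structure(list(center = c(cx, cy), a = a, b = b, angle = angle,
                 area = pi * a * b, mode = mode),
            class = "scaled_ellipse")
}

# Closed-form lens area of two unit-radius circles with centres `d` apart.
circle_lens_area <- function(d, r = 1) {
  if (d >= 2 * r) return(0)
  2 * r^2 * acos(d / (2 * r)) - (d / 2) * sqrt(4 * r^2 - d^2)
}

# Random non-degenerate scaled ellipse for property tests.
random_scaled_ellipse <- function() {
  make_scaled_ellipse(cx = runif(1, -2, 2), cy = runif(1, -2, 2),
                      a = runif(1, 0.5, 2.5), b = runif(1, 0.3, 1.5),
                      angle = runif(1, 0, pi))
}
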
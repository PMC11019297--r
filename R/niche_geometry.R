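#' Fit a bivariate standard ellipse to a group of isotope observations
#'
#' The standard ellipse of a bivariate sample is the ellipse whose semi-axes
#' are the square roots of the eigenvalues of the sample covariance matrix
#' (denominator n-1), centred on the coordinate-wise mean. Its area
#' SEA = pi * sqrt(lambda1 * lambda2) is the conventional measure of isotopic
#' niche width; the small-sample corrected area is
#' SEAc = SEA * (n-1)/(n-2).
#'
#' @param xy A two-column matrix or data.frame of (d13C, d15N) observations
#'   in permil.
#' @return An object of class `"ellipse_summary"`: list with `centroid`,
#'   `cov` (2x2), `eigenvalues` (lambda1 >= lambda2, permil^2), `orientation`
#'   (radians of the major axis), `sea`, `seac` (permil^2), `n`, and
#'   `degenerate` (`TRUE` when the points are collinear so lambda2 = 0 and
#'   SEA = 0).
#' @export
#' @examples
#' fit_ellipse(cbind(c(1, -1, 0, 0), c(0, 0, 1, -1)))
fit_ellipse <- function(xy) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L) stop("`xy` must have exactly two columns", call. = FALSE)
  if (any(!is.finite(xy))) stop("observations must be finite", call. = FALSE)
  n <- nrow(xy)
  if (n < 3L) {
    stop("insufficient sample: n = ", n,
         " (need n >= 3; SEAc is undefined at n = 2)", call. = FALSE)
  }
  centroid <- colMeans(xy)
  S <- stats::cov(xy)
  eig <- eigen(S, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)  # clip tiny negative rounding error
  degenerate <- lambda[2L] <= .Machine$double.eps * max(lambda[1L], 1)
  if (degenerate) lambda[2L] <- 0
  sea <- pi * sqrt(lambda[1L] * lambda[2L])
  structure(list(
    centroid = setNames(as.numeric(centroid), c("d13c", "d15n")),
    cov = S,
    eigenvalues = lambda,
    orientation = atan2(eig$vectors[2L, 1L], eig$vectors[1L, 1L]),
    sea = sea,
    seac = sea * (n - 1) / (n - 2),
    n = n,
    degenerate = degenerate
  ), class = "ellipse_summary")
}

#' @export
print.ellipse_summary <- function(x, ...) {
  cat(sprintf("standard ellipse (n = %d): centroid (%.3f, %.3f) permil\n",
              x$n, x$centroid[1L], x$centroid[2L]))
  cat(sprintf("  SEA = %.4f permil^2, SEAc = %.4f permil^2%s\n",
              x$sea, x$seac, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Scale a fitted ellipse to a drawing/overlap convention
#'
#' The fitted standard ellipse can be rescaled before computing areas or
#' overlap:
#' * `"standard"` - semi-axes sqrt(lambda_i), area = SEA;
#' * `"seac"` - semi-axes multiplied by sqrt((n-1)/(n-2)) so the area equals
#'   SEAc, the convention used for small-sample-corrected overlap;
#' * `"probability"` - semi-axes multiplied by the square root of the
#'   chi-square(2 df) quantile at `p`, the p-level data ellipse of the fitted
#'   bivariate normal (p = 0.50 and p = 0.95 are the usual plotting levels).
#'
#' @param e An `"ellipse_summary"` from [fit_ellipse()].
#' @param mode One of `"standard"`, `"seac"`, `"probability"` (aliases `"p50"`,
#'   `"p95"` select probability mode at those levels).
#' @param p Probability level in (0, 1) for `mode = "probability"`.
#' @return An object of class `"scaled_ellipse"`: `center`, semi-axes `a >= b`
#'   (permil), `angle` (radians), `area` (permil^2), `mode`.
#' @export
scale_ellipse <- function(e, mode = c("standard", "seac", "probability", "p50", "p95"),
                          p = NULL) {
  stopifnot(inherits(e, "ellipse_summary"))
  mode <- match.arg(mode)
  if (e$degenerate) stop("cannot scale a degenerate (collinear) ellipse", call. = FALSE)
  if (mode == "p50") { mode <- "probability"; p <- 0.50 }
  if (mode == "p95") { mode <- "probability"; p <- 0.95 }
  cc <- switch(mode,
    standard = 1,
    seac = sqrt((e$n - 1) / (e$n - 2)),
    probability = {
      if (is.null(p) || !is.numeric(p) || p <= 0 || p >= 1) {
        stop("probability level `p` must lie in (0, 1)", call. = FALSE)
      }
      sqrt(stats::qchisq(p, df = 2))
    })
  a <- sqrt(e$eigenvalues[1L]) * cc
  b <- sqrt(e$eigenvalues[2L]) * cc
  structure(list(
    center = e$centroid, a = a, b = b, angle = e$orientation,
    area = pi * a * b,
    mode = if (mode == "probability") sprintf("p%.4g", p) else mode
  ), class = "scaled_ellipse")
}

#' Polygonal approximation of a scaled ellipse boundary
#'
#' @param s A `"scaled_ellipse"`.
#' @param n_vertices Number of boundary vertices (inscribed polygon).
#' @return An `n_vertices` x 2 matrix of (x, y) vertices, counter-clockwise.
#' @export
ellipse_polygon <- function(s, n_vertices = 720L) {
  stopifnot(inherits(s, "scaled_ellipse"), n_vertices >= 3L)
  t <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  ca <- cos(s$angle); sa <- sin(s$angle)
  x <- s$a * cos(t); y <- s$b * sin(t)
  cbind(s$center[1L] + ca * x - sa * y,
        s$center[2L] + sa * x + ca * y)
}

# Shoelace area of a simple polygon (vertices in order, not closed).
polygon_area <- function(v) {
  n <- nrow(v)
  if (is.null(n) || n < 3L) return(0)
  x <- v[, 1L]; y <- v[, 2L]
  abs(sum(x * y[c(2:n, 1L)] - x[c(2:n, 1L)] * y)) / 2
}

# Sutherland-Hodgman clipping of polygon `subject` by CONVEX polygon `clip`
# (counter-clockwise). Exact for convex-convex intersection.
clip_convex <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (is.null(out) || nrow(out) == 0L) return(out)
    A <- clip[i, ]; B <- clip[if (i == nc) 1L else i + 1L, ]
    ex <- B[1L] - A[1L]; ey <- B[2L] - A[2L]
    # signed area; >= 0 means inside (left of edge) for CCW clip polygon
    side <- ex * (out[, 2L] - A[2L]) - ey * (out[, 1L] - A[1L])
    n <- nrow(out)
    nxt <- c(2:n, 1L)
    keep <- side >= 0
    cross <- xor(keep, keep[nxt])
    # candidate stream: vertex j, then the edge-(j, j+1) boundary crossing;
    # masked selection keeps polygon order without growing vectors
    t <- side / (side - side[nxt])
    ix <- out[, 1L] + t * (out[nxt, 1L] - out[, 1L])
    iy <- out[, 2L] + t * (out[nxt, 2L] - out[, 2L])
    mask <- as.vector(rbind(keep, cross))
    out <- cbind(as.vector(rbind(out[, 1L], ix))[mask],
                 as.vector(rbind(out[, 2L], iy))[mask])
  }
  out
}

# Squared canonical-frame coordinates: <= 1 inside the ellipse.
ellipse_quadform <- function(s, x, y) {
  ca <- cos(s$angle); sa <- sin(s$angle)
  dx <- x - s$center[1L]; dy <- y - s$center[2L]
  u <- (ca * dx + sa * dy) / s$a
  v <- (-sa * dx + ca * dy) / s$b
  u * u + v * v
}

ellipse_bbox <- function(s) {
  ca <- cos(s$angle); sa <- sin(s$angle)
  hx <- sqrt((s$a * ca)^2 + (s$b * sa)^2)
  hy <- sqrt((s$a * sa)^2 + (s$b * ca)^2)
  c(xmin = unname(s$center[1L]) - hx, xmax = unname(s$center[1L]) + hx,
    ymin = unname(s$center[2L]) - hy, ymax = unname(s$center[2L]) + hy)
}

#' Area of intersection of two scaled ellipses
#'
#' Default method approximates each boundary by an inscribed polygon
#' (`n_vertices` vertices) and clips one against the other
#' (Sutherland-Hodgman; exact for the convex polygons involved). The
#' `"monte_carlo"` method is a seeded stratified rejection sampler over the
#' intersection of the two bounding boxes: one jittered point per grid cell,
#' so sampling noise comes only from boundary cells. It serves as an
#' independent cross-check of the polygonal result.
#'
#' @param s1,s2 `"scaled_ellipse"` objects.
#' @param method `"polygonal"` (default) or `"monte_carlo"`.
#' @param n_vertices Polygon resolution for the polygonal method.
#' @param draws Target number of sample points for the Monte-Carlo method.
#' @param seed RNG seed for the Monte-Carlo method.
#' @return Intersection area in permil^2 (0 when disjoint). Symmetric in its
#'   arguments.
#' @export
intersection_area <- function(s1, s2, method = c("polygonal", "monte_carlo"),
                              n_vertices = 720L, draws = 200000L, seed = 1L) {
  stopifnot(inherits(s1, "scaled_ellipse"), inherits(s2, "scaled_ellipse"))
  if (s1$a <= 0 || s1$b <= 0 || s2$a <= 0 || s2$b <= 0) {
    stop("degenerate geometry: ellipse with zero semi-axis", call. = FALSE)
  }
  method <- match.arg(method)
  b1 <- ellipse_bbox(s1); b2 <- ellipse_bbox(s2)
  xmin <- max(b1["xmin"], b2["xmin"]); xmax <- min(b1["xmax"], b2["xmax"])
  ymin <- max(b1["ymin"], b2["ymin"]); ymax <- min(b1["ymax"], b2["ymax"])
  if (xmin >= xmax || ymin >= ymax) return(0)
  if (method == "polygonal") {
    poly <- clip_convex(ellipse_polygon(s1, n_vertices),
                        ellipse_polygon(s2, n_vertices))
    return(polygon_area(poly))
  }
  # stratified jittered grid over the joint bounding box
  w <- xmax - xmin; h <- ymax - ymin
  nx <- max(2L, round(sqrt(draws * w / h)))
  ny <- max(2L, ceiling(draws / nx))
  with_seed(seed, {
    gx <- rep(seq_len(nx), times = ny)
    gy <- rep(seq_len(ny), each = nx)
    px <- xmin + (gx - stats::runif(nx * ny)) * (w / nx)
    py <- ymin + (gy - stats::runif(nx * ny)) * (h / ny)
    inside <- ellipse_quadform(s1, px, py) <= 1 & ellipse_quadform(s2, px, py) <= 1
    mean(inside) * w * h
  })
}

#' Jaccard niche-overlap index of two scaled ellipses
#'
#' Overlap is quantified as
#' intersection / (area1 + area2 - intersection), i.e. intersection over
#' union: 1 for coincident ellipses, 0 for disjoint ones. A proxy for
#' similarity of resource use between the two groups.
#'
#' @inheritParams intersection_area
#' @param ... Passed on to [intersection_area()].
#' @return An object of class `"overlap_result"`: `area_1`, `area_2`,
#'   `intersection` (permil^2), `jaccard` (proportion), `percent`,
#'   `scale_mode`, `method`.
#' @export
overlap_index <- function(s1, s2, method = c("polygonal", "monte_carlo"), ...) {
  method <- match.arg(method)
  inter <- intersection_area(s1, s2, method = method, ...)
  inter <- min(inter, s1$area, s2$area)  # guard rounding above containment
  jac <- inter / (s1$area + s2$area - inter)
  structure(list(
    area_1 = s1$area, area_2 = s2$area, intersection = inter,
    jaccard = jac, percent = 100 * jac,
    scale_mode = paste(unique(c(s1$mode, s2$mode)), collapse = "/"),
    method = method
  ), class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "overlap (%s, %s): areas %.4f / %.4f, intersection %.4f => Jaccard %.4f (%.1f%%)\n",
    x$scale_mode, x$method, x$area_1, x$area_2, x$intersection, x$jaccard, x$percent))
  invisible(x)
}
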
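# All geometry operates on plain two-column coordinate matrices. Metric
# wrappers pass (f2, f1) so figures and hull vertices live in the
# conventional acoustic plane; areas themselves are axis-order invariant.

.as_coord_matrix <- function(points, what = "points") {
  m <- as.matrix(points)
  if (!is.numeric(m) || ncol(m) != 2) {
    vs_abort(paste0(what, " must be a two-column numeric matrix or data frame"),
             "vowelspace_geometry_error")
  }
  if (anyNA(m) || any(!is.finite(m))) {
    vs_abort(paste0(what, " contain missing or non-finite coordinates"),
             "vowelspace_geometry_error")
  }
  dimnames(m) <- NULL
  m
}

# signed cross product of (a - o) x (b - o)
.cross <- function(ox, oy, ax, ay, bx, by) {
  (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
}

# proper intersection test between segments p1-p2 and p3-p4 (shared endpoints
# between adjacent polygon edges are excluded by the caller)
.segments_cross <- function(p1, p2, p3, p4) {
  d1 <- .cross(p3[1], p3[2], p4[1], p4[2], p1[1], p1[2])
  d2 <- .cross(p3[1], p3[2], p4[1], p4[2], p2[1], p2[2])
  d3 <- .cross(p1[1], p1[2], p2[1], p2[2], p3[1], p3[2])
  d4 <- .cross(p1[1], p1[2], p2[1], p2[2], p4[1], p4[2])
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

.polygon_self_intersects <- function(m) {
  n <- nrow(m)
  if (n < 4) return(FALSE)
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    j <- i + 2
    while (j <= jmax) {
      if (.segments_cross(m[i, ], m[i + 1, ], m[j, ], m[(j %% n) + 1, ])) {
        return(TRUE)
      }
      j <- j + 1
    }
  }
  FALSE
}

#' Area of a polygon by the shoelace formula
#'
#' Computes the absolute shoelace area of a polygon given its vertices in
#' traversal order. The result is invariant to cyclic rotation of the vertex
#' list and to traversal direction. The vertex sequence is additionally
#' screened for self-intersection; a crossing polygon still yields the
#' absolute shoelace value but is flagged, because that value is no longer an
#' enclosed area in the usual sense.
#'
#' @param vertices Two-column numeric matrix or data frame of vertex
#'   coordinates in traversal order (for vowel space work, columns are
#'   (F2, F1) in Hz).
#' @return The area (squared coordinate units) with attribute
#'   `"self_intersecting"` (logical).
#' @examples
#' polygon_area(rbind(c(2500, 300), c(2000, 800), c(1000, 800), c(1000, 300)))
#' @export
polygon_area <- function(vertices) {
  m <- .as_coord_matrix(vertices, "vertices")
  n <- nrow(m)
  if (n < 3) {
    vs_abort("A polygon needs at least 3 vertices.",
             "vowelspace_geometry_error")
  }
  x <- m[, 1]; y <- m[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  area <- abs(sum(x * yn - xn * y)) / 2
  structure(area, self_intersecting = .polygon_self_intersects(m))
}

#' Convex hull of a point set (monotone chain)
#'
#' Andrew's monotone-chain construction of the convex hull. Vertices are
#' returned in counter-clockwise order starting from the lexicographically
#' smallest point; points strictly inside the hull and points lying on a
#' hull edge between two vertices are excluded, so the vertex list is the
#' canonical minimal one.
#'
#' @param points Two-column numeric matrix or data frame (for vowel space
#'   work, (F2, F1) in Hz). Duplicated coordinates are legal and never affect
#'   the hull.
#' @return An object of class `"vowelspace_hull"`: a list with `vertices`
#'   (counter-clockwise coordinate matrix), `area` (squared coordinate
#'   units), and `n_input`.
#' @examples
#' h <- convex_hull(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5)))
#' h$area
#' @export
convex_hull <- function(points) {
  m <- .as_coord_matrix(points)
  u <- unique(m)
  if (nrow(u) < 3) {
    vs_abort("Convex hull needs at least 3 distinct points.",
             "vowelspace_geometry_error")
  }
  ord <- order(u[, 1], u[, 2])
  x <- u[ord, 1]; y <- u[ord, 2]
  idx <- .monotone_chain(x, y)
  if (length(idx) < 3) {
    vs_abort("All points are collinear; the hull is degenerate.",
             "vowelspace_geometry_error")
  }
  vertices <- cbind(x[idx], y[idx])
  structure(
    list(vertices = vertices,
         area = as.numeric(polygon_area(vertices)),
         n_input = nrow(m)),
    class = "vowelspace_hull"
  )
}

# core monotone chain on lexicographically sorted coordinates; returns vertex
# indices counter-clockwise. Strict "> 0" turn test drops collinear boundary
# points.
.monotone_chain <- function(x, y) {
  n <- length(x)
  build <- function(seq_idx) {
    st <- integer(n)
    k <- 0L
    for (i in seq_idx) {
      while (k >= 2L &&
             .cross(x[st[k - 1L]], y[st[k - 1L]],
                    x[st[k]], y[st[k]], x[i], y[i]) <= 0) {
        k <- k - 1L
      }
      k <- k + 1L
      st[k] <- i
    }
    st[seq_len(k)]
  }
  lower <- build(seq_len(n))
  upper <- build(rev(seq_len(n)))
  c(lower[-length(lower)], upper[-length(upper)])
}

#' @export
print.vowelspace_hull <- function(x, ...) {
  cat("Convex hull:", nrow(x$vertices), "vertices from", x$n_input,
      "points; area =", format(x$area), "\n")
  invisible(x)
}

#' Bivariate-normal confidence ellipse for a token cloud
#'
#' Fits the ellipse that would contain a given probability mass of a
#' bivariate normal distribution with the sample mean and covariance of the
#' points: centre at the mean, axes along the covariance eigenvectors, and
#' semi-axis lengths `sqrt(lambda_i * q)` where `q` is the chi-square
#' quantile with 2 degrees of freedom at the requested coverage
#' (q = 5.991 at 0.95).
#'
#' @param points Two-column matrix or data frame, (F2, F1) in Hz.
#' @param coverage Probability mass the ellipse should cover (default 0.95).
#' @return An object of class `"vowelspace_ellipse"`: list with `center`
#'   (length-2, (F2, F1)), `semi_major`, `semi_minor` (Hz), `angle` (radians
#'   of the major axis from the F2 axis, in (-pi/2, pi/2]), `coverage`, `n`.
#' @examples
#' set.seed(1)
#' pts <- cbind(rnorm(200, 1500, 100), rnorm(200, 500, 40))
#' confidence_ellipse(pts)
#' @export
confidence_ellipse <- function(points, coverage = 0.95) {
  m <- .as_coord_matrix(points)
  if (nrow(m) < 3) {
    vs_abort("Confidence ellipse needs at least 3 points.",
             "vowelspace_geometry_error")
  }
  if (!is.numeric(coverage) || length(coverage) != 1 ||
      coverage < 0 || coverage >= 1) {
    vs_abort("coverage must be a probability in [0, 1).",
             "vowelspace_geometry_error")
  }
  S <- cov(m)
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) <= 0 || !all(is.finite(e$values))) {
    vs_abort("Sample covariance is degenerate; no ellipse is defined.",
             "vowelspace_geometry_error")
  }
  q <- qchisq(coverage, df = 2)
  v <- e$vectors[, 1]
  ang <- atan2(v[2], v[1])
  if (ang <= -pi / 2) ang <- ang + pi
  if (ang > pi / 2) ang <- ang - pi
  structure(
    list(center = colMeans(m),
         semi_major = sqrt(e$values[1] * q),
         semi_minor = sqrt(e$values[2] * q),
         angle = ang,
         coverage = coverage,
         n = nrow(m)),
    class = "vowelspace_ellipse"
  )
}

#' @export
print.vowelspace_ellipse <- function(x, ...) {
  cat(sprintf(
    "%.0f%% ellipse: center (%.1f, %.1f), semi-axes %.1f x %.1f, angle %.2f rad (n = %d)\n",
    100 * x$coverage, x$center[1], x$center[2],
    x$semi_major, x$semi_minor, x$angle, x$n))
  invisible(x)
}

#' Polygon outline of a confidence ellipse
#'
#' Discretises an ellipse for plotting or point-in-ellipse work.
#'
#' @param ellipse A `"vowelspace_ellipse"`.
#' @param n Number of outline points.
#' @return A tibble with columns `f2`, `f1` tracing the ellipse.
#' @export
ellipse_outline <- function(ellipse, n = 181) {
  theta <- seq(0, 2 * pi, length.out = n)
  ca <- cos(ellipse$angle); sa <- sin(ellipse$angle)
  ex <- ellipse$semi_major * cos(theta)
  ey <- ellipse$semi_minor * sin(theta)
  tibble::tibble(
    f2 = ellipse$center[1] + ex * ca - ey * sa,
    f1 = ellipse$center[2] + ex * sa + ey * ca
  )
}
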
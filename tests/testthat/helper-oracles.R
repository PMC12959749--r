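# Independent oracles used across the suite. They deliberately share no code
# with the package implementation.

# O(n^3) supporting-line convex hull: a directed pair (i, j) is a hull edge
# iff every other point lies strictly to its left. Returns the vertex
# coordinates sorted lexicographically (set comparison).
brute_hull_vertices <- function(pts) {
  n <- nrow(pts)
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      cr <- (pts[j, 1] - pts[i, 1]) * (pts[, 2] - pts[i, 2]) -
            (pts[j, 2] - pts[i, 2]) * (pts[, 1] - pts[i, 1])
      others <- setdiff(seq_len(n), c(i, j))
      if (all(cr[others] > 0)) on_hull[c(i, j)] <- TRUE
    }
  }
  v <- pts[on_hull, , drop = FALSE]
  v[order(v[, 1], v[, 2]), , drop = FALSE]
}

# shoelace on vertices ordered by angle about the centroid (valid for the
# convex/star-shaped polygons the tests generate)
angle_sorted_area <- function(v) {
  cx <- mean(v[, 1]); cy <- mean(v[, 2])
  o <- order(atan2(v[, 2] - cy, v[, 1] - cx))
  x <- v[o, 1]; y <- v[o, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# vectorised even-odd crossing test
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Monte-Carlo rejection-sampling polygon area
mc_polygon_area <- function(vx, vy, n_samples = 1e6) {
  xr <- range(vx); yr <- range(vy)
  px <- runif(n_samples, xr[1], xr[2])
  py <- runif(n_samples, yr[1], yr[2])
  mean(points_in_polygon(px, py, vx, vy)) * diff(xr) * diff(yr)
}

# random simple (star-shaped) polygon: random points ordered by angle
random_simple_polygon <- function(n_vertices) {
  pts <- cbind(runif(n_vertices), runif(n_vertices))
  cx <- mean(pts[, 1]); cy <- mean(pts[, 2])
  pts[order(atan2(pts[, 2] - cy, pts[, 1] - cx)), , drop = FALSE]
}

# minimal well-formed token table builder
make_tokens <- function(speaker = "S1", session = "baseline",
                        vowel = "IY", repetition = NULL,
                        f1 = c(460, 465, 461), f2 = c(1800, 1815, 1812)) {
  k <- max(length(f1), length(f2))
  tibble::tibble(
    speaker = speaker, session = session, vowel = vowel,
    repetition = if (is.null(repetition)) seq_len(k) else repetition,
    f1_hz = f1, f2_hz = f2
  )
}

# a full 10-vowel, 3-repetition speaker-session around the packaged DS
# group means, with deterministic within-vowel offsets
full_session_tokens <- function(speaker = "S1", session = "baseline",
                                jitter = 5) {
  g <- load_group_formants("DS")
  dplyr::bind_rows(lapply(seq_len(10), function(v) {
    make_tokens(
      speaker = speaker, session = session, vowel = g$vowel[v],
      f1 = g$f1_mean[v] + jitter * c(-1, 0, 1),
      f2 = g$f2_mean[v] + jitter * c(1, -1, 0)
    )
  }))
}

write_temp_csv <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- tempfile(fileext = ".csv", tmpdir = dir)
  readr::write_csv(df, path, progress = FALSE)
  path
}
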
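# Accepts tokens/means tables or a bare two-column (f1, f2) object and
# returns a numeric matrix with columns f1, f2.
.formant_matrix <- function(x) {
  if (is.data.frame(x)) {
    nm <- names(x)
    f1col <- intersect(c("f1_hz", "f1_mean", "f1"), nm)[1]
    f2col <- intersect(c("f2_hz", "f2_mean", "f2"), nm)[1]
    if (!is.na(f1col) && !is.na(f2col)) {
      return(.as_coord_matrix(cbind(x[[f1col]], x[[f2col]]), "formant values"))
    }
  }
  .as_coord_matrix(x, "formant values")
}

#' Articulatory-acoustic vowel space (AAVS)
#'
#' The square root of the generalised variance of the (F1, F2) values: with
#' `S` the 2x2 sample covariance matrix (denominator n - 1) of the supplied
#' points, AAVS = sqrt(det(S)) in Hz^2. It is a dispersion measure over the
#' whole vowel system — translation invariant, and zero exactly when the
#' points are collinear (the determinant is clamped at a relative tolerance
#' of 1e-12 so numerically collinear data give an exact zero).
#'
#' @param points Tokens or means table (any of the column pairs
#'   `f1_hz`/`f2_hz`, `f1_mean`/`f2_mean`, `f1`/`f2`), or a bare two-column
#'   (f1, f2) matrix. At least 3 points. Duplicated points are legal and
#'   contribute covariance weight.
#' @return AAVS in Hz^2 (non-negative scalar).
#' @examples
#' compute_aavs(cbind(c(0, 0, 2, 2), c(0, 2, 0, 2)))  # 4/3
#' @export
compute_aavs <- function(points) {
  m <- .formant_matrix(points)
  if (nrow(m) < 3) {
    vs_abort("AAVS needs at least 3 tokens.", "vowelspace_insufficient_data")
  }
  S <- cov(m)
  d <- S[1, 1] * S[2, 2] - S[1, 2]^2
  if (d <= 1e-12 * S[1, 1] * S[2, 2]) d <- 0
  sqrt(d)
}

#' Quadrilateral vowel space area (qVSA)
#'
#' The shoelace area of the quadrilateral through the mean (F2, F1)
#' coordinates of the four corner vowels, traversed in the fixed perimeter
#' order IY -> AE -> AA -> UW (high front, low front, low back, high back).
#' If the four means happen to form a crossing quadrilateral — possible in
#' severely centralised speech — the absolute shoelace value is still
#' returned but flagged via the `"self_intersecting"` attribute.
#'
#' @param means Per-vowel mean table for a single speaker-session
#'   ([compute_vowel_means()] layout) containing all four corner vowels.
#' @return qVSA in Hz^2, with attribute `"self_intersecting"`.
#' @examples
#' means <- tibble::tibble(
#'   speaker = "A", session = "baseline",
#'   vowel = c("IY", "AE", "AA", "UW"),
#'   f1_mean = c(300, 800, 800, 300),
#'   f2_mean = c(2500, 2000, 1000, 1000),
#'   n_tokens = 3L
#' )
#' compute_qvsa(means)  # 625000
#' @export
compute_qvsa <- function(means) {
  if (!is.data.frame(means) ||
      !all(c("vowel", "f1_mean", "f2_mean") %in% names(means))) {
    vs_abort("means must be a per-vowel mean table (see compute_vowel_means).",
             "vowelspace_geometry_error")
  }
  if (all(c("speaker", "session") %in% names(means)) &&
      nrow(unique(means[, c("speaker", "session")])) > 1) {
    vs_abort("compute_qvsa() expects means for a single speaker-session.",
             "vowelspace_geometry_error")
  }
  corners <- corner_vowels()
  missing <- setdiff(corners, means$vowel)
  if (length(missing) > 0) {
    vs_abort(paste0("Missing corner vowel(s): ",
                    paste(missing, collapse = ", ")),
             "vowelspace_missing_corner")
  }
  rows <- means[match(corners, means$vowel), ]
  polygon_area(cbind(rows$f2_mean, rows$f1_mean))
}

#' Convex-hull vowel space area (VSAhull)
#'
#' The area of the smallest convex polygon enclosing every vowel token of a
#' speaker-session in the (F2, F1) plane, all vowels pooled. Captures the
#' maximum articulatory reach rather than corner-vowel positions alone.
#'
#' @param tokens Token table for one speaker-session (or any table with
#'   formant columns); at least 3 non-collinear tokens.
#' @return VSAhull in Hz^2.
#' @export
compute_vsa_hull <- function(tokens) {
  m <- .formant_matrix(tokens)
  convex_hull(cbind(m[, 2], m[, 1]))$area
}

#' All three vowel space metrics per speaker-session
#'
#' Computes AAVS, qVSA and VSAhull for every (speaker, session) group in the
#' token table. qVSA is always computed on per-vowel means; VSAhull is always
#' computed on the pooled tokens; AAVS follows `mode`: over all tokens
#' (`"tokens"`, the default — the dispersion across every production) or
#' over the per-vowel means (`"means"` — the dispersion of vowel targets,
#' insensitive to within-vowel scatter). A metric that cannot be computed
#' for a group (e.g. a missing corner vowel for qVSA) is returned as `NA`
#' with an explanatory note, never as zero.
#'
#' @param tokens Token table covering one or more speaker-sessions.
#' @param mode `"tokens"` or `"means"`; AAVS input convention, recorded in
#'   the output.
#' @return A tibble with one row per (speaker, session): `speaker`,
#'   `session`, `mode`, `aavs`, `qvsa`, `vsahull` (Hz^2), `n_tokens`,
#'   `notes` (empty string when all three metrics computed cleanly).
#' @examples
#' cohort <- generate_tokens(cohort_config(n_speakers = 2, seed = 42))
#' session_metrics(cohort)
#' @export
session_metrics <- function(tokens, mode = c("tokens", "means")) {
  mode <- match.arg(mode)
  if (is.null(tokens) || nrow(tokens) == 0) {
    vs_abort("No tokens supplied.", "vowelspace_empty_error")
  }
  groups <- unique(tokens[, c("speaker", "session")])
  groups <- groups[order(groups$speaker, match(groups$session, session_levels())), ]
  res <- lapply(seq_len(nrow(groups)), function(i) {
    sub <- tokens[tokens$speaker == groups$speaker[i] &
                    tokens$session == groups$session[i], ]
    notes <- character(0)
    try_metric <- function(expr) {
      tryCatch(as.numeric(expr), vowelspace_error = function(e) {
        notes <<- c(notes, conditionMessage(e))
        NA_real_
      })
    }
    means <- compute_vowel_means(sub)
    aavs <- try_metric(
      if (mode == "tokens") compute_aavs(sub) else compute_aavs(means)
    )
    qvsa <- try_metric(compute_qvsa(means))
    vsahull <- try_metric(compute_vsa_hull(sub))
    tibble::tibble(
      speaker = groups$speaker[i], session = groups$session[i], mode = mode,
      aavs = aavs, qvsa = qvsa, vsahull = vsahull,
      n_tokens = nrow(sub), notes = paste(notes, collapse = "; ")
    )
  })
  dplyr::bind_rows(res)
}

#' Per-vowel formant shift vectors between sessions
#'
#' For every vowel present in both mean tables, the movement of its mean
#' position from baseline to post: `d_f1 = post - baseline` (and likewise
#' `d_f2`), in Hz. These are the arrow coordinates of a vowel-shift figure
#' (tail at baseline, head at post).
#'
#' @param baseline,post Per-vowel mean tables ([compute_vowel_means()]
#'   layout) for the same speaker or for group averages.
#' @return A tibble `vowel`, `d_f1`, `d_f2`, plus the baseline coordinates
#'   `f1_baseline`, `f2_baseline` for plotting. Vowels absent from either
#'   session are dropped; if no vowel is shared the result is empty and a
#'   warning is raised.
#' @export
shift_vectors <- function(baseline, post) {
  shared <- intersect(unique(baseline$vowel), unique(post$vowel))
  if (length(shared) == 0) {
    vs_warn("No vowels shared between sessions; no shift vectors.",
            "vowelspace_empty_warning")
    return(tibble::tibble(vowel = character(0), d_f1 = numeric(0),
                          d_f2 = numeric(0), f1_baseline = numeric(0),
                          f2_baseline = numeric(0)))
  }
  b <- baseline[match(shared, baseline$vowel), ]
  p <- post[match(shared, post$vowel), ]
  tibble::tibble(
    vowel = shared,
    d_f1 = p$f1_mean - b$f1_mean,
    d_f2 = p$f2_mean - b$f2_mean,
    f1_baseline = b$f1_mean,
    f2_baseline = b$f2_mean
  )
}

# corner-vowel positions in inventory order (IY, AE, AA, UW); pinned to
# match(corner_vowels(), vowel_inventory()$code) by a test
.corner_idx <- c(1L, 5L, 10L, 7L)

# fast metric kernel used by the simulation harness: f1/f2 numeric vectors,
# vidx integer vowel index (1..10). Same arithmetic as the exported metrics;
# equality is pinned by tests.
.session_metrics_fast <- function(f1, f2, vidx, mode = "tokens",
                                  corner_idx = .corner_idx) {
  cnt <- tabulate(vidx, nbins = 10L)
  m1 <- rowsum(f1, vidx, reorder = TRUE) / cnt[sort(unique(vidx))]
  m2 <- rowsum(f2, vidx, reorder = TRUE) / cnt[sort(unique(vidx))]
  # aavs
  if (mode == "tokens") { a1 <- f1; a2 <- f2 } else { a1 <- m1[, 1]; a2 <- m2[, 1] }
  n <- length(a1)
  c1 <- a1 - sum(a1) / n; c2 <- a2 - sum(a2) / n
  s11 <- sum(c1 * c1) / (n - 1); s22 <- sum(c2 * c2) / (n - 1)
  s12 <- sum(c1 * c2) / (n - 1)
  d <- s11 * s22 - s12^2
  if (d <= 1e-12 * s11 * s22) d <- 0
  aavs <- sqrt(d)
  # qvsa: shoelace over corner means in fixed order
  present <- sort(unique(vidx))
  ci <- match(corner_idx, present)
  qx <- m2[ci, 1]; qy <- m1[ci, 1]
  qvsa <- abs(sum(qx * c(qy[-1], qy[1]) - c(qx[-1], qx[1]) * qy)) / 2
  # hull over pooled tokens in (f2, f1)
  u <- unique(cbind(f2, f1))
  ord <- order(u[, 1], u[, 2])
  hidx <- .monotone_chain(u[ord, 1], u[ord, 2])
  hx <- u[ord, 1][hidx]; hy <- u[ord, 2][hidx]
  vsahull <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  c(aavs = aavs, qvsa = qvsa, vsahull = vsahull)
}
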
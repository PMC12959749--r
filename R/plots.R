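# All figures use the traditional vowel-chart orientation: F2 on x and F1 on
# y, both axes reversed, so high vowels sit at the top and front vowels at
# the right. Figures are deterministic (fixed ordering, no jitter).

.vowel_axes <- function() {
  list(
    ggplot2::scale_x_reverse(name = "F2 (Hz)"),
    ggplot2::scale_y_reverse(name = "F1 (Hz)")
  )
}

.ipa_labels <- function(codes) {
  inv <- vowel_inventory()
  inv$ipa[match(codes, inv$code)]
}

#' Vowel space overlay plot
#'
#' Plots per-vowel mean positions for one or more groups/speakers in the
#' (F2, F1) plane with IPA labels — e.g. a clinical cohort against reference
#' norms, or baseline against post session.
#'
#' @param means One or more per-vowel mean tables row-bound together
#'   ([compute_vowel_means()] or [load_group_formants()] layout); the
#'   `speaker` column distinguishes the overlaid sets.
#' @param connect_hull Draw the convex hull outline of each set's means.
#' @return A ggplot object.
#' @examples
#' plot_vowel_space(rbind(load_group_formants("DS"), load_group_formants("TD")))
#' @export
plot_vowel_space <- function(means, connect_hull = TRUE) {
  means <- dplyr::arrange(means, .data$speaker, .data$vowel)
  means$label <- .ipa_labels(means$vowel)
  p <- ggplot2::ggplot(
    means, ggplot2::aes(x = .data$f2_mean, y = .data$f1_mean,
                        colour = .data$speaker)
  ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       nudge_y = -18, show.legend = FALSE) +
    .vowel_axes() +
    ggplot2::labs(colour = NULL) +
    ggplot2::theme_minimal()
  if (connect_hull) {
    hulls <- dplyr::bind_rows(lapply(split(means, means$speaker), function(g) {
      if (nrow(unique(g[, c("f2_mean", "f1_mean")])) < 3) return(NULL)
      h <- convex_hull(cbind(g$f2_mean, g$f1_mean))
      tibble::tibble(speaker = g$speaker[1],
                     f2_mean = h$vertices[, 1], f1_mean = h$vertices[, 2])
    }))
    if (nrow(hulls) > 0) {
      p <- p + ggplot2::geom_polygon(
        data = hulls, fill = NA, linetype = "dashed", show.legend = FALSE
      )
    }
  }
  p
}

#' Formant shift-arrow plot
#'
#' Shows per-vowel movement between sessions as arrows in the (F2, F1)
#' plane: tail at the baseline mean, head at the post mean.
#'
#' @param baseline,post Per-vowel mean tables for the two sessions.
#' @return A ggplot object. The arrow coordinates are the
#'   [shift_vectors()] table and can be written alongside the figure.
#' @export
plot_shift_arrows <- function(baseline, post) {
  sv <- shift_vectors(baseline, post)
  sv$label <- .ipa_labels(sv$vowel)
  ggplot2::ggplot(
    sv, ggplot2::aes(x = .data$f2_baseline, y = .data$f1_baseline)
  ) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$f2_baseline + .data$d_f2,
                   yend = .data$f1_baseline + .data$d_f1),
      arrow = grid::arrow(length = grid::unit(2.5, "mm")),
      colour = "grey30"
    ) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), nudge_y = -15) +
    .vowel_axes() +
    ggplot2::theme_minimal()
}

#' Per-vowel token dispersion with confidence ellipses
#'
#' One panel per vowel showing individual tokens by session, overlaid with
#' bivariate-normal confidence ellipses at the requested coverage. Vowels
#' (or sessions) with too few tokens for an ellipse are drawn without one.
#'
#' @param tokens Token table covering one or both sessions.
#' @param coverage Ellipse coverage probability (default 0.95).
#' @return A ggplot object.
#' @export
plot_token_ellipses <- function(tokens, coverage = 0.95) {
  tokens <- dplyr::arrange(tokens, .data$vowel, .data$session,
                           .data$speaker, .data$repetition)
  cells <- unique(tokens[, c("vowel", "session")])
  outlines <- dplyr::bind_rows(lapply(seq_len(nrow(cells)), function(i) {
    sub <- tokens[tokens$vowel == cells$vowel[i] &
                    tokens$session == cells$session[i], ]
    ell <- tryCatch(
      confidence_ellipse(cbind(sub$f2_hz, sub$f1_hz), coverage),
      vowelspace_error = function(e) NULL
    )
    if (is.null(ell)) return(NULL)
    out <- ellipse_outline(ell)
    out$vowel <- cells$vowel[i]
    out$session <- cells$session[i]
    out
  }))
  p <- ggplot2::ggplot(
    tokens, ggplot2::aes(x = .data$f2_hz, y = .data$f1_hz,
                         colour = .data$session)
  ) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    .vowel_axes() +
    ggplot2::facet_wrap(~vowel, scales = "free") +
    ggplot2::labs(colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(outlines) && nrow(outlines) > 0) {
    p <- p + ggplot2::geom_path(
      data = outlines,
      ggplot2::aes(x = .data$f2, y = .data$f1, colour = .data$session),
      inherit.aes = FALSE
    )
  }
  p
}
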
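.predictor_cols <- c("d_aavs", "d_qvsa", "d_vsahull")

#' Pre/post change scores joined with intelligibility gains
#'
#' Builds the regression table: for each speaker with metrics in both
#' sessions and a gain score, the change in each vowel space metric
#' (post minus baseline) alongside the intelligibility gain. Speakers
#' missing a session, a metric value, or a gain score are excluded and
#' reported via the `"excluded"` attribute — exclusion is visible, never
#' silent.
#'
#' @param metrics Metric table from [session_metrics()] covering both
#'   sessions.
#' @param gains A tibble with columns `speaker` and `wcab_ae_gain` (the
#'   per-speaker intelligibility gain score).
#' @return A tibble `speaker`, `d_aavs`, `d_qvsa`, `d_vsahull`,
#'   `wcab_ae_gain`, with attribute `"excluded"` (tibble of `speaker`,
#'   `reason`).
#' @export
compute_change_scores <- function(metrics, gains) {
  excluded <- tibble::tibble(speaker = character(0), reason = character(0))
  exclude <- function(speaker, reason) {
    excluded <<- dplyr::bind_rows(excluded,
                                  tibble::tibble(speaker = speaker,
                                                 reason = reason))
  }
  wide <- tidyr::pivot_wider(
    metrics[, c("speaker", "session", "aavs", "qvsa", "vsahull")],
    names_from = "session", values_from = c("aavs", "qvsa", "vsahull")
  )
  speakers <- unique(metrics$speaker)
  rows <- lapply(speakers, function(sp) {
    w <- wide[wide$speaker == sp, ]
    needed <- c("aavs_baseline", "aavs_post", "qvsa_baseline", "qvsa_post",
                "vsahull_baseline", "vsahull_post")
    if (!all(needed %in% names(w))) {
      exclude(sp, "missing session"); return(NULL)
    }
    vals <- unlist(w[1, needed])
    if (anyNA(vals)) {
      exclude(sp, paste0("missing metric value(s): ",
                         paste(needed[is.na(vals)], collapse = ", ")))
      return(NULL)
    }
    g <- gains$wcab_ae_gain[match(sp, gains$speaker)]
    if (length(g) != 1 || is.na(g)) {
      exclude(sp, "missing gain score"); return(NULL)
    }
    tibble::tibble(
      speaker = sp,
      d_aavs = vals[["aavs_post"]] - vals[["aavs_baseline"]],
      d_qvsa = vals[["qvsa_post"]] - vals[["qvsa_baseline"]],
      d_vsahull = vals[["vsahull_post"]] - vals[["vsahull_baseline"]],
      wcab_ae_gain = g
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    vs_abort("No speaker has both sessions' metrics and a gain score.",
             "vowelspace_empty_error")
  }
  attr(out, "excluded") <- excluded
  out
}

#' Ordinary least squares model of intelligibility gain
#'
#' Fits `wcab_ae_gain ~ d_aavs + d_qvsa + d_vsahull` by ordinary least
#' squares with intercept, via the QR decomposition in [stats::lm()].
#' Standard errors come from the classical covariance
#' `sigma^2 (X'X)^(-1)` with `sigma^2 = RSS / df_resid`; p-values are
#' two-sided from the t distribution with `df_resid = n - 4` degrees of
#' freedom. The gain score is treated as a continuous response.
#'
#' @param records Change-score table ([compute_change_scores()] layout or
#'   [load_change_records()]), n >= 5.
#' @return An object of class `"intelligibility_fit"`: list with `terms`
#'   (tibble: `term`, `estimate`, `std_error`, `t_value`, `p_value` in
#'   model order), `n`, `df_resid`, `r_squared`, `adj_r_squared`, `sigma`,
#'   `residuals`, `fitted`, `data`, and the underlying `lm` object as `fit`.
#' @examples
#' fit <- fit_intelligibility_model(load_change_records())
#' fit
#' @export
fit_intelligibility_model <- function(records) {
  needed <- c(.predictor_cols, "wcab_ae_gain")
  if (!is.data.frame(records) || !all(needed %in% names(records))) {
    vs_abort(paste0("records must contain columns ",
                    paste(needed, collapse = ", ")),
             "vowelspace_model_error")
  }
  if (anyNA(records[needed]) ||
      !all(vapply(records[needed], function(x) all(is.finite(x)), logical(1)))) {
    vs_abort("Change scores and gains must be finite and non-missing.",
             "vowelspace_model_error")
  }
  n <- nrow(records)
  if (n < 5) {
    vs_abort(paste0("At least 5 speakers are needed to fit the 4-parameter ",
                    "model (got ", n, ")."),
             "vowelspace_insufficient_data")
  }
  fit <- lm(wcab_ae_gain ~ d_aavs + d_qvsa + d_vsahull,
            data = as.data.frame(records))
  if (fit$rank < 4) {
    aliased <- names(which(is.na(coef(fit))))
    vs_abort(paste0("Predictors are perfectly collinear; dependent column(s): ",
                    paste(aliased, collapse = ", ")),
             "vowelspace_collinearity_error")
  }
  # suppress summary.lm's "essentially perfect fit" chatter: exact linear
  # data is a legitimate input (noise-free simulations)
  s <- suppressWarnings(summary(fit))
  co <- s$coefficients
  structure(
    list(
      terms = tibble::tibble(
        term = rownames(co),
        estimate = unname(co[, 1]), std_error = unname(co[, 2]),
        t_value = unname(co[, 3]), p_value = unname(co[, 4])
      ),
      n = n,
      df_resid = fit$df.residual,
      r_squared = s$r.squared,
      adj_r_squared = s$adj.r.squared,
      sigma = s$sigma,
      residuals = unname(fit$residuals),
      fitted = unname(fit$fitted.values),
      data = records,
      fit = fit
    ),
    class = "intelligibility_fit"
  )
}

#' @export
print.intelligibility_fit <- function(x, ...) {
  cat("Intelligibility-gain model: wcab_ae_gain ~ d_aavs + d_qvsa + d_vsahull\n")
  cat(sprintf("n = %d, residual df = %d, R-squared = %.3f (adj. %.3f)\n\n",
              x$n, x$df_resid, x$r_squared, x$adj_r_squared))
  tab <- x$terms
  out <- data.frame(
    Predictor = tab$term,
    Estimate = formatC(tab$estimate, format = "f", digits = 5),
    Std_Error = formatC(tab$std_error, format = "f", digits = 6),
    t_value = formatC(tab$t_value, format = "f", digits = 3),
    p_value = formatC(tab$p_value, format = "f", digits = 4)
  )
  print(out, row.names = FALSE)
  invisible(x)
}

#' Variance inflation factors for the three change-score predictors
#'
#' Quantifies multicollinearity: for each predictor j, regress it on the
#' other two (with intercept) and report `VIF_j = 1 / (1 - R_j^2)`. A VIF of
#' 1 means no shared variance; large values mean the predictor is nearly a
#' linear combination of the others and its coefficient is unstable. A
#' perfectly collinear predictor yields `Inf` and is flagged.
#'
#' @param records Change-score table, or an `"intelligibility_fit"`.
#' @return A tibble `predictor`, `vif`, `collinear` (logical flag for
#'   infinite VIF).
#' @examples
#' compute_vif(load_change_records())
#' @export
compute_vif <- function(records) {
  if (inherits(records, "intelligibility_fit")) records <- records$data
  X <- records[.predictor_cols]
  if (any(vapply(X, function(v) sd(v) == 0 || !all(is.finite(v)), logical(1)))) {
    vs_abort("A predictor is constant or non-finite; VIF is undefined.",
             "vowelspace_degenerate_predictor")
  }
  vifs <- vapply(.predictor_cols, function(j) {
    others <- setdiff(.predictor_cols, j)
    aux <- lm(stats::reformulate(others, response = j), data = as.data.frame(X))
    r2 <- suppressWarnings(summary(aux))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  tibble::tibble(
    predictor = .predictor_cols,
    vif = unname(vifs),
    collinear = !is.finite(unname(vifs))
  )
}

#' Numeric residual diagnostics for the gain model
#'
#' Numeric counterparts of the visual regression checks: Shapiro-Wilk for
#' normality of residuals, the studentised Breusch-Pagan test for
#' heteroscedasticity, and the slope of |residual| on fitted values (zero
#' under homoscedasticity). Also returns the four standard diagnostic plot
#' datasets as plain tibbles for reporting.
#'
#' @param result An `"intelligibility_fit"` with at least 3 residual degrees
#'   of freedom.
#' @return An object of class `"residual_diagnostics"`: list with
#'   `normality` (statistic, p_value), `heteroscedasticity` (statistic,
#'   p_value), `abs_resid_slope`, and `plot_data` (tibbles
#'   `resid_vs_fitted`, `qq`, `scale_location`, `leverage`).
#' @export
residual_diagnostics <- function(result) {
  if (!inherits(result, "intelligibility_fit")) {
    vs_abort("result must come from fit_intelligibility_model().",
             "vowelspace_model_error")
  }
  if (result$df_resid < 3) {
    vs_abort("At least 3 residual degrees of freedom are needed.",
             "vowelspace_insufficient_data")
  }
  res <- result$residuals
  sw <- shapiro.test(res)
  bp <- lmtest::bptest(result$fit)
  slope <- unname(coef(lm(abs(res) ~ result$fitted))[2])
  h <- unname(stats::hatvalues(result$fit))
  std_res <- unname(stats::rstandard(result$fit))
  qq <- stats::qqnorm(std_res, plot.it = FALSE)
  structure(
    list(
      normality = list(statistic = unname(sw$statistic),
                       p_value = sw$p.value),
      heteroscedasticity = list(statistic = unname(bp$statistic),
                                p_value = bp$p.value),
      abs_resid_slope = slope,
      plot_data = list(
        resid_vs_fitted = tibble::tibble(fitted = result$fitted,
                                         residual = res),
        qq = tibble::tibble(theoretical = qq$x, sample = qq$y),
        scale_location = tibble::tibble(fitted = result$fitted,
                                        sqrt_abs_std_resid = sqrt(abs(std_res))),
        leverage = tibble::tibble(leverage = h, std_residual = std_res,
                                  cooks_d = unname(stats::cooks.distance(result$fit)))
      )
    ),
    class = "residual_diagnostics"
  )
}

#' @export
print.residual_diagnostics <- function(x, ...) {
  cat(sprintf("Shapiro-Wilk normality: W = %.4f, p = %.4f\n",
              x$normality$statistic, x$normality$p_value))
  cat(sprintf("Breusch-Pagan heteroscedasticity: BP = %.4f, p = %.4f\n",
              x$heteroscedasticity$statistic, x$heteroscedasticity$p_value))
  cat(sprintf("Slope of |residual| on fitted: %.4g\n", x$abs_resid_slope))
  invisible(x)
}
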
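#' Run the full acoustic-to-intelligibility pipeline
#'
#' Executes the analysis end to end: read and validate the baseline and post
#' formant tables and the gain-score table, compute per-session vowel space
#' metrics, derive change scores, fit the intelligibility-gain model with
#' VIF and residual diagnostics, and write all artefacts (metric and change
#' tables, machine-readable model report, text report, figures, run log) to
#' an output directory. Stage failures are re-raised with the stage name
#' after partial outputs and a failure marker are written, so a broken run
#' leaves an inspectable trail.
#'
#' @param baseline_path,post_path Paths to token CSVs for the two sessions
#'   (a single combined table may be given as `baseline_path` with
#'   `post_path = NULL`).
#' @param gains_path Path to a CSV with columns `speaker`, `wcab_ae_gain`.
#' @param out_dir Output directory (created if needed).
#' @param aavs_mode AAVS input convention, `"tokens"` or `"means"`.
#' @param coverage Ellipse coverage for the dispersion figure.
#' @param figures Write figures (PDF) and their data tables.
#' @param verbose Also print log lines to the console.
#' @return Invisibly, a list with `metrics`, `changes`, `fit`, `vif`,
#'   `diagnostics`, and the paths written.
#' @export
run_pipeline <- function(baseline_path, post_path = NULL, gains_path,
                         out_dir, aavs_mode = c("tokens", "means"),
                         coverage = 0.95, figures = TRUE, verbose = FALSE) {
  aavs_mode <- match.arg(aavs_mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  say <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    log_lines <<- c(log_lines, line)
    writeLines(log_lines, log_path)
    if (verbose) message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      say("FAILED at stage '%s': %s", name, conditionMessage(e))
      writeLines(paste0("failed at stage: ", name),
                 file.path(out_dir, "FAILED"))
      vs_abort(paste0("Pipeline stage '", name, "' failed: ",
                      conditionMessage(e)), "vowelspace_pipeline_error")
    })
  }

  tokens <- stage("read", {
    tok <- read_formant_table(baseline_path)
    if (!is.null(post_path)) {
      tok <- dplyr::bind_rows(tok, read_formant_table(post_path))
    }
    tok
  })
  issues <- validate_formant_tokens(tokens)
  say("read %d tokens (%d validation warnings)", nrow(tokens), nrow(issues))
  for (i in seq_len(nrow(issues))) {
    say("warning: row %d (%s/%s/%s rep %d): %s", issues$row[i],
        issues$speaker[i], issues$session[i], issues$vowel[i],
        issues$repetition[i], issues$message[i])
  }
  gains <- stage("read-gains", {
    g <- readr::read_csv(gains_path, show_col_types = FALSE, progress = FALSE)
    if (!all(c("speaker", "wcab_ae_gain") %in% names(g))) {
      vs_abort("gains table needs columns speaker, wcab_ae_gain",
               "vowelspace_schema_error")
    }
    g
  })

  metrics <- stage("metrics", session_metrics(tokens, mode = aavs_mode))
  readr::write_csv(metrics, file.path(out_dir, "metrics.csv"), progress = FALSE)
  say("computed metrics for %d speaker-sessions", nrow(metrics))

  changes <- stage("change-scores", compute_change_scores(metrics, gains))
  excluded <- attr(changes, "excluded")
  for (i in seq_len(nrow(excluded))) {
    say("excluded speaker %s: %s", excluded$speaker[i], excluded$reason[i])
  }
  say("change scores for %d speakers (%d excluded)", nrow(changes),
      nrow(excluded))
  readr::write_csv(changes, file.path(out_dir, "changes.csv"), progress = FALSE)

  fit <- stage("model", fit_intelligibility_model(changes))
  vif <- stage("model", compute_vif(changes))
  diagnostics <- stage("model", residual_diagnostics(fit))
  say("model fitted: n = %d, R-squared = %.3f", fit$n, fit$r_squared)

  model_json <- list(
    model = "wcab_ae_gain ~ d_aavs + d_qvsa + d_vsahull",
    n = fit$n, df_resid = fit$df_resid,
    r_squared = fit$r_squared, adj_r_squared = fit$adj_r_squared,
    sigma = fit$sigma,
    coefficients = fit$terms,
    vif = vif,
    diagnostics = list(
      shapiro_wilk = fit_diag_pair(diagnostics$normality),
      breusch_pagan = fit_diag_pair(diagnostics$heteroscedasticity),
      abs_resid_slope = diagnostics$abs_resid_slope
    ),
    excluded_speakers = excluded,
    package_version = as.character(utils::packageVersion("vowelspace"))
  )
  jsonlite::write_json(model_json, file.path(out_dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  report <- render_report(fit, vif = vif, changes = changes,
                          diagnostics = diagnostics)
  writeLines(report, file.path(out_dir, "report.txt"))

  paths <- c(metrics = file.path(out_dir, "metrics.csv"),
             changes = file.path(out_dir, "changes.csv"),
             model = file.path(out_dir, "model.json"),
             report = file.path(out_dir, "report.txt"),
             log = log_path)

  if (figures) {
    means <- compute_vowel_means(tokens)
    grand <- means |>
      dplyr::group_by(.data$session, .data$vowel) |>
      dplyr::summarise(f1_mean = mean(.data$f1_mean),
                       f2_mean = mean(.data$f2_mean),
                       n_tokens = sum(.data$n_tokens), .groups = "drop")
    grand$speaker <- paste0("group-", grand$session)
    fig <- function(name, plot_obj, data_tbl) {
      pdf_path <- file.path(out_dir, paste0(name, ".pdf"))
      # cairo renders the IPA glyphs the default pdf device cannot
      ggplot2::ggsave(pdf_path, plot_obj, width = 7, height = 5,
                      device = grDevices::cairo_pdf)
      readr::write_csv(data_tbl, file.path(out_dir, paste0(name, "_data.csv")),
                       progress = FALSE)
      pdf_path
    }
    base_means <- grand[grand$session == "baseline", ]
    post_means <- grand[grand$session == "post", ]
    figs <- c(
      overlay = stage("figures", fig("vowel_space_overlay",
                                     plot_vowel_space(grand), grand)),
      arrows = if (nrow(post_means) > 0) {
        stage("figures", fig("vowel_shift_arrows",
                             plot_shift_arrows(base_means, post_means),
                             shift_vectors(base_means, post_means)))
      },
      ellipses = stage("figures", fig("vowel_dispersion",
                                      plot_token_ellipses(tokens, coverage),
                                      tokens))
    )
    paths <- c(paths, figs)
    say("wrote %d figures", length(figs))
  }

  say("pipeline complete")
  invisible(list(metrics = metrics, changes = changes, fit = fit, vif = vif,
                 diagnostics = diagnostics, paths = paths))
}

fit_diag_pair <- function(x) list(statistic = x$statistic, p_value = x$p_value)

#' Render a plain-text analysis report
#'
#' Formats the fitted model, VIFs, diagnostics and (optionally) the
#' per-speaker change table as an aligned text report. Estimates are shown
#' to 5 decimals, t statistics to 3 and p-values to 4, mirroring
#' conventional regression-table formatting; full-precision values stay in
#' the machine-readable `model.json`.
#'
#' @param fit An `"intelligibility_fit"`.
#' @param vif Optional VIF table from [compute_vif()].
#' @param changes Optional change-score table.
#' @param diagnostics Optional [residual_diagnostics()] result.
#' @param seed Optional seed to stamp into the report.
#' @return Character vector of report lines.
#' @export
render_report <- function(fit, vif = NULL, changes = NULL,
                          diagnostics = NULL, seed = NULL) {
  if (!inherits(fit, "intelligibility_fit")) {
    vs_abort("fit must come from fit_intelligibility_model().",
             "vowelspace_model_error")
  }
  lines <- c(
    "Vowel space change and intelligibility gain",
    paste0("vowelspace ", utils::packageVersion("vowelspace"),
           " | generated ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    if (!is.null(seed)) paste0("seed: ", seed),
    ""
  )
  if (!is.null(changes)) {
    tab <- data.frame(
      Speaker = changes$speaker,
      d_AAVS = formatC(changes$d_aavs, format = "f", digits = 2),
      d_qVSA = formatC(changes$d_qvsa, format = "f", digits = 2),
      d_VSAhull = formatC(changes$d_vsahull, format = "f", digits = 2),
      Gain = changes$wcab_ae_gain
    )
    lines <- c(lines, "Per-speaker change scores:",
               utils::capture.output(print(tab, row.names = FALSE)), "")
  }
  co <- data.frame(
    Predictor = fit$terms$term,
    Estimate = formatC(fit$terms$estimate, format = "f", digits = 5),
    Std_Error = formatC(fit$terms$std_error, format = "f", digits = 6),
    t_value = formatC(fit$terms$t_value, format = "f", digits = 3),
    p_value = formatC(fit$terms$p_value, format = "f", digits = 4)
  )
  lines <- c(
    lines,
    "Model: wcab_ae_gain ~ d_aavs + d_qvsa + d_vsahull",
    sprintf("n = %d, residual df = %d, R-squared = %.4f (adj. %.4f), sigma = %.4f",
            fit$n, fit$df_resid, fit$r_squared, fit$adj_r_squared, fit$sigma),
    utils::capture.output(print(co, row.names = FALSE)), ""
  )
  if (!is.null(vif)) {
    lines <- c(lines, "Variance inflation factors:",
               sprintf("  %-10s %.3f", vif$predictor, vif$vif), "")
  }
  if (!is.null(diagnostics)) {
    lines <- c(
      lines, "Residual diagnostics:",
      sprintf("  Shapiro-Wilk W = %.4f, p = %.4f",
              diagnostics$normality$statistic, diagnostics$normality$p_value),
      sprintf("  Breusch-Pagan BP = %.4f, p = %.4f",
              diagnostics$heteroscedasticity$statistic,
              diagnostics$heteroscedasticity$p_value),
      sprintf("  |residual| vs fitted slope = %.4g",
              diagnostics$abs_resid_slope)
    )
  }
  lines
}
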
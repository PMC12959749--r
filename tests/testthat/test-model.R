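fake_metrics <- function(speakers, base, post) {
  dplyr::bind_rows(
    tibble::tibble(speaker = speakers, session = "baseline", mode = "tokens",
                   aavs = base[, 1], qvsa = base[, 2], vsahull = base[, 3],
                   n_tokens = 30L, notes = ""),
    tibble::tibble(speaker = speakers, session = "post", mode = "tokens",
                   aavs = post[, 1], qvsa = post[, 2], vsahull = post[, 3],
                   n_tokens = 30L, notes = "")
  )
}

test_that("change scores are post minus baseline, joined with gains", {
  base <- cbind(100, 200, 300)
  post <- cbind(150, 180, 330)
  m <- fake_metrics("A", base, post)
  gains <- tibble::tibble(speaker = "A", wcab_ae_gain = 5)
  cs <- compute_change_scores(m, gains)
  expect_equal(cs$d_aavs, 50)
  expect_equal(cs$d_qvsa, -20)
  expect_equal(cs$d_vsahull, 30)
  expect_equal(cs$wcab_ae_gain, 5)

  same <- compute_change_scores(fake_metrics("A", base, base), gains)
  expect_equal(unlist(same[, c("d_aavs", "d_qvsa", "d_vsahull")]),
               c(d_aavs = 0, d_qvsa = 0, d_vsahull = 0))
})

test_that("speakers missing a session, metric, or gain are excluded and reported", {
  base <- rbind(c(100, 200, 300), c(110, 210, 310), c(120, 220, 320))
  post <- rbind(c(105, 190, 330), c(NA, 205, 315), c(118, 230, 340))
  m <- fake_metrics(c("A", "B", "C"), base, post)
  m <- m[!(m$speaker == "C" & m$session == "post"), ]  # C has no post session
  gains <- tibble::tibble(speaker = c("A", "B"), wcab_ae_gain = c(1, 2))
  cs <- compute_change_scores(m, gains)
  expect_equal(cs$speaker, "A")
  excluded <- attr(cs, "excluded")
  expect_setequal(excluded$speaker, c("B", "C"))

  no_overlap <- tibble::tibble(speaker = "Z", wcab_ae_gain = 1)
  expect_error(compute_change_scores(m, no_overlap),
               class = "vowelspace_empty_error")
})

test_that("change scores on a synthetic cohort match a spreadsheet-style recomputation", {
  cfg <- cohort_config(n_speakers = 5, token_sd = 40, seed = 71)
  tokens <- generate_tokens(cfg)
  metrics <- session_metrics(tokens)
  gains <- tibble::tibble(speaker = unique(tokens$speaker),
                          wcab_ae_gain = seq_len(5))
  cs <- compute_change_scores(metrics, gains)
  # independent recomputation straight from the metric table
  for (sp in cs$speaker) {
    for (col in c("aavs", "qvsa", "vsahull")) {
      d <- metrics[[col]][metrics$speaker == sp & metrics$session == "post"] -
        metrics[[col]][metrics$speaker == sp & metrics$session == "baseline"]
      expect_equal(cs[[paste0("d_", col)]][cs$speaker == sp], d)
    }
  }
})

test_that("exact linear data is recovered exactly with R-squared 1", {
  set.seed(702)
  rec <- tibble::tibble(
    speaker = sprintf("S%02d", 1:10),
    d_aavs = rnorm(10, 0, 1000),
    d_qvsa = rnorm(10, 0, 5000),
    d_vsahull = rnorm(10, 0, 20000)
  )
  rec$wcab_ae_gain <- 2 + 0.001 * rec$d_aavs
  fit <- fit_intelligibility_model(rec)
  expect_equal(fit$terms$estimate, c(2, 0.001, 0, 0), tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("OLS output matches an explicit normal-equations oracle", {
  set.seed(703)
  for (k in seq_len(10)) {
    n <- sample(6:15, 1)
    rec <- tibble::tibble(
      speaker = sprintf("S%02d", seq_len(n)),
      d_aavs = rnorm(n, 0, 2e4),
      d_qvsa = rnorm(n, 0, 1e5),
      d_vsahull = rnorm(n, 0, 2e5)
    )
    rec$wcab_ae_gain <- rnorm(n, 0, 4)
    fit <- fit_intelligibility_model(rec)
    X <- cbind(1, rec$d_aavs, rec$d_qvsa, rec$d_vsahull)
    y <- rec$wcab_ae_gain
    beta <- solve(t(X) %*% X, t(X) %*% y)[, 1]
    resid <- y - X %*% beta
    sigma2 <- sum(resid^2) / (n - 4)
    se <- sqrt(diag(sigma2 * solve(t(X) %*% X)))
    tval <- beta / se
    pval <- 2 * pt(abs(tval), df = n - 4, lower.tail = FALSE)
    expect_equal(fit$terms$estimate, unname(beta), tolerance = 1e-8)
    expect_equal(fit$terms$std_error, unname(se), tolerance = 1e-8)
    expect_equal(fit$terms$t_value, unname(tval), tolerance = 1e-8)
    expect_equal(fit$terms$p_value, unname(pval), tolerance = 1e-8)
    # normal equations: residuals orthogonal to the design columns
    expect_lt(max(abs(t(X) %*% fit$residuals)) / sqrt(sum(y^2)), 1e-8)
    expect_lt(abs(sum(fit$residuals)), 1e-8 * sqrt(sum(y^2)))
    expect_equal(fit$df_resid, n - 4L)
  }
})

test_that("degenerate designs raise informative model errors", {
  rec <- load_change_records()
  expect_error(fit_intelligibility_model(rec[1:4, ]),
               class = "vowelspace_insufficient_data")
  dup <- rec
  dup$d_qvsa <- 2 * dup$d_aavs
  expect_error(fit_intelligibility_model(dup),
               class = "vowelspace_collinearity_error")
  nas <- rec
  nas$d_aavs[3] <- NA
  expect_error(fit_intelligibility_model(nas), class = "vowelspace_model_error")
})

test_that("estimates are invariant to record order and equivariant to rescaling", {
  rec <- load_change_records()
  f0 <- fit_intelligibility_model(rec)
  set.seed(704)
  for (k in seq_len(5)) {
    fp <- fit_intelligibility_model(rec[sample(nrow(rec)), ])
    expect_equal(fp$terms, f0$terms)
  }
  expect_equal(compute_vif(rec[sample(nrow(rec)), ]), compute_vif(rec))

  scaled <- rec
  scaled$d_aavs <- rec$d_aavs * 1000
  fs <- fit_intelligibility_model(scaled)
  i <- match("d_aavs", fs$terms$term)
  expect_equal(fs$terms$estimate[i], f0$terms$estimate[i] / 1000)
  expect_equal(fs$terms$std_error[i], f0$terms$std_error[i] / 1000)
  expect_equal(fs$terms$t_value[i], f0$terms$t_value[i])
  expect_equal(fs$terms$p_value[i], f0$terms$p_value[i])
})

test_that("VIFs follow the auxiliary-regression definition", {
  # orthogonal centred predictors share no variance
  ortho <- tibble::tibble(
    speaker = sprintf("S%d", 1:8),
    d_aavs = c(1, 1, 1, 1, -1, -1, -1, -1),
    d_qvsa = c(1, 1, -1, -1, 1, 1, -1, -1),
    d_vsahull = c(1, -1, 1, -1, 1, -1, 1, -1),
    wcab_ae_gain = rnorm(8)
  )
  v <- compute_vif(ortho)
  expect_equal(v$vif, rep(1, 3))
  expect_false(any(v$collinear))

  dup <- ortho
  dup$d_qvsa <- -3 * dup$d_aavs
  vd <- compute_vif(dup)
  expect_true(all(is.infinite(vd$vif[vd$predictor %in% c("d_aavs", "d_qvsa")])))
  expect_true(any(vd$collinear))

  const <- ortho
  const$d_vsahull <- 7
  expect_error(compute_vif(const), class = "vowelspace_degenerate_predictor")
})

test_that("VIFs agree with the car package on the published records", {
  skip_if_not_installed("car")
  rec <- load_change_records()
  mine <- compute_vif(rec)
  theirs <- car::vif(lm(wcab_ae_gain ~ d_aavs + d_qvsa + d_vsahull,
                        data = rec))
  expect_equal(mine$vif, unname(theirs[mine$predictor]), tolerance = 1e-10)
  # all VIFs >= 1 by construction
  expect_true(all(mine$vif >= 1))
})

test_that("diagnostics are well calibrated under normal residuals", {
  set.seed(705)
  reject <- 0
  for (k in seq_len(100)) {
    p <- shapiro.test(rnorm(500))$p.value
    if (p <= 0.05) reject <- reject + 1
  }
  expect_lte(reject, 10)  # normality should be accepted in >= 90% of draws
})

test_that("a symmetric residual pattern yields a zero |residual|-on-fitted slope", {
  rec <- tibble::tibble(
    speaker = sprintf("S%d", 1:8),
    d_aavs = rep(c(10, 20, 30, 40), each = 2),
    d_qvsa = rep(c(5, -5, 15, -15), each = 2),
    d_vsahull = rep(c(100, 50, -50, -100), each = 2)
  )
  e <- rep(c(1, -1), 4)  # orthogonal to the pair-constant design columns
  rec$wcab_ae_gain <- 1 + 0.1 * rec$d_aavs + e
  fit <- fit_intelligibility_model(rec)
  expect_equal(fit$residuals, e, tolerance = 1e-8)
  d <- residual_diagnostics(fit)
  expect_equal(d$abs_resid_slope, 0, tolerance = 1e-8)
})

test_that("diagnostics on the published cohort fit are finite with df 9", {
  fit <- fit_intelligibility_model(load_change_records())
  expect_equal(fit$df_resid, 9L)
  d <- residual_diagnostics(fit)
  expect_true(is.finite(d$normality$statistic))
  expect_true(d$normality$p_value >= 0 && d$normality$p_value <= 1)
  expect_true(is.finite(d$heteroscedasticity$statistic))
  expect_true(d$heteroscedasticity$p_value >= 0 &&
                d$heteroscedasticity$p_value <= 1)
  expect_true(is.finite(d$abs_resid_slope))
  expect_equal(nrow(d$plot_data$resid_vs_fitted), 13)
  expect_equal(nrow(d$plot_data$qq), 13)
  expect_equal(nrow(d$plot_data$leverage), 13)
})

test_that("confidence intervals attain nominal coverage on simulated cohorts", {
  rec <- recover_parameters(cohort_config(n_speakers = 60, seed = 706), 200)
  expect_equal(rec$n_failed, 0)
  expect_true(all(rec$summary$ci_coverage > 0.90))
  expect_true(all(rec$summary$ci_coverage < 0.99))
  expect_true(all(abs(rec$summary$bias) <= 3 * rec$summary$bias_mc_se))
})
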
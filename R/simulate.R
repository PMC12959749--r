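#' Configuration for a synthetic speaker cohort
#'
#' Describes a two-session, ten-vowel, repeated-production elicitation
#' design and a linear outcome model, so the whole pipeline can be exercised
#' and validated without access to raw recordings. A token's formants are
#'
#' `(f1, f2) = vowel target + speaker offset + session shift (post only) + token noise`
#'
#' with the speaker offset a single (f1, f2) translation per speaker
#' (translation leaves all three metrics invariant, cleanly separating
#' speaker identity from vowel-space size) and token noise drawn from a
#' per-vowel bivariate normal. A speaker's intelligibility gain is then
#' `beta0 + beta . (d_aavs, d_qvsa, d_vsahull) + N(0, outcome_sd)` with the
#' change scores computed from the speaker's own tokens.
#'
#' Defaults mirror the study cohort the package models: 13 speakers, 3
#' repetitions of each of the 10 /hVt/ vowels per session, vowel targets at
#' the published Down-syndrome baseline group means, outcome coefficients at
#' the published regression estimates, and outcome noise at the published
#' fit's residual scale (4.05 gain units). No published values exist for
#' within-vowel token scatter or between-speaker offsets, so their defaults
#' (60 Hz and 50 Hz) are illustrative, chosen as plausible magnitudes for
#' child vowel formants; session shifts default to zero because the study's
#' per-vowel shift magnitudes are not printed as numbers.
#'
#' @param n_speakers Number of speakers (>= 1).
#' @param vowel_targets Per-vowel target means: tibble with `vowel`, `f1`,
#'   `f2` covering the full inventory. Default: published DS baseline means.
#' @param speaker_sd SD (Hz) of the per-speaker (f1, f2) translation.
#' @param token_sd Within-vowel token noise: a scalar SD in Hz (isotropic,
#'   shared by all vowels), a length-10 vector of per-vowel isotropic SDs in
#'   inventory order, or a named list of per-vowel 2x2 covariance matrices
#'   (Hz^2).
#' @param session_shift Per-vowel (d_f1, d_f2) added at the post session:
#'   `NULL` for none, or a tibble with `vowel`, `d_f1`, `d_f2`.
#' @param reps Tokens per vowel per session (>= 1; the study design uses 3).
#' @param outcome_coefs Length-4 numeric: intercept, then coefficients on
#'   (d_aavs, d_qvsa, d_vsahull) in gain units per Hz^2.
#' @param outcome_sd SD of the gain noise (gain units).
#' @param aavs_mode AAVS input convention used when computing the change
#'   scores that drive the outcome (`"tokens"` or `"means"`).
#' @param seed Integer seed; the cohort is bit-reproducible given
#'   (config, seed).
#' @return A `"cohort_config"` list.
#' @examples
#' cohort_config(n_speakers = 5, seed = 7)
#' @export
cohort_config <- function(n_speakers = 13,
                          vowel_targets = NULL,
                          speaker_sd = 50,
                          token_sd = 60,
                          session_shift = NULL,
                          reps = 3,
                          outcome_coefs = c(intercept = -0.027,
                                            d_aavs = -0.00022,
                                            d_qvsa = -0.00001,
                                            d_vsahull = 0.00004),
                          outcome_sd = 4.05,
                          aavs_mode = c("tokens", "means"),
                          seed = 1) {
  aavs_mode <- match.arg(aavs_mode)
  inv <- vowel_inventory()
  if (is.null(vowel_targets)) {
    g <- load_group_formants("DS")
    vowel_targets <- tibble::tibble(vowel = g$vowel, f1 = g$f1_mean,
                                    f2 = g$f2_mean)
  }
  problems <- character(0)
  if (!is.numeric(n_speakers) || length(n_speakers) != 1 || n_speakers < 1 ||
      n_speakers != round(n_speakers)) {
    problems <- c(problems, "n_speakers must be a positive integer")
  }
  if (!is.numeric(reps) || length(reps) != 1 || reps < 1 ||
      reps != round(reps)) {
    problems <- c(problems, "reps must be a positive integer")
  }
  if (!is.numeric(speaker_sd) || length(speaker_sd) != 1 || speaker_sd < 0) {
    problems <- c(problems, "speaker_sd must be a non-negative scalar")
  }
  if (!is.numeric(outcome_sd) || length(outcome_sd) != 1 || outcome_sd < 0) {
    problems <- c(problems, "outcome_sd must be a non-negative scalar")
  }
  if (!is.numeric(outcome_coefs) || length(outcome_coefs) != 4 ||
      anyNA(outcome_coefs)) {
    problems <- c(problems, "outcome_coefs must be 4 finite numbers")
  }
  if (!is.data.frame(vowel_targets) ||
      !all(c("vowel", "f1", "f2") %in% names(vowel_targets)) ||
      !setequal(vowel_targets$vowel, inv$code)) {
    problems <- c(problems,
                  "vowel_targets must cover the full 10-vowel inventory")
  }
  if (!is.numeric(seed) || length(seed) != 1 || seed != round(seed)) {
    problems <- c(problems, "seed must be an integer")
  }
  cov_list <- tryCatch(.token_cov_list(token_sd, inv$code),
                       error = function(e) {
                         problems <<- c(problems, conditionMessage(e))
                         NULL
                       })
  if (!is.null(session_shift)) {
    if (!is.data.frame(session_shift) ||
        !all(c("vowel", "d_f1", "d_f2") %in% names(session_shift))) {
      problems <- c(problems,
                    "session_shift must have columns vowel, d_f1, d_f2")
    }
  }
  if (length(problems) > 0) {
    vs_abort(paste0("Invalid cohort configuration: ",
                    paste(problems, collapse = "; ")),
             "vowelspace_config_error")
  }
  targets <- vowel_targets[match(inv$code, vowel_targets$vowel), ]
  shift <- matrix(0, nrow = 10, ncol = 2,
                  dimnames = list(inv$code, c("d_f1", "d_f2")))
  if (!is.null(session_shift)) {
    i <- match(session_shift$vowel, inv$code)
    shift[i, 1] <- session_shift$d_f1
    shift[i, 2] <- session_shift$d_f2
  }
  structure(
    list(n_speakers = as.integer(n_speakers),
         targets = cbind(f1 = targets$f1, f2 = targets$f2),
         speaker_sd = speaker_sd,
         token_chol = lapply(cov_list, .cov_factor),
         token_cov = cov_list,
         session_shift = shift,
         reps = as.integer(reps),
         outcome_coefs = unname(outcome_coefs),
         outcome_sd = outcome_sd,
         aavs_mode = aavs_mode,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# matrix square root usable for singular (e.g. zero-noise) covariances:
# returns t with t' t = S, applied as noise %*% t
.cov_factor <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  diag(sqrt(pmax(e$values, 0))) %*% t(e$vectors)
}

# normalise the token_sd argument to a list of 10 per-vowel 2x2 covariances
.token_cov_list <- function(token_sd, codes) {
  iso <- function(s) diag(c(s^2, s^2))
  if (is.numeric(token_sd) && length(token_sd) == 1) {
    if (token_sd < 0) stop("token_sd must be non-negative")
    return(stats::setNames(rep(list(iso(token_sd)), 10), codes))
  }
  if (is.numeric(token_sd) && length(token_sd) == 10) {
    if (any(token_sd < 0)) stop("token_sd must be non-negative")
    return(stats::setNames(lapply(token_sd, iso), codes))
  }
  if (is.list(token_sd) && length(token_sd) == 10) {
    if (!setequal(names(token_sd), codes)) {
      stop("per-vowel token_sd list must be named by the 10 vowel codes")
    }
    ok <- vapply(token_sd, function(S) {
      is.matrix(S) && all(dim(S) == 2) && isSymmetric(S) &&
        all(eigen(S, only.values = TRUE)$values >= 0)
    }, logical(1))
    if (!all(ok)) stop("each token_sd covariance must be 2x2 positive semi-definite")
    return(token_sd[codes])
  }
  stop("token_sd must be a scalar SD, 10 per-vowel SDs, or 10 2x2 covariances")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort config: %d speakers x 2 sessions x 10 vowels x %d reps (seed %d)\n",
    x$n_speakers, x$reps, x$seed))
  cat(sprintf("speaker_sd = %g Hz, outcome_sd = %g, aavs mode = %s\n",
              x$speaker_sd, x$outcome_sd, x$aavs_mode))
  invisible(x)
}

# one shared stream per cohort, split into independent per-speaker and
# outcome substream seeds so generation is order-independent
.cohort_seeds <- function(config) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  list(speakers = sample.int(.Machine$integer.max - 1L, config$n_speakers),
       outcome = sample.int(.Machine$integer.max - 1L, 1L))
}

.speaker_ids <- function(n) sprintf("S%03d", seq_len(n))

# raw per-speaker draw: returns list(f1, f2, session, vidx) for the 2 x 10 x
# reps tokens of one speaker, in fixed (session, vowel, rep) order
.generate_speaker <- function(config, speaker_seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(speaker_seed)
  reps <- config$reps
  per_session <- 10L * reps
  offset <- rnorm(2, 0, config$speaker_sd)
  vidx <- rep(rep(1:10, each = reps), times = 2)
  sess <- rep(session_levels(), each = per_session)
  noise <- matrix(rnorm(2L * 2L * per_session), ncol = 2)
  # per-vowel covariance via the Cholesky factor
  for (v in 1:10) {
    rows <- which(vidx == v)
    noise[rows, ] <- noise[rows, , drop = FALSE] %*% config$token_chol[[v]]
  }
  f1 <- config$targets[vidx, 1] + offset[1] + noise[, 1] +
    ifelse(sess == "post", config$session_shift[vidx, 1], 0)
  f2 <- config$targets[vidx, 2] + offset[2] + noise[, 2] +
    ifelse(sess == "post", config$session_shift[vidx, 2], 0)
  list(f1 = f1, f2 = f2, session = sess, vidx = vidx,
       repetition = rep(rep(seq_len(reps), times = 10), times = 2))
}

#' Generate synthetic formant tokens for a cohort
#'
#' Draws the full token table for a synthetic cohort: both sessions, all ten
#' vowels, `reps` repetitions per vowel per speaker. Regeneration from the
#' same configuration (including seed) is bit-identical, and each speaker's
#' draws come from an independent substream, so cohorts of different sizes
#' share their leading speakers.
#'
#' @param config A [cohort_config()].
#' @return A token tibble in [read_formant_table()] layout
#'   (`speaker`, `session`, `vowel`, `repetition`, `f1_hz`, `f2_hz`), with
#'   the configuration attached as attribute `"config"`.
#' @examples
#' tokens <- generate_tokens(cohort_config(n_speakers = 2, seed = 11))
#' nrow(tokens)  # 2 speakers x 2 sessions x 10 vowels x 3 reps
#' @export
generate_tokens <- function(config) {
  if (!inherits(config, "cohort_config")) {
    vs_abort("config must come from cohort_config().", "vowelspace_config_error")
  }
  seeds <- .cohort_seeds(config)
  inv <- vowel_inventory()
  ids <- .speaker_ids(config$n_speakers)
  parts <- lapply(seq_len(config$n_speakers), function(i) {
    d <- .generate_speaker(config, seeds$speakers[i])
    tibble::tibble(
      speaker = ids[i],
      session = d$session,
      vowel = inv$code[d$vidx],
      repetition = as.integer(d$repetition),
      f1_hz = d$f1,
      f2_hz = d$f2
    )
  })
  out <- dplyr::bind_rows(parts)
  attr(out, "config") <- config
  out
}

#' Simulate intelligibility gains for a synthetic cohort
#'
#' Computes each speaker's true vowel-space change scores from the generated
#' tokens (via [session_metrics()] and [compute_change_scores()]-style
#' subtraction) and draws gains from the configured linear outcome model:
#' `gain = beta0 + beta . deltas + N(0, outcome_sd)`. The gain noise comes
#' from its own substream, so the same tokens always receive the same gains.
#'
#' @param tokens Token table from [generate_tokens()] (both sessions per
#'   speaker).
#' @param config The [cohort_config()] used to generate the tokens.
#' @return A tibble `speaker`, `d_aavs`, `d_qvsa`, `d_vsahull` (the true
#'   change scores), and `wcab_ae_gain` (the simulated gain) — directly
#'   usable by [fit_intelligibility_model()].
#' @export
simulate_gains <- function(tokens, config) {
  if (!inherits(config, "cohort_config")) {
    vs_abort("config must come from cohort_config().", "vowelspace_config_error")
  }
  seeds <- .cohort_seeds(config)
  metrics <- session_metrics(tokens, mode = config$aavs_mode)
  deltas <- .deltas_from_metrics(metrics)
  .gains_from_deltas(deltas, config, seeds$outcome)
}

.deltas_from_metrics <- function(metrics) {
  wide <- tidyr::pivot_wider(
    metrics[, c("speaker", "session", "aavs", "qvsa", "vsahull")],
    names_from = "session", values_from = c("aavs", "qvsa", "vsahull")
  )
  tibble::tibble(
    speaker = wide$speaker,
    d_aavs = wide$aavs_post - wide$aavs_baseline,
    d_qvsa = wide$qvsa_post - wide$qvsa_baseline,
    d_vsahull = wide$vsahull_post - wide$vsahull_baseline
  )
}

.gains_from_deltas <- function(deltas, config, outcome_seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(outcome_seed)
  b <- config$outcome_coefs
  mu <- b[1] + b[2] * deltas$d_aavs + b[3] * deltas$d_qvsa +
    b[4] * deltas$d_vsahull
  deltas$wcab_ae_gain <- mu + rnorm(nrow(deltas), 0, config$outcome_sd)
  deltas
}

#' Simulate a complete cohort
#'
#' Convenience wrapper: [generate_tokens()] plus [simulate_gains()].
#'
#' @param config A [cohort_config()].
#' @return List with `tokens`, `gains` (change scores + simulated gain per
#'   speaker), and `config`.
#' @export
simulate_cohort <- function(config) {
  tokens <- generate_tokens(config)
  list(tokens = tokens, gains = simulate_gains(tokens, config),
       config = config)
}

#' Parameter recovery study for the gain model
#'
#' Repeatedly generates a cohort, simulates gains, refits the
#' intelligibility model, and summarises how well the generating
#' coefficients are recovered: per-coefficient bias (with its Monte-Carlo
#' standard error), empirical standard error, and the coverage of the
#' classical 95% (or `conf_level`) confidence intervals. This is the
#' package's calibration harness: with a correctly specified linear model
#' the bias should be statistically zero and coverage should match the
#' nominal level.
#'
#' Each replicate draws from an independent substream derived from the
#' configuration seed, and uses a fast internal metric kernel whose
#' equality with the exported metric functions is pinned by the test suite.
#'
#' @param config A [cohort_config()]; its `outcome_coefs` are the true
#'   values being recovered.
#' @param n_replicates Number of replicates (>= 1).
#' @param conf_level Confidence level for the coverage check.
#' @return An object of class `"recovery_summary"`: list with `summary`
#'   (tibble: `term`, `true_value`, `mean_estimate`, `bias`, `bias_mc_se`,
#'   `empirical_se`, `ci_coverage`), `estimates` (replicate x term matrix),
#'   `n_replicates`, `n_failed`, `config`.
#' @examples
#' \donttest{
#' rec <- recover_parameters(cohort_config(n_speakers = 30, seed = 3), 50)
#' rec$summary
#' }
#' @export
recover_parameters <- function(config, n_replicates, conf_level = 0.95) {
  if (!inherits(config, "cohort_config")) {
    vs_abort("config must come from cohort_config().", "vowelspace_config_error")
  }
  if (!is.numeric(n_replicates) || n_replicates < 1) {
    vs_abort("n_replicates must be >= 1.", "vowelspace_config_error")
  }
  n_replicates <- as.integer(n_replicates)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  terms <- c("(Intercept)", .predictor_cols)
  est <- matrix(NA_real_, n_replicates, 4, dimnames = list(NULL, terms))
  se <- est
  failed <- 0L
  tcrit <- qt(1 - (1 - conf_level) / 2, df = config$n_speakers - 4)
  for (r in seq_len(n_replicates)) {
    res <- tryCatch(.one_replicate(config, rep_seeds[r]),
                    error = function(e) NULL)
    if (is.null(res)) { failed <- failed + 1L; next }
    est[r, ] <- res$estimate
    se[r, ] <- res$std_error
  }
  ok <- !is.na(est[, 1])
  true <- config$outcome_coefs
  cover <- vapply(1:4, function(j) {
    mean(abs(est[ok, j] - true[j]) <= tcrit * se[ok, j])
  }, numeric(1))
  emp_se <- apply(est[ok, , drop = FALSE], 2, sd)
  bias <- colMeans(est[ok, , drop = FALSE]) - true
  structure(
    list(
      summary = tibble::tibble(
        term = terms,
        true_value = true,
        mean_estimate = unname(colMeans(est[ok, , drop = FALSE])),
        bias = unname(bias),
        bias_mc_se = unname(emp_se / sqrt(sum(ok))),
        empirical_se = unname(emp_se),
        ci_coverage = unname(cover)
      ),
      estimates = est,
      n_replicates = n_replicates,
      n_failed = failed,
      config = config
    ),
    class = "recovery_summary"
  )
}

# one recovery replicate: generate with the replicate seed, compute deltas
# with the fast kernel, draw gains, refit through the exported model fitter
.one_replicate <- function(config, rep_seed) {
  cfg <- config
  cfg$seed <- rep_seed
  seeds <- .cohort_seeds(cfg)
  n <- cfg$n_speakers
  deltas <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    d <- .generate_speaker(cfg, seeds$speakers[i])
    base <- d$session == "baseline"
    mb <- .session_metrics_fast(d$f1[base], d$f2[base], d$vidx[base],
                                mode = cfg$aavs_mode)
    mp <- .session_metrics_fast(d$f1[!base], d$f2[!base], d$vidx[!base],
                                mode = cfg$aavs_mode)
    deltas[i, ] <- mp - mb
  }
  records <- tibble::tibble(
    speaker = .speaker_ids(n),
    d_aavs = deltas[, 1], d_qvsa = deltas[, 2], d_vsahull = deltas[, 3]
  )
  records <- .gains_from_deltas(records, cfg, seeds$outcome)
  fit <- fit_intelligibility_model(records)
  fit$terms
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf(
    "Parameter recovery: %d replicates of %d speakers (%d failed)\n",
    x$n_replicates, x$config$n_speakers, x$n_failed))
  print(as.data.frame(x$summary), row.names = FALSE, digits = 4)
  invisible(x)
}
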
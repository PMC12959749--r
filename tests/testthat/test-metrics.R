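test_that("AAVS matches the 2x2 determinant closed forms", {
  # independent axes: each marginal sample variance 4/3, covariance 0
  sq <- cbind(c(0, 0, 2, 2), c(0, 2, 0, 2))
  expect_equal(compute_aavs(sq), 4 / 3)
  # identical points: no variance
  expect_equal(compute_aavs(cbind(rep(500, 4), rep(1500, 4))), 0)
  # five hand-picked points against an elementwise covariance oracle
  f1 <- c(480, 620, 750, 530, 900)
  f2 <- c(1810, 1750, 1620, 1680, 1500)
  s11 <- sum((f1 - mean(f1))^2) / 4
  s22 <- sum((f2 - mean(f2))^2) / 4
  s12 <- sum((f1 - mean(f1)) * (f2 - mean(f2))) / 4
  expect_equal(compute_aavs(cbind(f1, f2)), sqrt(s11 * s22 - s12^2))
  expect_error(compute_aavs(cbind(c(1, 2), c(3, 4))),
               class = "vowelspace_insufficient_data")
})

test_that("AAVS is exactly zero on collinear inputs", {
  set.seed(501)
  for (k in seq_len(50)) {
    x <- runif(sample(3:20, 1), 200, 2000)
    a <- runif(1, -2, 2); b <- runif(1, 100, 900)
    expect_identical(compute_aavs(cbind(a * x + b, x)), 0)
  }
})

test_that("qVSA traverses corners in fixed order and flags degeneracies", {
  trap <- tibble::tibble(
    speaker = "A", session = "baseline",
    vowel = c("IY", "AE", "AA", "UW"),
    f1_mean = c(300, 800, 800, 300),
    f2_mean = c(2500, 2000, 1000, 1000),
    n_tokens = 3L
  )
  expect_equal(as.numeric(compute_qvsa(trap)), 625000)
  # order of rows in the table must not matter
  expect_equal(as.numeric(compute_qvsa(trap[c(3, 1, 4, 2), ])), 625000)

  # collapsed quadrilateral
  point <- trap
  point$f1_mean <- 500; point$f2_mean <- 1500
  expect_equal(as.numeric(compute_qvsa(point)), 0)

  expect_error(compute_qvsa(trap[trap$vowel != "UW", ]),
               class = "vowelspace_missing_corner")
  expect_error(compute_qvsa(trap[trap$vowel != "UW", ]), "UW")
})

test_that("qVSA of the published group corner means matches hand shoelace", {
  ds <- load_group_formants("DS")
  expect_equal(as.numeric(compute_qvsa(ds)), 116996)
})

test_that("VSAhull pools all tokens and ignores duplicates", {
  ds <- load_group_formants("DS")
  mean_pts <- tibble::tibble(f1_hz = ds$f1_mean, f2_hz = ds$f2_mean)
  tripled <- full_session_tokens(jitter = 0)  # 3 identical reps per vowel
  expect_equal(compute_vsa_hull(tripled), compute_vsa_hull(mean_pts))

  set.seed(504)
  sq <- tibble::tibble(
    f1_hz = c(0, 0, 1, 1, runif(10, 0.2, 0.8)),
    f2_hz = c(0, 1, 0, 1, runif(10, 0.2, 0.8))
  )
  expect_equal(compute_vsa_hull(sq), 1)
})

test_that("session metrics bundle the three measures per speaker-session", {
  tokens <- dplyr::bind_rows(full_session_tokens(session = "baseline"),
                             full_session_tokens(session = "post", jitter = 8))
  m <- session_metrics(tokens)
  expect_equal(nrow(m), 2)
  expect_equal(m$session, c("baseline", "post"))
  expect_true(all(is.finite(m$aavs)) && all(is.finite(m$qvsa)) &&
                all(is.finite(m$vsahull)))
  expect_equal(m$n_tokens, c(30L, 30L))
  expect_equal(m$mode, rep("tokens", 2))
})

test_that("a missing corner vowel disables qVSA only, with a note", {
  tokens <- full_session_tokens()
  tokens <- tokens[tokens$vowel != "UW", ]
  m <- session_metrics(tokens)
  expect_true(is.na(m$qvsa))
  expect_match(m$notes, "UW")
  expect_true(is.finite(m$aavs))
  expect_true(is.finite(m$vsahull))
})

test_that("mean-level AAVS equals token-level AAVS on collapsed repetitions", {
  tokens <- full_session_tokens(jitter = 0)
  m_means <- session_metrics(tokens, mode = "means")
  ds <- load_group_formants("DS")
  expect_equal(m_means$aavs,
               compute_aavs(cbind(ds$f1_mean, ds$f2_mean)))
  expect_equal(m_means$mode, "means")
})

test_that("shift vectors are per-vowel post-minus-baseline differences", {
  b <- compute_vowel_means(full_session_tokens(session = "baseline"))
  expect_equal(shift_vectors(b, b)$d_f1, rep(0, 10))

  b1 <- b[b$vowel == "IY", ]
  p1 <- b1
  p1$f1_mean <- 450; p1$f2_mean <- 1900
  b1$f1_mean <- 462; b1$f2_mean <- 1810
  sv <- shift_vectors(b1, p1)
  expect_equal(sv$d_f1, -12)
  expect_equal(sv$d_f2, 90)

  none <- b1; none$vowel <- "UW"
  expect_warning(out <- shift_vectors(b1, none),
                 class = "vowelspace_empty_warning")
  expect_equal(nrow(out), 0)
})

test_that("group shift vectors equal the mean of speaker shift vectors", {
  cfg <- cohort_config(
    n_speakers = 4, seed = 31,
    session_shift = tibble::tibble(vowel = vowel_inventory()$code,
                                   d_f1 = seq(-20, 25, 5),
                                   d_f2 = seq(45, 0, -5))
  )
  tokens <- generate_tokens(cfg)
  means <- compute_vowel_means(tokens)
  per_speaker <- lapply(unique(tokens$speaker), function(sp) {
    shift_vectors(means[means$speaker == sp & means$session == "baseline", ],
                  means[means$speaker == sp & means$session == "post", ])
  })
  grand <- means |>
    dplyr::group_by(.data$session, .data$vowel) |>
    dplyr::summarise(f1_mean = mean(.data$f1_mean),
                     f2_mean = mean(.data$f2_mean), .groups = "drop")
  g <- shift_vectors(grand[grand$session == "baseline", ],
                     grand[grand$session == "post", ])
  avg_d_f1 <- rowMeans(sapply(per_speaker, function(s) s$d_f1[match(g$vowel, s$vowel)]))
  expect_equal(g$d_f1, unname(avg_d_f1))
})

test_that("metrics are translation invariant", {
  set.seed(502)
  for (k in seq_len(40)) {
    tokens <- full_session_tokens(jitter = runif(1, 1, 30))
    shift <- runif(2, -400, 400)
    moved <- tokens
    moved$f1_hz <- moved$f1_hz + shift[1]
    moved$f2_hz <- moved$f2_hz + shift[2]
    m0 <- session_metrics(tokens); m1 <- session_metrics(moved)
    expect_equal(m1$aavs, m0$aavs, tolerance = 1e-9)
    expect_equal(m1$qvsa, m0$qvsa, tolerance = 1e-9)
    expect_equal(m1$vsahull, m0$vsahull, tolerance = 1e-9)
  }
})

test_that("scaling all coordinates by k scales every metric by k^2", {
  set.seed(503)
  for (k in seq_len(40)) {
    tokens <- full_session_tokens(jitter = runif(1, 1, 30))
    s <- runif(1, 0.2, 3)
    scaled <- tokens
    scaled$f1_hz <- scaled$f1_hz * s
    scaled$f2_hz <- scaled$f2_hz * s
    m0 <- session_metrics(tokens); m1 <- session_metrics(scaled)
    expect_equal(m1$aavs, s^2 * m0$aavs)
    expect_equal(m1$qvsa, s^2 * m0$qvsa)
    expect_equal(m1$vsahull, s^2 * m0$vsahull)
  }
})

test_that("qVSA never exceeds VSAhull when built from the same tokens", {
  cfg <- cohort_config(n_speakers = 10, token_sd = 45, seed = 32)
  m <- session_metrics(generate_tokens(cfg))
  expect_true(all(m$qvsa <= m$vsahull))
})

test_that("the fast metric kernel matches the exported metric path", {
  inv <- vowel_inventory()
  for (seed in c(601, 602, 603)) {
    cfg <- cohort_config(n_speakers = 2, token_sd = 55, seed = seed)
    tokens <- generate_tokens(cfg)
    for (mode in c("tokens", "means")) {
      pub <- session_metrics(tokens, mode = mode)
      for (i in seq_len(nrow(pub))) {
        sub <- tokens[tokens$speaker == pub$speaker[i] &
                        tokens$session == pub$session[i], ]
        fast <- vowelspace:::.session_metrics_fast(
          sub$f1_hz, sub$f2_hz, match(sub$vowel, inv$code), mode = mode)
        expect_equal(unname(fast),
                     c(pub$aavs[i], pub$qvsa[i], pub$vsahull[i]))
      }
    }
  }
})
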
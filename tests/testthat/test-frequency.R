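test_that("frequency bookkeeping matches hand enumeration, relative and global", {
  seqs <- list(seq_of(c(1, 0, 1), id = "S1"), seq_of(c(1, 1), id = "S2"))
  rel <- frequencyProfile(seqs)
  expect_equal(positives(rel), c(2L, 1L, 1L))
  expect_equal(atRisk(rel), c(2L, 2L, 1L))
  expect_equal(frequencies(rel), c(1.0, 0.5, 1.0))
  glob <- frequencyProfile(seqs, mode = "global")
  expect_equal(frequencies(glob), c(1.0, 0.5, 0.5))
  # all-negative cohort
  zero <- frequencyProfile(list(seq_of(c(0, 0, 0)), seq_of(c(0, 0))))
  expect_equal(frequencies(zero), c(0, 0, 0))
  expect_error(frequencyProfile(list()), "at least one")
  expect_error(frequencyProfile(list(seq_of(1, tf = "A"), seq_of(1, tf = "B"))),
               "mix")
})

test_that("at-risk counts are non-increasing and start at the cohort size", {
  set.seed(3)
  for (rep in 1:10) {
    lens <- sample(3:30, 8, replace = TRUE)
    seqs <- lapply(seq_along(lens), function(i) {
      seq_of(stats::rbinom(lens[i], 1, 0.4), id = paste0("S", i))
    })
    prof <- frequencyProfile(seqs)
    expect_equal(atRisk(prof)[1], 8L)
    expect_true(all(diff(atRisk(prof)) <= 0))
    expect_equal(length(prof), max(lens))
  }
})

test_that("smoothing preserves constants and reproduces cubics exactly", {
  const <- smoothProfile(profile_of(rep(0.4, 20)))
  expect_equal(frequencies(const, smoothed = TRUE), rep(0.4, 20),
               tolerance = 1e-12)
  # a degree-3 filter passes any cubic through unchanged
  i <- 1:30
  t <- (i - 15) / 15
  f <- 0.5 + 0.2 * t - 0.1 * t^2 + 0.15 * t^3
  stopifnot(all(f >= 0 & f <= 1))  # keep clear of the [0,1] clip
  sm <- frequencies(smoothProfile(profile_of(f)), smoothed = TRUE)
  expect_equal(sm[6:25], f[6:25], tolerance = 1e-9)
  expect_equal(sm, f, tolerance = 1e-9)  # edge polynomial is the cubic itself
})

test_that("smoothing equals a per-window least-squares fit at every rank", {
  set.seed(5)
  for (rep in 1:20) {
    f <- stats::runif(25, 0.2, 0.8)
    sm <- frequencies(smoothProfile(profile_of(f)), smoothed = TRUE)
    expect_equal(sm, pmin(1, pmax(0, oracle_savgol(f, 11L, 3L))),
                 tolerance = 1e-8)
  }
})

test_that("smoothing is linear where the [0,1] clip is inactive", {
  set.seed(6)
  f <- stats::runif(30, 0.3, 0.7)
  g <- stats::runif(30, 0.3, 0.7)
  a <- 0.4; b <- 0.5
  lhs <- frequencies(smoothProfile(profile_of(a * f + b * g)), smoothed = TRUE)
  rhs <- a * frequencies(smoothProfile(profile_of(f)), smoothed = TRUE) +
    b * frequencies(smoothProfile(profile_of(g)), smoothed = TRUE)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("profiles shorter than the window shrink it; length < 2 passes through", {
  f <- stats::runif(7, 0.2, 0.8)
  sm <- smoothProfile(profile_of(f))
  expect_equal(sm@smoothing$window, 7L)
  expect_equal(frequencies(sm, smoothed = TRUE),
               pmin(1, pmax(0, oracle_savgol(f, 7L, 3L))), tolerance = 1e-8)
  expect_warning(tiny <- smoothProfile(profile_of(0.5)), "unsmoothed")
  expect_equal(frequencies(tiny, smoothed = TRUE), 0.5)
})

test_that("mirror edge mode reflects without repeating the end points", {
  f <- c(0.1, 0.2, 0.6, 0.2, 0.1, 0.15, 0.3, 0.25, 0.2, 0.1, 0.05, 0.1)
  sm <- smoothProfile(profile_of(f), smoothingConfig(5, 2, "mirror"))
  padded <- c(f[3:2], f, f[11:10])
  expected <- pmin(1, pmax(0, oracle_savgol(padded, 5L, 2L)[3:14]))
  # interior rows of the padded fit are plain central windows
  expect_equal(frequencies(sm, smoothed = TRUE), expected, tolerance = 1e-8)
})

test_that("smoothed output is clipped to the unit interval", {
  f <- c(rep(0, 6), rep(1, 8), rep(0, 6))  # boxcar causes overshoot
  sm <- frequencies(smoothProfile(profile_of(f)), smoothed = TRUE)
  expect_true(all(sm >= 0 & sm <= 1))
})

test_that("relative frequencies are censoring-unbiased while global are biased low", {
  # right-truncated sequences: a deep rank is only seen by long sequences
  cfg <- block_config(list(c(16, 23), c(30, 36)), p_in = 0.9, p_out = 0.02,
                      truncation = list(type = "uniform", min = 20, max = 39))
  coh <- generateCohort(cfg, 200, seed = 17)
  seqs <- orderSequences(coh$set, "X")
  rel <- frequencyProfile(seqs)
  glob <- frequencyProfile(seqs, mode = "global")
  deep <- 30:36  # inside the deep block, truncation removes ~half the cohort
  frac_seen <- atRisk(rel)[deep] / rel@NTotal
  expect_true(all(frac_seen < 0.85))
  # identity: global = relative * (Ni / N) -- the truncation factor
  expect_equal(frequencies(glob)[deep],
               frequencies(rel)[deep] * frac_seen, tolerance = 1e-12)
  # relative stays near truth, global is dragged down by the censoring
  expect_lt(max(abs(frequencies(rel)[deep] - 0.9)), 0.12)
  expect_true(all(frequencies(glob)[deep] < 0.8))
})
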
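test_that("period detection recovers the generator truth", {
  spec <- synth_spec(period = 10, n_frames = 200, frame_interval = 0.5,
                     noise_sd = 0, seed = 1)
  k <- make_kymograph(spec)
  p <- detect_period(k, window = c(0, 99.5))
  expect_lt(abs(p - 10), 0.5 + 1e-9)
  # invariant to uniform intensity rescaling
  k2 <- k; k2$I <- k$I * 0.3
  expect_equal(detect_period(k2, window = c(0, 99.5)), p)
})

test_that("period is zero for a time-constant kymograph", {
  I <- matrix(rep(seq(1, 2, length.out = 11), each = 40), nrow = 40)
  k <- as_min_kymograph(time = seq(0, 39), x = seq(0, 2, length.out = 11),
                        I = I)
  expect_equal(detect_period(k, window = c(0, 39)), 0)
})

test_that("period detection rejects dampening grids", {
  # amplitude decaying 10% per cycle fails the <5% peak-change rule
  tt <- seq(0, 100, by = 0.5)
  env <- 0.9^(tt / 10)
  I <- outer(env * (0.5 + 0.5 * cos(2 * pi * tt / 10)),
             exp(-2 * seq(0, 1, length.out = 11))) + 0.05
  k <- as_min_kymograph(tt, seq(0, 2, length.out = 11), I)
  expect_equal(detect_period(k, window = c(0, 100)), 0)
})

test_that("gradient fit recovers exact exponential parameters", {
  x <- seq(0, 1, length.out = 26)
  y <- 0.96 * exp(-2.89 * x) + 0.17
  f <- fit_gradient(x, y)
  expect_equal(f$a, 0.96, tolerance = 1e-7)
  expect_equal(f$lambda_N, 2.89, tolerance = 1e-7)
  expect_equal(f$c, 0.17, tolerance = 1e-7)
  expect_lt(f$residual, 1e-8)
})

test_that("gradient fit handles orientation, flatness and short input", {
  x <- seq(0, 1, length.out = 26)
  # right-peaked profile is mirrored before fitting
  y <- 1.2 * exp(-2 * (1 - x)) + 0.1
  f <- fit_gradient(x, y)
  expect_equal(f$lambda_N, 2, tolerance = 1e-6)
  # flat profile has lambda_N = 0 by convention
  ff <- fit_gradient(x, rep(0.4, 26))
  expect_equal(ff$lambda_N, 0)
  expect_true(ff$flat)
  expect_equal(ff$c, 0.4)
  # only 3 points between the maximum and the minimum
  expect_error(fit_gradient(c(0, 0.25, 0.5, 0.75, 1),
                            c(0.5, 0.6, 1, 0.5, 0.45)),
               "4 points")
})

test_that("gradient fit recovers lambda within 0.1 under noise", {
  x <- seq(0, 1, length.out = 51)
  set.seed(101)
  lam <- replicate(100, {
    y <- 1 * exp(-2 * x) + 0.2 + rnorm(51, 0, 0.01)
    fit_gradient(x, y)$lambda_N
  })
  # unbiased within the tolerance, with at most a ~2-sigma tail outside it
  expect_lt(abs(mean(lam) - 2), 0.1)
  expect_gte(mean(lam > 1.9 & lam < 2.1), 0.95)
})

test_that("I_Ratio of a symmetric synthetic kymograph matches closed form", {
  spec <- synth_spec(a = 1, lambda = 2, c = 0.2, period = 10,
                     n_frames = 200, frame_interval = 0.5, noise_sd = 0,
                     seed = 2)
  k <- make_kymograph(spec)
  ir <- compute_iratio(k, window = c(0, 99.5))
  expect_equal(ir, (exp(-1) + 0.2) / 1.2, tolerance = 1e-6)
})

test_that("I_Ratio is flagged missing for non-alternating maxima", {
  # oscillation whose spatial maximum never leaves the left half
  tt <- seq(0, 100, by = 0.5)
  I <- outer(0.6 + 0.4 * cos(2 * pi * tt / 10),
             exp(-2 * seq(0, 1, length.out = 11)))
  k <- as_min_kymograph(tt, seq(0, 2, length.out = 11), I)
  ir <- compute_iratio(k, window = c(0, 100))
  expect_true(is.na(ir))
  expect_match(attr(ir, "reason"), "irregular")
})

test_that("pattern classification distinguishes the four classes", {
  spec <- synth_spec(period = 10, n_frames = 200, frame_interval = 0.5,
                     noise_sd = 0, seed = 3)
  expect_equal(classify_pattern(make_kymograph(spec), window = c(0, 99.5)),
               "pole_to_pole")
  # constant in time
  I <- matrix(rep(seq(1, 2, length.out = 11), each = 40), nrow = 40)
  k <- as_min_kymograph(seq(0, 39), seq(0, 2, length.out = 11), I)
  expect_equal(classify_pattern(k, window = c(0, 39)), "none")
  # argmax stays in one half
  tt <- seq(0, 100, by = 0.5)
  I <- outer(0.6 + 0.4 * cos(2 * pi * tt / 10),
             exp(-2 * seq(0, 1, length.out = 11)))
  k <- as_min_kymograph(tt, seq(0, 2, length.out = 11), I)
  expect_equal(classify_pattern(k, window = c(0, 100)), "irregular")
  # alternation only in the trailing half of the window
  g <- exp(-2 * seq(0, 1, length.out = 11))
  mL <- 0.5 + 0.5 * cos(2 * pi * tt / 10)
  I2 <- outer(mL, g) + outer(1 - mL, rev(g))
  I2[tt < 50, ] <- outer(0.6 + 0.4 * cos(2 * pi * tt[tt < 50] / 10), g)
  k2 <- as_min_kymograph(tt, seq(0, 2, length.out = 11), I2)
  expect_equal(classify_pattern(k2, window = c(0, 100)), "late_onset")
})

test_that("biphasic fit recovers an exact two-segment series", {
  L <- seq(1.6, 4.6, by = 0.2)
  y <- ifelse(L <= 3, 0.5 * L + 0.2, 1.7)
  f <- fit_biphasic(L, y)
  expect_equal(f$model, "biphasic")
  expect_equal(f$slope, 0.5, tolerance = 1e-8)
  expect_equal(f$intercept, 0.2, tolerance = 1e-8)
  expect_equal(f$plateau, 1.7, tolerance = 1e-8)
  expect_lt(abs(f$breakpoint - 3), 0.2 + 1e-9)
})

test_that("biphasic fit prefers the constant model for flat data", {
  L <- seq(1.6, 4.6, by = 0.2)
  f <- fit_biphasic(L, rep(2, length(L)))
  expect_equal(f$model, "stable")
  expect_equal(f$plateau, 2)
  expect_error(fit_biphasic(L, rep(0, length(L))), "zero")
})

test_that("synthetic kymograph truth record matches the analysis chain", {
  spec <- synth_spec(a = 0.96, lambda = 2.89, c = 0.17, period = 12,
                     n_frames = 240, frame_interval = 0.5, noise_sd = 0,
                     seed = 4)
  k <- make_kymograph(spec)
  expect_equal(detect_period(k, c(0, 119.5)), k$truth$period,
               tolerance = 0.05)
  pp <- pole_profiles(k, window = c(0, 119.5))
  f <- fit_gradient(pp$x_norm, pp$merged, orient = FALSE)
  expect_equal(f$lambda_N, 2.89, tolerance = 1e-3)
  ir <- compute_iratio(k, window = c(0, 119.5))
  expect_equal(ir, k$truth$I_ratio, tolerance = 1e-3)
})
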
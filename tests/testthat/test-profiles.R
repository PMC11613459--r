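# simple synthetic series for direct construction in tests
flat_series <- function(n_frames = 25, n_x = 21, L = 2.0, value = 1) {
  do.call(rbind, lapply(seq_len(n_frames), function(j)
    data.frame(cell_id = "c1", frame = j, time_s = (j - 1) * 12,
               x_norm = seq(0, 1, length.out = n_x),
               intensity = rep(value, n_x), length_um = L)))
}

test_that("photobleach normalization leaves an undecayed series unchanged", {
  df <- make_profile_series(synth_spec(bleach = 0, noise_sd = 0, seed = 5))
  out <- photobleach_normalize(df)
  expect_lt(abs(out$b_hat), 1e-8)
  # beyond the per-frame minimum shift, intensities are unchanged
  shifted <- ave(df$intensity, df$frame, FUN = function(v) v - min(v))
  expect_equal(out$series$intensity, shifted, tolerance = 1e-8)
})

test_that("photobleach normalization recovers the decay rate and removes it", {
  df <- make_profile_series(synth_spec(bleach = 0.01, noise_sd = 0,
                                       n_frames = 40, seed = 6))
  out <- photobleach_normalize(df)
  expect_gt(out$b_hat, 0.009); expect_lt(out$b_hat, 0.011)
  tot_in <- tapply(ave(df$intensity, df$frame,
                       FUN = function(v) v - min(v)), df$frame, sum)
  tot_out <- tapply(out$series$intensity, out$series$frame, sum)
  tj <- tapply(df$time_s, df$frame, function(v) v[1])
  # corrected totals are flat within 1%
  expect_lt(diff(range(tot_out)) / mean(tot_out), 0.01)
  # fitted slope reduced at least 100-fold
  s_in <- abs(coef(lm(tot_in ~ tj))[2])
  s_out <- abs(coef(lm(tot_out ~ tj))[2])
  expect_lt(s_out, s_in / 100)
  # re-applying the fitted decay reproduces the (shifted) input
  back <- out$series$intensity * exp(-out$b_hat * out$series$time_s)
  shifted <- ave(df$intensity, df$frame, FUN = function(v) v - min(v))
  expect_equal(back, shifted, tolerance = 1e-8)
})

test_that("the alternative printed-sign convention deepens the decay", {
  df <- make_profile_series(synth_spec(bleach = 0.01, noise_sd = 0,
                                       n_frames = 40, seed = 6))
  out <- photobleach_normalize(df, printed_sign = TRUE)
  tot <- tapply(out$series$intensity, out$series$frame, sum)
  expect_lt(tot[length(tot)], tot[1] * 0.7)
})

test_that("center fraction of a uniform profile equals the zone width", {
  df <- flat_series(L = 2.0)
  expect_equal(center_fraction(df), 0.1, tolerance = 1e-12)
})

test_that("center fraction matches a dense quadrature oracle", {
  set.seed(8)
  for (rep in 1:5) {
    n_x <- 31; L <- 2.5
    xs <- seq(0, 1, length.out = n_x)
    shape <- pmax(0.05, 1 - 3 * abs(xs - 0.5)) + runif(n_x, 0, 0.2)
    df <- do.call(rbind, lapply(1:20, function(j)
      data.frame(cell_id = "c", frame = j, time_s = j, x_norm = xs,
                 intensity = shape, length_um = L)))
    # oracle: dense piecewise-linear quadrature of the same profile
    dense <- seq(0, 1, length.out = 20001)
    y <- approx(xs, shape, xout = dense)$y
    xa <- 0.5 - 0.1 / L; xb <- 0.5 + 0.1 / L
    inz <- dense >= xa & dense <= xb
    oracle <- sum(diff(dense[inz]) * (y[inz][-1] + y[inz][-sum(inz)]) / 2) /
      sum(diff(dense) * (y[-1] + y[-length(y)]) / 2)
    expect_equal(center_fraction(df), oracle, tolerance = 1e-4)
  }
})

test_that("midcell-depleted profiles have a lower center fraction", {
  xs <- seq(0, 1, length.out = 21)
  v <- abs(xs - 0.5) + 0.2     # V-shaped, depleted at midcell
  df <- flat_series()
  df$intensity <- rep(v, 25)
  expect_lt(center_fraction(df), 0.1)
  expect_error(center_fraction(flat_series(L = 0.15)), "degenerate")
})

test_that("two-sided estimator reproduces the closed-form intersection", {
  df <- make_profile_series(synth_spec(a = 1, lambda = 2, c = 0,
                                       bleach = 0, noise_sd = 0,
                                       n_frames = 40, seed = 9))
  fit <- estimate_iratio_experimental(df)
  expect_equal(unname(fit$m["left"]), 0, tolerance = 1e-9)
  expect_equal(unname(fit$m["right"]), 1, tolerance = 1e-9)
  expect_equal(fit$lambda_prime, 2, tolerance = 1e-3)
  expect_equal(fit$intersection, 0.5, tolerance = 1e-3)
  expect_equal(fit$I_ratio, exp(-1), tolerance = 1e-3)
})

test_that("two-sided estimator is scale invariant and needs both poles", {
  df <- make_profile_series(synth_spec(a = 1, lambda = 2, c = 0,
                                       bleach = 0, noise_sd = 0.01,
                                       n_frames = 40, seed = 10))
  f1 <- estimate_iratio_experimental(df)
  df2 <- df; df2$intensity <- df2$intensity * 37
  f2 <- estimate_iratio_experimental(df2)
  expect_equal(f1$I_ratio, f2$I_ratio, tolerance = 1e-12)
  # one-sided data: every frame left-peaked
  one <- df[df$frame %% 2 == 1, ]
  expect_error(estimate_iratio_experimental(one), "degenerate|both pole")
})

test_that("pooled decay-rate is the frame-count-weighted mean", {
  # direct check of the lambda' combination on a constructed fit
  lambda <- c(left = 2, right = 4); n_g <- c(left = 10, right = 30)
  expect_equal(unname(sum(lambda * n_g) / sum(n_g)), 3.5)
})

test_that("biexponential correction recovers parameters and growth", {
  sim <- make_snapshot_series(n_cells = 10, n_rounds = 50, interval = 900,
                              alpha = 0.5, beta = 1000, noise_sd = 0,
                              seed = 11)
  out <- biexp_snapshot_correction(sim$series, sim$reference)
  expect_equal(unname(out$biexp["a1"]), 0.7, tolerance = 0.05)
  expect_equal(unname(out$biexp["b1"]), 0.05, tolerance = 0.05 * 0.05 + 0.01)
  expect_equal(unname(out$biexp["a2"]), 0.3, tolerance = 0.05)
  expect_equal(unname(out$alpha_bar), 0.5, tolerance = 0.02 * 0.5)
  expect_equal(unname(out$beta_bar), 1000, tolerance = 20)

  # doubling the growth slope doubles the recovered slope
  sim2 <- make_snapshot_series(n_cells = 10, n_rounds = 50, interval = 900,
                               alpha = 1.0, beta = 1000, noise_sd = 0,
                               seed = 11)
  out2 <- biexp_snapshot_correction(sim2$series, sim2$reference)
  expect_equal(out2$alpha_bar / out$alpha_bar, 2, tolerance = 0.01)
})

test_that("a constant reference reduces to a constant rescale", {
  sim <- make_snapshot_series(n_cells = 5, n_rounds = 20, interval = 900,
                              alpha = 0, beta = 800,
                              biexp = c(a1 = 0.5, b1 = 0, a2 = 0.5, b2 = 0),
                              noise_sd = 0, seed = 12)
  out <- biexp_snapshot_correction(sim$series, sim$reference)
  # flat cells stay flat after correction
  expect_lt(max(abs(out$per_cell$alpha_j)), 1e-10)
  expect_equal(unname(out$beta_bar), 800, tolerance = 1e-6)
})

test_that("intensity-to-molecule conversion is pinned at the anchor", {
  set.seed(13)
  tt <- seq(0, 90, by = 5)
  counts <- 1800 + 8 * tt
  intens <- counts / 3.7 + rnorm(length(tt), 0, 5)
  out <- molecules_from_intensity(tt, intens, anchor_time = 75,
                                  anchor_molecules = 1800 + 8 * 75)
  expect_equal(out$fitted_molecules[1], 1800, tolerance = 0.03 * 1800)
  expect_equal(out$fitted_molecules[length(tt)], 1800 + 8 * 90,
               tolerance = 0.03 * (1800 + 8 * 90))
  # zone counts are total times the fraction
  out2 <- molecules_from_intensity(tt, intens, 75, 2000, fraction = 0.1)
  expect_equal(out2$zone_molecules, out2$molecules * 0.1)
  expect_warning(molecules_from_intensity(tt, intens, 120, 2000), "outside")
})

test_that("profile series round-trip through CSV and validate", {
  df <- make_profile_series(synth_spec(noise_sd = 0.01, seed = 14))
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_series(df, path)
  back <- read_profile_series(path)
  expect_equal(nrow(back), nrow(df))
  bad <- df; bad$x_norm[1] <- 2
  expect_error(profile_series(bad), "x_norm")
})
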
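# trapezoidal integral of y over x (x sorted)
.trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Validate a tidy profile-series table
#'
#' A profile series holds, for one cell, the 1D fluorescence intensity
#' profiles of consecutive movie frames: columns `frame`, `time_s`,
#' `x_norm` (normalized position, 0 at one pole and 1 at the other),
#' `intensity` (a.u.) and `length_um`. An optional `cell_id` column is kept.
#'
#' @param df data.frame with the columns above
#' @return the validated data.frame, positions sorted within frames
#' @export
profile_series <- function(df) {
  need <- c("frame", "time_s", "x_norm", "intensity", "length_um")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("profile series is missing columns: ", paste(miss, collapse = ", "))
  if (any(df$x_norm < -1e-9 | df$x_norm > 1 + 1e-9))
    stop("x_norm must lie in [0, 1]")
  df[order(df$frame, df$x_norm), , drop = FALSE]
}

#' Photobleaching normalization of a profile series
#'
#' Each frame is first shifted so its minimum intensity is 0. The per-frame
#' totals \eqn{S_{T_j} = \sum_x I_j(x)} are then fitted with a single
#' exponential decay \eqn{f(t) = a e^{-b t}} and the fitted decay is removed
#' by dividing each profile by \eqn{e^{-\hat b T_j}}, so corrected totals
#' have no fitted trend. Setting `printed_sign = TRUE` instead multiplies by
#' \eqn{e^{-\hat b T_j}}, which deepens rather than removes a decay; it is
#' provided for comparison with the alternative sign convention.
#'
#' @param df a [profile_series()] table for one cell
#' @param printed_sign use the multiply-by-`exp(-b t)` convention
#' @return list with `series` (corrected table), `b_hat`, `a_hat`
#' @export
photobleach_normalize <- function(df, printed_sign = FALSE) {
  df <- profile_series(df)
  frames <- split(df, df$frame)
  if (length(frames) < 3) stop("need at least 3 frames to fit the decay")
  df$intensity <- stats::ave(df$intensity, df$frame,
                             FUN = function(v) v - min(v))
  tot <- vapply(split(df$intensity, df$frame), sum, numeric(1))
  tj <- vapply(split(df$time_s, df$frame), function(v) v[1], numeric(1))
  if (any(tot <= 0)) stop("non-positive frame totals; cannot fit decay")
  # log-linear estimate, polished by nonlinear least squares when the data
  # are not already an exact exponential (where the polish is singular)
  lf <- stats::lm(log(tot) ~ tj)
  a_hat <- exp(unname(stats::coef(lf)[1]))
  b_hat <- -unname(stats::coef(lf)[2])
  fit <- tryCatch(
    minpack.lm::nlsLM(tot ~ a * exp(-b * tj),
                      start = list(a = a_hat, b = b_hat)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    b_hat <- unname(stats::coef(fit)["b"])
    a_hat <- unname(stats::coef(fit)["a"])
  }
  fac <- if (printed_sign) exp(-b_hat * df$time_s) else exp(b_hat * df$time_s)
  df$intensity <- df$intensity * fac
  list(series = df, b_hat = b_hat, a_hat = a_hat)
}

#' Fraction of profile intensity in the midcell zone
#'
#' The midcell zone spans +/- 100 nm of the cell midpoint, i.e.
#' `[0.5 - 0.1/L, 0.5 + 0.1/L]` on the normalized length for a cell of
#' length `L` um. Intensities are linearly interpolated at the zone
#' boundaries, both the zone and the whole profile are integrated by the
#' trapezoidal rule, and the fraction is the ratio of the zone mean to the
#' total mean over the first `n_frames` frames (all frames, with a warning,
#' if the series is shorter).
#'
#' @param df a [profile_series()] table for one cell
#' @param n_frames number of leading frames to average (default 20)
#' @return midcell intensity fraction in `[0, 1]`
#' @export
center_fraction <- function(df, n_frames = 20) {
  df <- profile_series(df)
  frames <- split(df, df$frame)
  if (length(frames) < n_frames) {
    warning("series has ", length(frames), " < ", n_frames,
            " frames; using all of them")
    n_frames <- length(frames)
  }
  frames <- frames[seq_len(n_frames)]
  vals <- vapply(frames, function(fr) {
    L <- fr$length_um[1]
    if (L <= 0.2) stop("cell length ", L, " um: midcell zone is degenerate")
    xa <- 0.5 - 0.1 / L; xb <- 0.5 + 0.1 / L
    x <- fr$x_norm; y <- fr$intensity
    ya <- stats::approx(x, y, xout = xa)$y
    yb <- stats::approx(x, y, xout = xb)$y
    inz <- x > xa & x < xb
    xc <- c(xa, x[inz], xb); yc <- c(ya, y[inz], yb)
    c(center = .trapz(xc, yc), total = .trapz(x, y))
  }, numeric(2))
  mean(vals["center", ]) / mean(vals["total", ])
}

# local linear-regression slope of intensity at position x0
.local_slope <- function(x, y, x0, window) {
  sel <- abs(x - x0) <= window
  if (sum(sel) < 2) stop("fewer than 2 points within the slope window at x = ", x0)
  unname(stats::coef(stats::lm(y[sel] ~ x[sel]))[2])
}

# closed-form amplitude for y ~ d * w, w = exp(-lambda |x - m|)
.amp_given_lambda <- function(x, y, m, lambda) {
  w <- exp(-lambda * abs(x - m))
  sum(w * y) / sum(w * w)
}

#' Two-sided exponential estimate of the intensity ratio
#'
#' Implements the measurement-side estimator of `I_Ratio` for a
#' pole-to-pole oscillating cell:
#' \enumerate{
#' \item per frame, the intensity slope is estimated at normalized positions
#'   0.2 and 0.8 by local linear regression over `+/- slope_window`;
#' \item frames are split into left- and right-peaked groups by 2-means
#'   clustering on the two slopes (deterministically initialized from the
#'   extreme frames), and frames whose slope magnitude falls in the pooled
#'   first quartile are excluded as too flat;
#' \item each group's pooled points are smoothed by Gaussian-kernel
#'   (Nadaraya-Watson) regression to locate the peak position `m_i`;
#' \item a two-sided exponential \eqn{d_i e^{-\lambda_i |x - m_i|}} is fitted
#'   per group, the decay rates are pooled into the frame-count-weighted
#'   mean \eqn{\lambda'}, and the amplitudes are refitted with
#'   \eqn{\lambda'} fixed;
#' \item `I_min` is the intensity where the two refitted curves intersect,
#'   `I_max` the maximum of the fitted curves, and
#'   `I_Ratio = I_min / I_max`.
#' }
#'
#' @param df a [profile_series()] table for one cell (already
#'   bleaching-corrected)
#' @param slope_window half-width of the slope-regression window
#' @param bandwidth Gaussian kernel bandwidth; default is
#'   [stats::bw.nrd0()] of the pooled positions
#' @param grid_n evaluation grid size on `[0, 1]`
#' @return object of class `two_sided_fit`: list with `groups` (per-frame
#'   assignment), `excluded` frames, `m`, `lambda`, `lambda_prime`, `d`
#'   (refitted amplitudes), `I_max`, `I_min`, `I_ratio`, `intersection`,
#'   and the smoothed `curves`
#' @export
estimate_iratio_experimental <- function(df, slope_window = 0.05,
                                         bandwidth = NULL, grid_n = 201) {
  df <- profile_series(df)
  frames <- split(df, df$frame)
  if (length(frames) < 8) stop("need at least 8 frames")
  slopes <- t(vapply(frames, function(fr)
    c(s02 = .local_slope(fr$x_norm, fr$intensity, 0.2, slope_window),
      s08 = .local_slope(fr$x_norm, fr$intensity, 0.8, slope_window)),
    numeric(2)))
  centers <- slopes[c(which.min(slopes[, 1]), which.max(slopes[, 1])), ,
                    drop = FALSE]
  if (any(duplicated(centers))) stop("slope features are degenerate")
  km <- stats::kmeans(slopes, centers = centers)
  # pooled first-quartile exclusion on the per-frame slope magnitude
  # (strictly below the quartile, so tied magnitudes are never all dropped)
  mag <- pmax(abs(slopes[, 1]), abs(slopes[, 2]))
  keep <- mag >= stats::quantile(mag, 0.25)
  cl <- km$cluster
  # the left-peaked group decays to the right: more negative slope at 0.2
  left_cl <- which.min(tapply(slopes[, 1], cl, mean))
  is_left <- (cl == left_cl) & keep
  is_right <- (cl != left_cl) & keep
  if (!any(is_left) || !any(is_right) ||
      mean(slopes[is_left, 1]) >= 0 || mean(slopes[is_right, 1]) <= 0)
    stop("frames do not span both pole states")
  pool <- function(sel) do.call(rbind, frames[sel])[, c("x_norm", "intensity")]
  pl <- pool(is_left); pr <- pool(is_right)
  if (is.null(bandwidth)) bandwidth <- stats::bw.nrd0(c(pl$x_norm, pr$x_norm))
  grid <- seq(0, 1, length.out = grid_n)
  nw <- function(p) vapply(grid, function(g) {
    w <- stats::dnorm((g - p$x_norm) / bandwidth)
    sum(w * p$intensity) / sum(w)
  }, numeric(1))
  fl <- nw(pl); fr_ <- nw(pr)
  m <- c(left = grid[which.max(fl)], right = grid[which.max(fr_)])
  fit_lambda <- function(p, mi) {
    rss <- function(lam) {
      d <- .amp_given_lambda(p$x_norm, p$intensity, mi, lam)
      sum((p$intensity - d * exp(-lam * abs(p$x_norm - mi)))^2)
    }
    stats::optimize(rss, c(1e-3, 60))$minimum
  }
  lambda <- c(left = fit_lambda(pl, m["left"]),
              right = fit_lambda(pr, m["right"]))
  n_g <- c(left = sum(is_left), right = sum(is_right))
  lambda_prime <- unname(sum(lambda * n_g) / sum(n_g))
  d <- c(left = .amp_given_lambda(pl$x_norm, pl$intensity, m["left"],
                                  lambda_prime),
         right = .amp_given_lambda(pr$x_norm, pr$intensity, m["right"],
                                   lambda_prime))
  I_max <- max(d)
  # intersection of the two refitted curves between the peaks
  ml <- m["left"]; mr <- m["right"]
  if (mr < ml) { tmp <- mr; mr <- ml; ml <- tmp }
  xstar <- unname((ml + mr) / 2 +
                    log(d[if (m["left"] <= m["right"]) "left" else "right"] /
                          d[if (m["left"] <= m["right"]) "right" else "left"]) /
                    (2 * lambda_prime))
  ok <- xstar > ml && xstar < mr && xstar > 0 && xstar < 1
  I_min <- if (ok) unname(d["left"] * exp(-lambda_prime * abs(xstar - m["left"])))
           else NA_real_
  structure(list(groups = ifelse(cl == left_cl, "left", "right"),
                 excluded = names(frames)[!keep],
                 slopes = slopes, m = m, lambda = lambda,
                 lambda_prime = lambda_prime, d = d,
                 I_max = I_max, I_min = I_min,
                 I_ratio = if (ok) I_min / I_max
                           else structure(NA_real_, reason = "no intersection in (0,1)"),
                 intersection = if (ok) xstar else NA_real_,
                 curves = list(grid = grid, left = fl, right = fr_)),
            class = "two_sided_fit")
}

#' @export
print.two_sided_fit <- function(x, ...) {
  cat(sprintf(
    "two-sided exponential fit: lambda' = %.3f, I_max = %.4g, I_min = %.4g, I_Ratio = %.4g\n",
    x$lambda_prime, x$I_max, x$I_min,
    if (is.na(x$I_ratio)) NA else x$I_ratio))
  invisible(x)
}

#' Snapshot-series container
#'
#' Per-cell total intensities `C_j(k)` indexed by the exposure round `k`
#' (the number of prior light exposures), with time stamps, plus the
#' division-bracket rounds `[c1, c2]` delimiting the frames between two cell
#' divisions.
#'
#' @param obs data.frame with columns `cell_id`, `k`, `time_s`, `intensity`
#' @param brackets data.frame with columns `cell_id`, `c1`, `c2`; defaults
#'   to each cell's full range of rounds
#' @return object of class `snapshot_series`
#' @export
snapshot_series <- function(obs, brackets = NULL) {
  need <- c("cell_id", "k", "time_s", "intensity")
  miss <- setdiff(need, names(obs))
  if (length(miss))
    stop("snapshot series is missing columns: ", paste(miss, collapse = ", "))
  if (any(obs$k < 0) || any(obs$k != round(obs$k)))
    stop("exposure rounds k must be non-negative integers")
  if (is.null(brackets)) {
    rng <- do.call(rbind, lapply(split(obs, obs$cell_id), function(d)
      data.frame(cell_id = d$cell_id[1], c1 = min(d$k), c2 = max(d$k))))
    brackets <- rng[order(rng$cell_id), ]
    rownames(brackets) <- NULL
  }
  if (any(brackets$c1 > brackets$c2)) stop("need c1 <= c2")
  structure(list(obs = obs, brackets = brackets), class = "snapshot_series")
}

#' Biexponential photobleaching correction of snapshot series
#'
#' Fits the reference decay observations (normalized so the first exposure
#' is 1) with \eqn{f(k) = a_1 e^{-b_1 k} + a_2 e^{-b_2 k}}, divides every
#' cell's intensities by \eqn{\hat f(k)}, and regresses each cell's
#' corrected intensities on time within its division bracket, yielding
#' per-cell growth slopes/intercepts and their population means.
#'
#' @param series a [snapshot_series()]
#' @param reference data.frame with columns `k`, `intensity` (normalized
#'   decay, decreasing from 1)
#' @return list with `biexp` (fitted `a1, b1, a2, b2`), `corrected` (the
#'   series with corrected intensities), `per_cell` (data.frame of
#'   `alpha_j`, `beta_j`), `alpha_bar`, `beta_bar`
#' @export
biexp_snapshot_correction <- function(series, reference) {
  stopifnot(inherits(series, "snapshot_series"))
  if (!all(c("k", "intensity") %in% names(reference)))
    stop("reference needs columns k and intensity")
  k <- reference$k; y <- reference$intensity
  if (stats::sd(y) < 1e-12 * max(abs(mean(y)), 1)) {
    cf <- c(a1 = mean(y) / 2, b1 = 0, a2 = mean(y) / 2, b2 = 0)
  } else {
    lf <- stats::lm(log(pmax(y, 1e-12)) ~ k)
    b0 <- max(1e-4, -unname(stats::coef(lf)[2]))
    a0 <- exp(unname(stats::coef(lf)[1]))
    fit <- minpack.lm::nlsLM(
      y ~ a1 * exp(-b1 * k) + a2 * exp(-b2 * k),
      start = list(a1 = 0.7 * a0, b1 = 5 * b0, a2 = 0.3 * a0,
                   b2 = 0.2 * b0),
      lower = c(0, 0, 0, 0),
      control = minpack.lm::nls.lm.control(maxiter = 1000))
    if (!fit$convInfo$isConv && fit$m$deviance() > 1e-6 * sum(y^2))
      stop("biexponential fit did not converge; residual RSS = ",
           format(fit$m$deviance()))
    cf <- stats::coef(fit)
  }
  fhat <- function(kk) cf["a1"] * exp(-cf["b1"] * kk) +
    cf["a2"] * exp(-cf["b2"] * kk)
  obs <- series$obs
  obs$corrected <- obs$intensity / as.numeric(fhat(obs$k))
  per_cell <- do.call(rbind, lapply(split(obs, obs$cell_id), function(d) {
    br <- series$brackets[series$brackets$cell_id == d$cell_id[1], ]
    d <- d[d$k >= br$c1 & d$k <= br$c2, ]
    t0 <- d$time_s[which.min(d$k)]
    co <- stats::coef(stats::lm(corrected ~ I(time_s - t0), data = d))
    data.frame(cell_id = d$cell_id[1], alpha_j = unname(co[2]),
               beta_j = unname(co[1]))
  }))
  rownames(per_cell) <- NULL
  list(biexp = cf, corrected = snapshot_series(obs, series$brackets),
       per_cell = per_cell,
       alpha_bar = mean(per_cell$alpha_j), beta_bar = mean(per_cell$beta_j))
}

#' Convert fluorescence intensity to molecule counts
#'
#' Fits intensity versus time by simple linear regression and pins the
#' fitted line to a calibration anchor (`anchor_molecules` at
#' `anchor_time`), giving a linear intensity-to-molecules conversion.
#' When a midcell-zone intensity fraction is supplied (see
#' [center_fraction()]), zone counts are `total * fraction`.
#'
#' @param times observation times
#' @param intensities total-intensity observations (bleaching-corrected)
#' @param anchor_time time at which the molecule count is known
#' @param anchor_molecules molecule count at `anchor_time`
#' @param fraction optional midcell-zone intensity fraction
#' @return list with `conversion` (molecules per intensity unit), `fit`
#'   (the `lm`), `molecules` (per observation), `fitted_molecules`, and
#'   `zone_molecules` when `fraction` is given
#' @export
molecules_from_intensity <- function(times, intensities, anchor_time,
                                     anchor_molecules = 2205,
                                     fraction = NULL) {
  fit <- stats::lm(intensities ~ times)
  if (anchor_time < min(times) || anchor_time > max(times))
    warning("anchor time ", anchor_time, " lies outside the fitted range")
  at_anchor <- unname(stats::predict(fit,
                                     newdata = data.frame(times = anchor_time)))
  if (at_anchor <= 0) stop("fitted intensity at the anchor is non-positive")
  conv <- anchor_molecules / at_anchor
  out <- list(conversion = conv, fit = fit,
              molecules = intensities * conv,
              fitted_molecules = unname(stats::fitted(fit)) * conv)
  if (!is.null(fraction)) out$zone_molecules <- out$molecules * fraction
  out
}

#' Read / write tidy profile-series CSV
#'
#' @param path CSV with columns `cell_id, frame, time_s, x_norm, intensity,
#'   length_um`
#' @return data.frame
#' @export
read_profile_series <- function(path) {
  profile_series(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_profile_series
#' @param df profile-series table
#' @export
write_profile_series <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
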
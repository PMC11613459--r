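# indices of strict-left / plateau-right local maxima of a series
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3 || max(y) - min(y) <= 0) return(integer(0))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

# frame indices inside the analysis window
.window_idx <- function(kymo, window) {
  if (window[1] < min(kymo$time) - 1e-9 || window[2] > max(kymo$time) + 1e-9)
    stop("analysis window [", window[1], ", ", window[2],
         "] s outside the stored trajectory")
  which(kymo$time >= window[1] - 1e-9 & kymo$time <= window[2] + 1e-9)
}

#' Oscillation period from a kymograph
#'
#' Per grid point, locates consecutive temporal maxima of the normalized
#' membrane intensity within the analysis window. A grid point is accepted
#' only if every pair of consecutive peak amplitudes changes by less than
#' `peak_tol` (default 5%); larger changes indicate a dampening (or
#' otherwise non-stationary) oscillation at that position. The period is the
#' aggregate over accepted grid points of the mean inter-peak interval, and
#' 0 if no grid point qualifies. Peaks live on the frame grid (no sub-frame
#' interpolation), so periods are integer multiples of the frame interval.
#'
#' The aggregate across grid points is the median by default: in a
#' pole-to-pole oscillation a grid point lying exactly at midcell is visited
#' by both half-waves and oscillates at twice the pole frequency with equal
#' peak amplitudes, so it passes the damping filter while carrying half the
#' period; the median is insensitive to this single degenerate grid whereas
#' the mean is biased by it.
#'
#' @param kymo a `min_kymograph`
#' @param window analysis window (s), default `c(40, 140)`
#' @param peak_tol maximum relative change between consecutive peaks
#' @param aggregate `"median"` (default) or `"mean"` across grid points
#' @return period in seconds (0 if no stable oscillation)
#' @export
detect_period <- function(kymo, window = c(40, 140), peak_tol = 0.05,
                          aggregate = c("median", "mean")) {
  stopifnot(inherits(kymo, "min_kymograph"))
  aggregate <- match.arg(aggregate)
  idx <- .window_idx(kymo, window)
  tt <- kymo$time[idx]
  I <- kymo$I[idx, , drop = FALSE]
  per_grid <- rep(NA_real_, ncol(I))
  for (g in seq_len(ncol(I))) {
    pk <- local_maxima(I[, g])
    if (length(pk) < 2) next
    amp <- I[pk, g]
    rel <- abs(diff(amp)) / amp[-length(amp)]
    if (any(rel >= peak_tol)) next
    per_grid[g] <- mean(diff(tt[pk]))
  }
  ok <- per_grid[!is.na(per_grid)]
  if (!length(ok)) return(0)
  if (aggregate == "mean") mean(ok) else stats::median(ok)
}

#' Exponential fit of a concentration-gradient profile
#'
#' Fits \eqn{I(x) = a e^{-\lambda_N x} + c} by nonlinear least squares to the
#' sub-interval running from the profile maximum to the profile minimum
#' (positions on the normalized cell length). The profile is expected with
#' its maximum at smaller x; if `orient = TRUE` a profile peaking on the
#' right is mirrored first. A spatially flat profile (peak-to-trough range
#' below `flat_tol` of the mean) has no gradient to fit and returns
#' `lambda_N = 0` by convention.
#'
#' @param x normalized positions in `[0, 1]`
#' @param I intensities
#' @param flat_tol flatness threshold (fraction of the mean intensity)
#' @param orient mirror the profile if its maximum lies at larger x
#' @return object of class `gradient_fit`: list with `a`, `lambda_N`, `c`,
#'   `range` (fit interval), `residual` (RSS), `flat` flag
#' @export
fit_gradient <- function(x, I, flat_tol = 0.01, orient = TRUE) {
  stopifnot(length(x) == length(I))
  o <- order(x)
  x <- x[o]; I <- I[o]
  m <- mean(I)
  if (m <= 0 || (max(I) - min(I)) < flat_tol * abs(m))
    return(structure(list(a = 0, lambda_N = 0, c = m,
                          range = range(x), residual = 0, flat = TRUE),
                     class = "gradient_fit"))
  if (orient && which.max(I) > which.min(I)) {
    x <- rev(1 - x); I <- rev(I)
  }
  i_max <- which.max(I); i_min <- which.min(I)
  if (i_max >= i_min) stop("profile maximum does not precede its minimum")
  xs <- x[i_max:i_min]; ys <- I[i_max:i_min]
  if (length(xs) < 4) stop("fewer than 4 points between maximum and minimum")
  # log-linear start values
  c0 <- min(ys) - 0.05 * (max(ys) - min(ys))
  lf <- stats::lm(log(ys - c0) ~ xs)
  start <- list(a = exp(unname(stats::coef(lf)[1])),
                lam = max(1e-6, -unname(stats::coef(lf)[2])), cc = c0)
  fit <- minpack.lm::nlsLM(ys ~ a * exp(-lam * xs) + cc, start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  structure(list(a = unname(cf["a"]), lambda_N = unname(cf["lam"]),
                 c = unname(cf["cc"]), range = c(xs[1], xs[length(xs)]),
                 residual = sum(stats::resid(fit)^2), flat = FALSE),
            class = "gradient_fit")
}

#' @export
print.gradient_fit <- function(x, ...) {
  cat(sprintf("gradient fit: I(x) = %.4g * exp(-%.4g x) + %.4g  (RSS %.3g)\n",
              x$a, x$lambda_N, x$c, x$residual))
  invisible(x)
}

#' Pole-peak profiles and their merge
#'
#' Identifies the times at which the spatial intensity maximum attains a
#' temporal peak, separated by whether the maximum sits in the left or right
#' cell half. Because the true peak generally falls between stored frames,
#' the profile at each pole peak is, by default, interpolated at the
#' sub-frame peak time (quadratic in time through the three frames around
#' the peak); otherwise the nearest-frame profile is used. Each pole profile
#' is the average of the per-peak profiles (each normalized to its own
#' maximum); the right profile is mirrored and merged with the left by
#' averaging. Also reports the maximum pointwise relative difference (in %)
#' between the first left-peak profile and the mirrored subsequent
#' right-peak profile, a measure of the symmetry of the stable oscillation.
#'
#' @param kymo a `min_kymograph`
#' @param window analysis window (s)
#' @param interpolate evaluate profiles at the quadratic-interpolated
#'   sub-frame peak time (default) rather than at the nearest frame
#' @return list with `x_norm`, `left`, `right_mirrored`, `merged`,
#'   `times_left`, `times_right`, `max_rel_diff_pct`
#' @export
pole_profiles <- function(kymo, window = c(40, 140), interpolate = TRUE) {
  stopifnot(inherits(kymo, "min_kymograph"))
  idx <- .window_idx(kymo, window)
  tt <- kymo$time[idx]
  I <- kymo$I[idx, , drop = FALSE]
  xn <- (kymo$x - min(kymo$x)) / (max(kymo$x) - min(kymo$x))
  M <- apply(I, 1, max)
  side <- apply(I, 1, function(r) xn[which.max(r)] < 0.5)
  pk <- local_maxima(M)
  if (length(pk) < 2) stop("fewer than two pole peaks in the window")
  left_pk <- pk[side[pk]]
  right_pk <- pk[!side[pk]]
  if (!length(left_pk) || !length(right_pk))
    stop("peaks do not visit both poles")
  norm_prof <- function(i) {
    p <- I[i, ]
    if (interpolate && i > 1 && i < nrow(I)) {
      y <- M[(i - 1):(i + 1)]
      den <- y[1] - 2 * y[2] + y[3]
      if (den < 0) {
        delta <- 0.5 * (y[1] - y[3]) / den   # sub-frame offset in [-0.5, 0.5]
        v1 <- I[i - 1, ]; v2 <- I[i, ]; v3 <- I[i + 1, ]
        a2 <- (v1 - 2 * v2 + v3) / 2
        b1 <- (v3 - v1) / 2
        p <- v2 + b1 * delta + a2 * delta^2
      }
    }
    p / max(p)
  }
  left <- colMeans(do.call(rbind, lapply(left_pk, norm_prof)))
  right <- colMeans(do.call(rbind, lapply(right_pk, norm_prof)))
  right_m <- rev(right)
  # symmetry check on one consecutive left/right pair
  l1 <- left_pk[1]
  r1 <- right_pk[right_pk > l1][1]
  if (is.na(r1)) { l1 <- left_pk[left_pk > right_pk[1]][1]; r1 <- right_pk[1] }
  d <- NA_real_
  if (!is.na(l1) && !is.na(r1)) {
    a <- norm_prof(l1); b <- rev(norm_prof(r1))
    d <- 100 * max(abs(a - b) / pmax(a, b))
  }
  list(x_norm = xn, left = left, right_mirrored = right_m,
       merged = (left + right_m) / 2,
       times_left = tt[left_pk], times_right = tt[right_pk],
       max_rel_diff_pct = d)
}

#' Midcell-to-pole intensity ratio of a kymograph
#'
#' For a pole-to-pole oscillation, builds the merged pole profile (see
#' [pole_profiles()]), reads `I_max = I(x = 0)` and `I_min = I(x = 0.5)` by
#' linear interpolation on the normalized length, and returns
#' `I_Ratio = I_min / I_max`. Defined only when the spatial maximum
#' alternates between the poles; otherwise `NA` is returned with an
#' attribute `reason`.
#'
#' @param kymo a `min_kymograph`
#' @param window analysis window (s)
#' @return I_Ratio in `[0, 1]`, or flagged `NA`
#' @export
compute_iratio <- function(kymo, window = c(40, 140)) {
  cls <- classify_pattern(kymo, window)
  if (cls != "pole_to_pole")
    return(structure(NA_real_, reason = paste0("pattern is '", cls, "'")))
  pp <- pole_profiles(kymo, window)
  i0 <- stats::approx(pp$x_norm, pp$merged, xout = 0, rule = 2)$y
  i5 <- stats::approx(pp$x_norm, pp$merged, xout = 0.5, rule = 2)$y
  i5 / i0
}

#' Classify the oscillation pattern of a kymograph
#'
#' Tracks the temporal peaks of the per-frame spatial maximum and the cell
#' half in which each peak occurs. The pattern is `pole_to_pole` when
#' consecutive peaks alternate between halves for at least `alternation`
#' (default 90%) of peak pairs across the window; `late_onset` when that
#' criterion holds only over the trailing half of the window; `none` when
#' there is no temporal oscillation; `irregular` otherwise.
#'
#' @param kymo a `min_kymograph`
#' @param window analysis window (s)
#' @param alternation minimum fraction of alternating peak pairs
#' @return one of `"pole_to_pole"`, `"late_onset"`, `"irregular"`, `"none"`
#' @export
classify_pattern <- function(kymo, window = c(40, 140), alternation = 0.9) {
  stopifnot(inherits(kymo, "min_kymograph"))
  idx <- .window_idx(kymo, window)
  tt <- kymo$time[idx]
  I <- kymo$I[idx, , drop = FALSE]
  xn <- (kymo$x - min(kymo$x)) / (max(kymo$x) - min(kymo$x))
  M <- apply(I, 1, max)
  pk <- local_maxima(M)
  # no temporal oscillation anywhere: flat in time at every grid point
  temporal <- any(apply(I, 2, function(y) length(local_maxima(y)) >= 2))
  if (!temporal) return("none")
  if (length(pk) < 2) return("irregular")
  side <- apply(I[pk, , drop = FALSE], 1, function(r) xn[which.max(r)] < 0.5)
  alt_frac <- function(s) if (length(s) < 2) 0 else mean(diff(s) != 0)
  if (alt_frac(side) >= alternation && length(unique(side)) == 2)
    return("pole_to_pole")
  tail_sel <- tt[pk] >= window[1] + (window[2] - window[1]) / 2
  s2 <- side[tail_sel]
  if (length(s2) >= 3 && alt_frac(s2) >= alternation &&
      length(unique(s2)) == 2)
    return("late_onset")
  "irregular"
}

#' Biphasic fit of the gradient steepness versus cell length
#'
#' The decay constant `lambda_N` typically increases with length and then
#' plateaus. This fits a two-segment model -- linear
#' `lambda_N = a L + b` below a breakpoint and constant `lambda_N = c`
#' above it -- choosing the breakpoint that minimizes the total residual sum
#' of squares. A single constant model is preferred (via BIC) when the data
#' carry no increasing phase.
#'
#' @param length cell lengths (um)
#' @param lambda_N gradient decay constants; entries equal to 0 (no spatial
#'   gradient) are dropped before fitting
#' @return list with `model` (`"biphasic"` or `"stable"`), `slope`,
#'   `intercept`, `plateau`, `breakpoint`, `rss`
#' @export
fit_biphasic <- function(length, lambda_N) {
  keep <- lambda_N > 0
  if (!any(keep)) stop("all lambda_N are zero; nothing to fit")
  L <- length[keep]; y <- lambda_N[keep]
  o <- order(L); L <- L[o]; y <- y[o]
  n <- length(L)
  if (n < 4) stop("need at least 4 lengths with lambda_N > 0")
  rss_const <- sum((y - mean(y))^2)
  scale <- sum(y^2)
  if (rss_const <= 1e-12 * scale)
    return(list(model = "stable", slope = NA_real_, intercept = NA_real_,
                plateau = mean(y), breakpoint = NA_real_, rss = rss_const))
  best <- NULL
  for (k in 2:(n - 2)) {          # k = last index of the increasing segment
    li <- 1:k; ri <- (k + 1):n
    fl <- stats::lm(y[li] ~ L[li])
    rss <- sum(stats::resid(fl)^2) + sum((y[ri] - mean(y[ri]))^2)
    if (is.null(best) || rss < best$rss)
      best <- list(slope = unname(stats::coef(fl)[2]),
                   intercept = unname(stats::coef(fl)[1]),
                   plateau = mean(y[ri]),
                   breakpoint = (L[k] + L[k + 1]) / 2, rss = rss)
  }
  bic_const <- n * log(max(rss_const, 1e-300) / n) + 1 * log(n)
  bic_bi <- n * log(max(best$rss, 1e-300) / n) + 4 * log(n)
  if (bic_const <= bic_bi)
    return(list(model = "stable", slope = NA_real_, intercept = NA_real_,
                plateau = mean(y), breakpoint = NA_real_, rss = rss_const))
  c(list(model = "biphasic"), best)
}

#' All oscillation descriptors of a kymograph
#'
#' Convenience wrapper computing the period, pattern class, merged-profile
#' gradient fit (`lambda_N`) and `I_Ratio` in one call. `lambda_N` is 0 and
#' `I_Ratio` is `NA` for non-pole-to-pole patterns.
#'
#' @param kymo a `min_kymograph`
#' @param window analysis window (s)
#' @return list with `period`, `pattern_class`, `lambda_N`, `I_ratio`,
#'   `fit` (the `gradient_fit` or `NULL`)
#' @export
kymo_metrics <- function(kymo, window = c(40, 140)) {
  period <- detect_period(kymo, window)
  cls <- classify_pattern(kymo, window)
  lam <- 0; fit <- NULL; ir <- NA_real_
  if (cls == "pole_to_pole") {
    pp <- pole_profiles(kymo, window)
    fit <- tryCatch(fit_gradient(pp$x_norm, pp$merged, orient = FALSE),
                    error = function(e) NULL)
    if (!is.null(fit)) lam <- fit$lambda_N
    i0 <- stats::approx(pp$x_norm, pp$merged, xout = 0, rule = 2)$y
    i5 <- stats::approx(pp$x_norm, pp$merged, xout = 0.5, rule = 2)$y
    ir <- i5 / i0
  }
  list(period = period, pattern_class = cls, lambda_N = lam, I_ratio = ir,
       fit = fit)
}
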
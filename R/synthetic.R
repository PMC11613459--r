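# run expr with a locally seeded RNG, restoring the caller's state
.with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Specification of a synthetic oscillation
#'
#' Describes the alternating-pole exponential gradient
#' \eqn{a e^{-\lambda x} + c} used to emulate measured MinD intensity
#' profiles: its shape, oscillation period, sampling, cell length,
#' photobleaching decay and additive Gaussian noise. The defaults follow
#' the measured reference gradient (`a = 0.96`, `lambda = 2.89`,
#' `c = 0.17`), the experimental median oscillation period (46 s), the
#' 12-s imaging interval, and the median cell length (2.84 um). A seed is
#' mandatory; generators restore the caller's RNG state.
#'
#' @param a gradient amplitude (a.u.)
#' @param lambda gradient decay constant (per normalized length)
#' @param c gradient offset (a.u.)
#' @param period oscillation period (s)
#' @param n_frames number of frames
#' @param frame_interval frame spacing (s)
#' @param length_um cell length (um)
#' @param bleach photobleaching decay rate (1/s)
#' @param noise_sd additive Gaussian noise standard deviation (a.u.)
#' @param n_x number of positions across the cell
#' @param seed RNG seed (mandatory)
#' @return object of class `synth_spec`
#' @export
synth_spec <- function(a = 0.96, lambda = 2.89, c = 0.17, period = 46,
                       n_frames = 60, frame_interval = 12,
                       length_um = 2.84, bleach = 0, noise_sd = 0,
                       n_x = 51, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(a >= 0, lambda >= 0, period > 0, n_frames >= 2,
            frame_interval > 0, length_um > 0, bleach >= 0, noise_sd >= 0,
            n_x >= 5)
  structure(list(a = a, lambda = lambda, c = c, period = period,
                 n_frames = n_frames, frame_interval = frame_interval,
                 length_um = length_um, bleach = bleach,
                 noise_sd = noise_sd, n_x = n_x, seed = seed),
            class = "synth_spec")
}

# closed-form I_Ratio of the merged gradient a e^(-lambda x) + c
.truth_iratio <- function(a, lambda, c) (a * exp(-lambda / 2) + c) / (a + c)

#' Synthetic kymograph with known metrics
#'
#' Builds \eqn{I(x, t) = m_L(t) g(x) + m_R(t) g(1 - x)} on a cell-centered
#' grid, where \eqn{g(x) = a e^{-\lambda x} + c} and the two pole envelopes
#' \eqn{m_L = 0.5 + 0.5\cos(2\pi t / T)}, \eqn{m_R = 1 - m_L} alternate
#' with period `T`; optional additive Gaussian noise. The `truth` element
#' records the generating period, `lambda_N` and the closed-form
#' `I_Ratio = (a e^{-\lambda/2} + c) / (a + c)` for parameter-recovery
#' tests.
#'
#' @param spec a [synth_spec()]
#' @return a `min_kymograph` with a `truth` record
#' @export
make_kymograph <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  .with_seed(spec$seed, {
    tt <- (seq_len(spec$n_frames) - 1) * spec$frame_interval
    xn <- seq(0, 1, length.out = spec$n_x)
    g <- spec$a * exp(-spec$lambda * xn) + spec$c
    mL <- 0.5 + 0.5 * cos(2 * pi * tt / spec$period)
    I <- outer(mL, g) + outer(1 - mL, rev(g))
    if (spec$noise_sd > 0)
      I <- pmax(I + matrix(stats::rnorm(length(I), 0, spec$noise_sd),
                           nrow = nrow(I)), 0)
    as_min_kymograph(tt, xn * spec$length_um, I,
                     truth = list(period = spec$period,
                                  lambda_N = spec$lambda,
                                  I_ratio = .truth_iratio(spec$a, spec$lambda,
                                                          spec$c)))
  })
}

#' Synthetic experimental-style profile series
#'
#' Emulates a time-lapse of 1D intensity profiles from a pole-to-pole
#' oscillating cell: frames alternate between the left-peaked gradient
#' \eqn{g(x)} and its mirror \eqn{g(1-x)}, the whole profile decays as
#' \eqn{e^{-b t}} (photobleaching) and additive Gaussian noise is applied.
#' The attached `truth` attribute records the bleach rate, gradient decay
#' constant and closed-form `I_Ratio`.
#'
#' @param spec a [synth_spec()]
#' @return a [profile_series()] data.frame with attribute `truth`
#' @export
make_profile_series <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  .with_seed(spec$seed, {
    xn <- seq(0, 1, length.out = spec$n_x)
    g <- spec$a * exp(-spec$lambda * xn) + spec$c
    rows <- lapply(seq_len(spec$n_frames), function(j) {
      t_j <- (j - 1) * spec$frame_interval
      prof <- if (j %% 2 == 1) g else rev(g)
      y <- prof * exp(-spec$bleach * t_j)
      if (spec$noise_sd > 0)
        y <- pmax(y + stats::rnorm(spec$n_x, 0, spec$noise_sd), 0)
      data.frame(cell_id = "synth", frame = j, time_s = t_j, x_norm = xn,
                 intensity = y, length_um = spec$length_um)
    })
    out <- do.call(rbind, rows)
    attr(out, "truth") <- list(bleach = spec$bleach,
                               lambda = spec$lambda,
                               I_ratio = .truth_iratio(spec$a, spec$lambda,
                                                       spec$c))
    out
  })
}

#' Synthetic snapshot series with biexponential bleaching
#'
#' Per-cell total intensities grow linearly in time
#' (\eqn{\beta + \alpha t}) and are multiplied by the biexponential
#' photobleaching factor \eqn{f(k) = a_1 e^{-b_1 k} + a_2 e^{-b_2 k}} of the
#' exposure round `k`. A normalized reference decay series (constant true
#' signal under the same bleaching) is generated alongside.
#'
#' @param n_cells number of cells
#' @param n_rounds exposure rounds per cell (k = 0 .. n_rounds - 1)
#' @param interval time between exposures (s)
#' @param alpha linear growth slope (intensity/s)
#' @param beta intercept (intensity at the first bracketed frame)
#' @param biexp named vector `c(a1, b1, a2, b2)`; `a1 + a2` should be 1 so
#'   the reference starts at 1
#' @param noise_sd additive noise on intensities
#' @param seed RNG seed (mandatory)
#' @return list with `series` (a [snapshot_series()]), `reference`
#'   (data.frame `k`, `intensity`) and `truth`
#' @export
make_snapshot_series <- function(n_cells = 20, n_rounds = 30,
                                 interval = 900, alpha = 0.5, beta = 1000,
                                 biexp = c(a1 = 0.7, b1 = 0.05, a2 = 0.3,
                                           b2 = 0.005),
                                 noise_sd = 0, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  .with_seed(seed, {
    k <- 0:(n_rounds - 1)
    f <- biexp["a1"] * exp(-biexp["b1"] * k) +
      biexp["a2"] * exp(-biexp["b2"] * k)
    reference <- data.frame(k = k,
                            intensity = as.numeric(f / f[1]) +
                              if (noise_sd > 0)
                                stats::rnorm(n_rounds, 0, noise_sd / beta)
                              else 0)
    obs <- do.call(rbind, lapply(seq_len(n_cells), function(j) {
      tj <- k * interval
      true <- beta + alpha * tj
      y <- true * as.numeric(f)
      if (noise_sd > 0) y <- y + stats::rnorm(n_rounds, 0, noise_sd)
      data.frame(cell_id = j, k = k, time_s = tj, intensity = y)
    }))
    list(series = snapshot_series(obs),
         reference = reference,
         truth = list(alpha = alpha, beta = beta, biexp = biexp))
  })
}
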
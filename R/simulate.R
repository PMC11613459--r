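#' Simulation configuration
#'
#' Defaults follow the reference numerical setup: 0.2-um grid,
#' dt = 3.125e-5 s, 140 s of simulated time with the first 40 s discarded as
#' burn-in, and output frames every 0.15625 s (= 5000 steps), so detected
#' periods are exact multiples of the frame interval.
#'
#' The explicit scheme requires `dt <= dx^2 / (2 max D)`; the constructor
#' checks this against the supplied diffusion coefficients when
#' [simulate_min()] runs.
#'
#' @param length cell length (um)
#' @param dx grid spacing (um)
#' @param dt time step (s)
#' @param t_end total simulated time (s)
#' @param burn_in initial interval (s) excluded from analysis
#' @param frame_interval spacing of stored frames (s); must be an integer
#'   multiple of `dt`
#' @param totals a `min_totals`
#' @return object of class `sim_config`
#' @export
sim_config <- function(length, dx = 0.2, dt = 3.125e-5, t_end = 140,
                       burn_in = 40, frame_interval = 0.15625,
                       totals = reference_totals()) {
  stopifnot(inherits(totals, "min_totals"))
  if (length <= 0 || dx <= 0 || dt <= 0 || t_end <= 0)
    stop("length, dx, dt and t_end must be positive")
  if (burn_in >= t_end) stop("burn_in must be smaller than t_end")
  fe <- frame_interval / dt
  if (abs(fe - round(fe)) > 1e-8)
    stop("frame_interval must be an integer multiple of dt")
  nsteps <- t_end / frame_interval
  if (abs(nsteps - round(nsteps)) > 1e-8)
    stop("t_end must be an integer multiple of frame_interval")
  structure(list(length = length, dx = dx, dt = dt, t_end = t_end,
                 burn_in = burn_in, frame_interval = frame_interval,
                 totals = totals),
            class = "sim_config")
}

#' Initial condition: MinD polar cap, MinE uniform
#'
#' MinD starts concentrated in one half of the cell, with half of it
#' membrane-bound (`c_d`) and half cytosolic; MinE is distributed uniformly
#' in the cytosol. The cytosolic MinD half is assigned to the ATP-bound
#' binding-competent form `c_DT`; nucleotide exchange redistributes it
#' within ~1 s, so the long-run attractor is insensitive to this choice.
#' Totals are scaled to the simulated length at fixed concentration.
#'
#' @param config a `sim_config`
#' @return a `min_field`
#' @export
initialize_field <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- round(config$length / config$dx)
  if (n < 2) stop("grid has fewer than 2 points")
  x <- (seq_len(n) - 0.5) * config$dx
  dens <- protein_densities(config$totals)
  massD <- dens["minD"] * config$length
  massE <- dens["minE"] * config$length
  left <- x < config$length / 2
  n_left <- sum(left)
  if (n_left == 0) stop("no grid points in the left half")
  half_dens <- (massD / 2) / (n_left * config$dx)
  c_d <- ifelse(left, half_dens, 0)
  c_DT <- ifelse(left, half_dens, 0)
  min_field(x, c_DD = 0, c_DT = c_DT, c_E = unname(massE / config$length),
            c_d = c_d, c_de = 0)
}

#' Integrate the Min reaction-diffusion equations
#'
#' Propagates the five-species system by explicit forward Euler with a
#' central-difference Laplacian and no-flux (mirrored ghost point)
#' boundaries, storing frames every `frame_interval`. The maximum per-step
#' concentration change relative to the mean density is monitored; a value
#' above 5% indicates the step size is too coarse for the kinetics and
#' triggers a warning.
#'
#' @param params a `min_params`
#' @param config a `sim_config`
#' @param D a `min_diffusion`
#' @param field optional initial `min_field`; defaults to
#'   [initialize_field()]
#' @return object of class `min_kymograph`: list with `time` (s), `x` (um),
#'   five frame-by-position species matrices, and `I`, the membrane-bound
#'   MinD intensity `c_d + c_de` normalized to its maximum over the stored
#'   frames
#' @export
simulate_min <- function(params, config, D = reference_diffusion(),
                         field = NULL) {
  stopifnot(inherits(params, "min_params"), inherits(config, "sim_config"),
            inherits(D, "min_diffusion"))
  Dmax <- max(D$D_D, D$D_E, D$D_d, D$D_de)
  if (Dmax > 0 && config$dt > config$dx^2 / (2 * Dmax))
    stop("explicit-scheme stability violated: need dt <= dx^2/(2 max D) = ",
         format(config$dx^2 / (2 * Dmax)))
  if (is.null(field)) field <- initialize_field(config)
  stopifnot(inherits(field, "min_field"))
  n <- length(field$x)
  if (abs(field$dx - config$dx) > 1e-9)
    stop("field grid spacing does not match config dx")

  c0 <- rbind(field$c_DD, field$c_DT, field$c_E, field$c_d, field$c_de)
  frame_every <- as.integer(round(config$frame_interval / config$dt))
  nsteps <- as.integer(round(config$t_end / config$dt))
  nsteps <- (nsteps %/% frame_every) * frame_every
  res <- min_integrate_cpp(c0, config$dx, config$dt, nsteps, frame_every,
                           k = c(params$k_D, params$k_dD, params$k_dE,
                                 params$k_de, params$k_ADP_ATP),
                           D = c(D$D_D, D$D_D, D$D_E, D$D_d, D$D_de))
  if (res$max_rel_change > 0.05)
    warning("per-step concentration change exceeded 5% of the maximum ",
            "density (", format(res$max_rel_change),
            "); consider a smaller dt")
  times <- seq(0, by = config$frame_interval,
               length.out = nrow(res$c_d))
  memb <- res$c_d + res$c_de
  mx <- max(memb)
  structure(list(time = times, x = field$x,
                 c_DD = res$c_DD, c_DT = res$c_DT, c_E = res$c_E,
                 c_d = res$c_d, c_de = res$c_de,
                 I = if (mx > 0) memb / mx else memb,
                 max_rel_change = res$max_rel_change,
                 config = config, params = params, D = D),
            class = "min_kymograph")
}

#' Construct a kymograph from an intensity matrix
#'
#' Used by the synthetic generators and by tests; `I` is renormalized to
#' its maximum.
#'
#' @param time frame times (s)
#' @param x positions (um)
#' @param I frame-by-position intensity matrix
#' @param truth optional list of ground-truth metrics
#' @return object of class `min_kymograph`
#' @export
as_min_kymograph <- function(time, x, I, truth = NULL) {
  stopifnot(nrow(I) == length(time), ncol(I) == length(x))
  mx <- max(I)
  structure(list(time = time, x = x, I = if (mx > 0) I / mx else I,
                 truth = truth),
            class = "min_kymograph")
}

#' Total MinD and MinE mass per frame
#'
#' @param kymo a `min_kymograph` produced by [simulate_min()]
#' @return data.frame with columns `time`, `minD`, `minE` (molecules)
#' @export
kymo_mass <- function(kymo) {
  stopifnot(inherits(kymo, "min_kymograph"))
  if (is.null(kymo$c_DD)) stop("kymograph does not carry species trajectories")
  dx <- kymo$config$dx
  data.frame(time = kymo$time,
             minD = rowSums(kymo$c_DD + kymo$c_DT + kymo$c_d + kymo$c_de) * dx,
             minE = rowSums(kymo$c_E + kymo$c_de) * dx)
}

#' Write a kymograph as long-format TSV
#'
#' One row per (time, position, species); species are the five model fields
#' plus the normalized membrane intensity `I`.
#'
#' @param kymo a `min_kymograph`
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_kymograph <- function(kymo, path) {
  stopifnot(inherits(kymo, "min_kymograph"))
  sp <- intersect(c(SPECIES, "I"), names(kymo))
  rows <- lapply(sp, function(s) {
    m <- kymo[[s]]
    data.frame(time_s = rep(kymo$time, times = length(kymo$x)),
               position_um = rep(kymo$x, each = length(kymo$time)),
               species = s, density = as.vector(m))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.min_kymograph <- function(x, ...) {
  cat(sprintf("Min kymograph: %d frames x %d grid points\n",
              length(x$time), length(x$x)))
  cat(sprintf("  t = [%g, %g] s, x = [%g, %g] um\n",
              min(x$time), max(x$time), min(x$x), max(x$x)))
  invisible(x)
}

#' Plot a kymograph
#'
#' @param x a `min_kymograph`
#' @param ... passed to [graphics::image()]
#' @export
plot.min_kymograph <- function(x, ...) {
  graphics::image(x$time, x$x, x$I, xlab = "time (s)",
                  ylab = "position (um)", ...)
  invisible(x)
}
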
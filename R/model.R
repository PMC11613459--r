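SPECIES <- c("c_DD", "c_DT", "c_E", "c_d", "c_de")

#' Construct a 1D concentration field
#'
#' Holds the five species densities (molecules/um) on a cell-centered grid.
#' `c_DD`/`c_DT` are cytosolic MinD-ADP/MinD-ATP, `c_E` cytosolic MinE,
#' `c_d` membrane-bound MinD-ATP and `c_de` the membrane-bound MinDE complex.
#'
#' @param x grid-point positions (um), equally spaced cell centers
#' @param c_DD,c_DT,c_E,c_d,c_de species densities, one value per grid point
#' @return object of class `min_field`
#' @export
min_field <- function(x, c_DD, c_DT, c_E, c_d, c_de) {
  n <- length(x)
  dens <- list(c_DD = c_DD, c_DT = c_DT, c_E = c_E, c_d = c_d, c_de = c_de)
  for (nm in names(dens)) {
    v <- dens[[nm]]
    if (length(v) == 1L) dens[[nm]] <- rep(v, n)
    else if (length(v) != n) stop(nm, " must have length 1 or length(x)")
    if (any(!is.finite(dens[[nm]])) || any(dens[[nm]] < 0))
      stop(nm, " must be finite and non-negative")
  }
  if (n > 1) {
    dx <- diff(x)
    if (max(abs(dx - dx[1])) > 1e-9 * dx[1]) stop("grid must be equally spaced")
    dx <- dx[1]
  } else dx <- NA_real_
  structure(c(list(x = x, dx = dx), dens), class = "min_field")
}

#' Total MinD and MinE mass of a field
#'
#' MinD mass sums `c_DD + c_DT + c_d + c_de`, MinE mass `c_E + c_de`, each
#' times the grid spacing. Both are conserved by the reaction-diffusion
#' dynamics under no-flux boundaries.
#'
#' @param field a `min_field`
#' @return named vector `c(minD = , minE = )`, in molecules
#' @export
field_mass <- function(field) {
  stopifnot(inherits(field, "min_field"))
  c(minD = sum(field$c_DD + field$c_DT + field$c_d + field$c_de) * field$dx,
    minE = sum(field$c_E + field$c_de) * field$dx)
}

#' Reaction terms of the Min model
#'
#' Evaluates, per grid point, the chemical-kinetics part of the five
#' governing equations (no diffusion):
#' \deqn{dc_{DD} = -k_{ADP\to ATP} c_{DD} + k_{de} c_{de}}
#' \deqn{dc_{DT} = k_{ADP\to ATP} c_{DD} - (k_D c_{DT} + k_{dD} c_d c_{DT})}
#' \deqn{dc_E = k_{de} c_{de} - k_{dE} c_d c_E}
#' \deqn{dc_d = k_D c_{DT} + k_{dD} c_d c_{DT} - k_{dE} c_d c_E}
#' \deqn{dc_{de} = k_{dE} c_d c_E - k_{de} c_{de}}
#' The MinD terms and the MinE terms each sum to zero identically (mass
#' conservation).
#'
#' @param field a `min_field` (or a named list/vector with the five species)
#' @param params a `min_params`
#' @return list of the five per-species time derivatives (molecules/um/s)
#' @export
reaction_rates <- function(field, params) {
  stopifnot(inherits(params, "min_params"))
  cDD <- field$c_DD; cDT <- field$c_DT; cE <- field$c_E
  cd <- field$c_d; cde <- field$c_de
  if (any(c(cDD, cDT, cE, cd, cde) < 0))
    stop("negative density in field")
  exch <- params$k_ADP_ATP * cDD
  att  <- params$k_D * cDT
  rec  <- params$k_dD * cd * cDT
  flux <- params$k_dE * cd * cE
  rel  <- params$k_de * cde
  list(c_DD = -exch + rel,
       c_DT = exch - att - rec,
       c_E  = rel - flux,
       c_d  = att + rec - flux,
       c_de = flux - rel)
}

# evaluate the five reaction terms at a uniform state given as a 5-vector
# in SPECIES order
reaction_rates_vec <- function(u, params) {
  f <- reaction_rates(list(c_DD = u[1], c_DT = u[2], c_E = u[3],
                           c_d = u[4], c_de = u[5]), params)
  unlist(f, use.names = FALSE)
}

# mass-constraint residual in c_d for the uniform steady state; all other
# species are eliminated through the stationarity identities
.ss_from_cd <- function(cd, params, dD, dE) {
  cE  <- dE / (1 + params$k_dE * cd / params$k_de)
  cde <- dE - cE
  cDT <- params$k_de * cde / (params$k_D + params$k_dD * cd)
  cDD <- params$k_de * cde / params$k_ADP_ATP
  c(c_DD = cDD, c_DT = cDT, c_E = cE, c_d = cd, c_de = cde)
}

#' Homogeneous steady state of the Min model
#'
#' Finds the spatially uniform state `u*` with vanishing reaction terms under
#' the two mass constraints (`c_DD + c_DT + c_d + c_de` equals the MinD
#' density, `c_E + c_de` the MinE density). The problem is reduced to a
#' single unknown, the membrane MinD density `c_d`: stationarity of the
#' individual reactions expresses every other species in terms of `c_d`,
#' leaving a scalar mass-balance residual that is bracketed on
#' `[0, minD density]`, located by a sign-change scan and polished with
#' [stats::uniroot()]. If the residual has several sign changes every root is
#' returned and the result is flagged.
#'
#' @param params a `min_params`
#' @param totals a `min_totals`
#' @param length cell length (um); the steady state itself is
#'   length-independent because densities are fixed, but the argument is kept
#'   for interface symmetry with the stability analysis
#' @param n_scan number of scan points for root bracketing
#' @param tol residual tolerance on the five reaction terms
#' @return list with `u` (named 5-vector, the physical root), `residual`
#'   (max abs reaction term), `all_roots` (matrix, one row per root) and
#'   `multiple_roots` flag
#' @export
uniform_steady_state <- function(params, totals, length = NULL,
                                 n_scan = 4096, tol = 1e-9) {
  stopifnot(inherits(params, "min_params"), inherits(totals, "min_totals"))
  dens <- protein_densities(totals)
  dD <- unname(dens["minD"]); dE <- unname(dens["minE"])

  g <- function(cd) {   # vectorized in cd
    cE <- dE / (1 + params$k_dE * cd / params$k_de)
    cde <- dE - cE
    cde * params$k_de / (params$k_D + params$k_dD * cd) +
      cde * params$k_de / params$k_ADP_ATP + cd + cde - dD
  }
  grid <- seq(0, dD, length.out = n_scan)
  gv <- g(grid)
  sgn <- sign(gv)
  idx <- which(sgn[-1] * sgn[-n_scan] < 0)
  roots <- numeric(0)
  for (i in idx) {
    r <- stats::uniroot(g, c(grid[i], grid[i + 1]), tol = .Machine$double.eps^0.75)
    roots <- c(roots, r$root)
  }
  # exact hits on scan points
  roots <- sort(unique(c(roots, grid[gv == 0])))
  if (!length(roots))
    stop("steady-state search failed: no sign change of the mass residual; ",
         "max |g| = ", format(min(abs(gv))))
  states <- t(vapply(roots, .ss_from_cd, numeric(5),
                     params = params, dD = dD, dE = dE))
  res <- apply(states, 1, function(u)
    max(abs(reaction_rates_vec(unname(u), params))))
  if (min(res) > tol)
    stop("steady-state residual ", format(min(res)), " exceeds tolerance ",
         format(tol))
  best <- which.min(res)
  list(u = states[best, ], residual = res[best],
       all_roots = states, multiple_roots = length(roots) > 1L)
}
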
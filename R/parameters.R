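#' Kinetic rate constants of the Min reaction network
#'
#' Bundles the five rate constants governing the reaction steps of the
#' 1D Min model: spontaneous membrane attachment of cytosolic MinD-ATP
#' (`k_D`, 1/s), recruitment of cytosolic MinD-ATP by membrane-bound MinD
#' (`k_dD`, um/s), recruitment of cytosolic MinE by membrane-bound MinD
#' (`k_dE`, um/s), dissociation of the membrane-bound MinDE complex through
#' MinE-stimulated ATP hydrolysis (`k_de`, 1/s), and cytosolic nucleotide
#' exchange recharging MinD-ADP to MinD-ATP (`k_ADP_ATP`, 1/s).
#'
#' Concentrations are linear densities (molecules/um), so the second-order
#' constants `k_dD` and `k_dE` carry units um/s and every product
#' `k * c * c` has units (molecules/um)/s.
#'
#' @param k_D spontaneous membrane attachment rate (1/s)
#' @param k_dD MinD self-recruitment rate (um/s)
#' @param k_dE MinE recruitment rate (um/s)
#' @param k_de MinDE dissociation rate (1/s)
#' @param k_ADP_ATP nucleotide exchange rate (1/s)
#' @return object of class `min_params`
#' @examples
#' min_params(1.66, 0.22, 0.82, 0.33, 1.09)
#' @export
min_params <- function(k_D, k_dD, k_dE, k_de, k_ADP_ATP) {
  p <- list(k_D = k_D, k_dD = k_dD, k_dE = k_dE, k_de = k_de,
            k_ADP_ATP = k_ADP_ATP)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(nm, " must be a single finite positive number")
  }
  structure(p, class = "min_params")
}

#' Diffusion coefficients of the five Min species
#'
#' `D_D` applies to both cytosolic MinD-ADP and MinD-ATP, `D_E` to cytosolic
#' MinE; `D_d` and `D_de` are the (much smaller) membrane-bound MinD and
#' MinDE coefficients. All in um^2/s.
#'
#' @param D_D cytosolic MinD diffusion (um^2/s)
#' @param D_E cytosolic MinE diffusion (um^2/s)
#' @param D_d membrane-bound MinD diffusion (um^2/s)
#' @param D_de membrane-bound MinDE diffusion (um^2/s)
#' @return object of class `min_diffusion`
#' @export
min_diffusion <- function(D_D = 16, D_E = 10, D_d = 0.2, D_de = 0.2) {
  d <- list(D_D = D_D, D_E = D_E, D_d = D_d, D_de = D_de)
  for (nm in names(d)) {
    v <- d[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop(nm, " must be a single finite non-negative number")
  }
  structure(d, class = "min_diffusion")
}

#' Total protein copy numbers and the reference cell length
#'
#' Copy numbers are held at fixed concentration when rescaling to other cell
#' lengths: the linear densities `minD_total / reference_length` and
#' `minE_total / reference_length` (molecules/um) are invariant.
#'
#' @param minD_total total MinD molecules per cell at `reference_length`
#' @param minE_total total MinE molecules per cell at `reference_length`
#' @param reference_length cell length (um) at which the counts apply
#' @return object of class `min_totals`
#' @export
min_totals <- function(minD_total = 2205, minE_total = 1580,
                       reference_length = 2.84) {
  t <- list(minD_total = minD_total, minE_total = minE_total,
            reference_length = reference_length)
  for (nm in names(t)) {
    v <- t[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(nm, " must be a single finite positive number")
  }
  structure(t, class = "min_totals")
}

#' Reference kinetic parameter set (#2827)
#'
#' The screened reference set that reproduces the experimental oscillation
#' features: k_D = 1.66 1/s, k_dD = 0.22 um/s, k_dE = 0.82 um/s,
#' k_de = 0.33 1/s, k_ADP_ATP = 1.09 1/s.
#'
#' @return a `min_params` object
#' @export
reference_params <- function() {
  min_params(k_D = 1.66, k_dD = 0.22, k_dE = 0.82, k_de = 0.33,
             k_ADP_ATP = 1.09)
}

#' Reference diffusion coefficients
#'
#' Cytosolic MinD 16 um^2/s, cytosolic MinE 10 um^2/s, membrane-bound
#' species 0.2 um^2/s.
#'
#' @return a `min_diffusion` object
#' @export
reference_diffusion <- function() min_diffusion()

#' Reference protein totals
#'
#' 2,205 MinD and 1,580 MinE molecules per cell (1.95 and 1.40 uM) at the
#' experimental median cell length of 2.84 um.
#'
#' @return a `min_totals` object
#' @export
reference_totals <- function() min_totals()

#' Linear protein densities (molecules/um)
#'
#' Densities are length-invariant because totals scale proportionally with
#' length at fixed concentration.
#'
#' @param totals a `min_totals` object
#' @return named vector with elements `minD` and `minE`
#' @export
protein_densities <- function(totals) {
  stopifnot(inherits(totals, "min_totals"))
  c(minD = totals$minD_total / totals$reference_length,
    minE = totals$minE_total / totals$reference_length)
}

#' @export
print.min_params <- function(x, ...) {
  cat("Min kinetic parameters:\n")
  cat(sprintf("  k_D       = %g 1/s\n", x$k_D))
  cat(sprintf("  k_dD      = %g um/s\n", x$k_dD))
  cat(sprintf("  k_dE      = %g um/s\n", x$k_dE))
  cat(sprintf("  k_de      = %g 1/s\n", x$k_de))
  cat(sprintf("  k_ADP_ATP = %g 1/s\n", x$k_ADP_ATP))
  invisible(x)
}

#' Read a table of kinetic parameter sets
#'
#' Expects a CSV with header columns `set_id, k_D, k_dD, k_dE, k_de,
#' k_ADP_ATP, D_D, D_E, D_d, D_de`.
#'
#' @param path CSV file path
#' @return data.frame with one row per parameter set
#' @export
read_parameter_sets <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("set_id", "k_D", "k_dD", "k_dE", "k_de", "k_ADP_ATP",
            "D_D", "D_E", "D_d", "D_de")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("parameter CSV is missing columns: ", paste(miss, collapse = ", "))
  df
}

#' Write a table of kinetic parameter sets
#'
#' @param df data.frame as produced by [sample_parameter_sets()] or read by
#'   [read_parameter_sets()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_parameter_sets <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Extract one row of a parameter table as model objects
#'
#' @param df parameter table
#' @param set_id id of the row to extract
#' @return list with components `params` (`min_params`) and `D`
#'   (`min_diffusion`)
#' @export
parameter_row <- function(df, set_id) {
  row <- df[df$set_id == set_id, , drop = FALSE]
  if (nrow(row) != 1L) stop("set_id ", set_id, " not found (or duplicated)")
  list(params = min_params(row$k_D, row$k_dD, row$k_dE, row$k_de,
                           row$k_ADP_ATP),
       D = min_diffusion(row$D_D, row$D_E, row$D_d, row$D_de))
}
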
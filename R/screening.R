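#' Randomly sample kinetic parameter sets
#'
#' Each of `k_D`, `k_dD`, `k_dE` and `k_ADP_ATP` is drawn as `10^N` with
#' independent `N ~ Normal(0, 3)`; `k_de` is fixed at 0.33 1/s (the dynamics
#' are particularly sensitive to it in time) and the diffusion coefficients
#' at their reference values. Uses the current R RNG state; call
#' `set.seed()` for reproducibility.
#'
#' @param n number of sets
#' @param start_id first `set_id` (consecutive integers follow)
#' @return parameter table (data.frame) in the CSV column layout of
#'   [read_parameter_sets()]
#' @export
sample_parameter_sets <- function(n, start_id = 1L) {
  draw <- function() 10^stats::rnorm(n, 0, 3)
  D <- reference_diffusion()
  data.frame(set_id = seq.int(start_id, length.out = n),
             k_D = draw(), k_dD = draw(), k_dE = draw(), k_de = 0.33,
             k_ADP_ATP = draw(),
             D_D = D$D_D, D_E = D$D_E, D_d = D$D_d, D_de = D$D_de)
}

#' Screening configuration
#'
#' The four-filter screen: F1 linear instability of the pole-to-pole mode
#' (`q = pi/L` at the reference length), F2 a spatiotemporal pattern
#' (nonzero period at more than one simulated length), F3 period >=
#' `period_min` and a pole-to-pole pattern at the focus lengths, F4
#' `lambda_range[1] <= lambda_N <= lambda_range[2]` at the focus lengths.
#'
#' @param n_sets number of parameter sets entering the screen
#' @param lengths simulated cell lengths (um)
#' @param t_end simulated time per run (s)
#' @param burn_in discarded initial interval (s)
#' @param period_min minimum period (s) for F3
#' @param lambda_range allowed `lambda_N` interval for F4
#' @param focus_lengths lengths (um) at which F3/F4 are evaluated
#' @param stability_length length (um) defining the F1 wavenumber
#' @param count_semantics `"draws"`: `n_sets` are drawn and all screened;
#'   `"survivors"`: sampling continues until `n_sets` sets pass F1
#' @param require_both require F3/F4 to hold at *both* focus lengths
#'   (otherwise at least one)
#' @return object of class `screen_config`
#' @export
screen_config <- function(n_sets, lengths = seq(1.6, 4.6, by = 0.2),
                          t_end = 140, burn_in = 40,
                          period_min = 15, lambda_range = c(1.2, 3),
                          focus_lengths = c(2.8, 3.0),
                          stability_length = 3.0,
                          count_semantics = c("draws", "survivors"),
                          require_both = TRUE) {
  count_semantics <- match.arg(count_semantics)
  stopifnot(n_sets >= 1, all(diff(lengths) > 0), period_min > 0,
            lambda_range[1] > 0, lambda_range[2] > lambda_range[1])
  if (!all(focus_lengths %in% lengths))
    stop("focus_lengths must be among the simulated lengths")
  structure(list(n_sets = n_sets, lengths = lengths, t_end = t_end,
                 burn_in = burn_in, period_min = period_min,
                 lambda_range = lambda_range, focus_lengths = focus_lengths,
                 stability_length = stability_length,
                 count_semantics = count_semantics,
                 require_both = require_both),
            class = "screen_config")
}

# per-length metrics of one parameter set
.screen_one <- function(params, D, totals, config) {
  res <- lapply(config$lengths, function(L) {
    cfg <- sim_config(length = L, t_end = config$t_end,
                      burn_in = config$burn_in, totals = totals)
    kymo <- simulate_min(params, cfg, D)
    m <- kymo_metrics(kymo, window = c(config$burn_in, config$t_end))
    data.frame(length_um = L, period_s = m$period, lambda_N = m$lambda_N,
               I_ratio = m$I_ratio, pattern_class = m$pattern_class)
  })
  do.call(rbind, res)
}

#' Run the four-filter parameter screen
#'
#' Samples parameter sets (under the caller's RNG state), applies the linear
#' stability screen (F1), simulates every F1 survivor at all configured
#' lengths, and applies the period/pattern/gradient filters F2-F4. Filters
#' are monotone: each filter is evaluated only on the survivors of the
#' previous one, so `pass = f1 & f2 & f3 & f4`.
#'
#' @param config a `screen_config`
#' @param totals a `min_totals`
#' @param sets optional pre-built parameter table (e.g. read with
#'   [read_parameter_sets()]); when supplied no sampling takes place and
#'   `count_semantics` is ignored
#' @param progress print one line per simulated set
#' @return list with `sets` (parameter table with filter flags `f1..f4` and
#'   `pass`), `metrics` (per set and length), and `funnel` (named survivor
#'   counts after each filter)
#' @export
run_screen <- function(config, totals = reference_totals(), sets = NULL,
                       progress = FALSE) {
  stopifnot(inherits(config, "screen_config"))
  if (!is.null(sets)) {
    sets <- classify_instability_batch(sets, totals,
                                       length = config$stability_length)
    sets$f1 <- sets$oscillatory == 1L
  } else if (config$count_semantics == "draws") {
    sets <- sample_parameter_sets(config$n_sets)
    sets <- classify_instability_batch(sets, totals,
                                       length = config$stability_length)
    sets$f1 <- sets$oscillatory == 1L
  } else {
    # keep drawing until n_sets pass the linear-stability screen
    sets <- NULL; next_id <- 1L
    repeat {
      batch <- sample_parameter_sets(max(config$n_sets, 100L),
                                     start_id = next_id)
      next_id <- next_id + nrow(batch)
      batch <- classify_instability_batch(batch, totals,
                                          length = config$stability_length)
      batch$f1 <- batch$oscillatory == 1L
      sets <- rbind(sets, batch)
      if (sum(sets$f1) >= config$n_sets) break
    }
    cutoff <- which(sets$f1)[config$n_sets]
    sets <- sets[seq_len(cutoff), ]
  }
  sets$f2 <- FALSE; sets$f3 <- FALSE; sets$f4 <- FALSE
  metrics <- NULL
  agg <- if (config$require_both) all else any
  for (i in which(sets$f1)) {
    pr <- parameter_row(sets, sets$set_id[i])
    pm <- tryCatch(.screen_one(pr$params, pr$D, totals, config),
                   error = function(e) NULL)
    if (progress)
      message("set ", sets$set_id[i], ": ",
              if (is.null(pm)) "simulation failed"
              else paste0(sum(pm$period_s > 0), " oscillating lengths"))
    if (is.null(pm)) next
    pm$set_id <- sets$set_id[i]
    metrics <- rbind(metrics, pm)
    sets$f2[i] <- sum(pm$period_s > 0) > 1
    if (!sets$f2[i]) next
    foc <- pm[pm$length_um %in% config$focus_lengths, ]
    sets$f3[i] <- agg(foc$period_s >= config$period_min &
                        foc$pattern_class == "pole_to_pole")
    if (!sets$f3[i]) next
    sets$f4[i] <- agg(foc$lambda_N >= config$lambda_range[1] &
                        foc$lambda_N <= config$lambda_range[2])
  }
  sets$pass <- sets$f1 & sets$f2 & sets$f3 & sets$f4
  funnel <- c(sampled = nrow(sets), f1 = sum(sets$f1), f2 = sum(sets$f2),
              f3 = sum(sets$f3), f4 = sum(sets$f4), pass = sum(sets$pass))
  list(sets = sets, metrics = metrics, funnel = funnel)
}

#' One-constant sensitivity sweep
#'
#' Varies a single kinetic rate constant over a grid around a base set and
#' reports the oscillation descriptors at each value and length.
#'
#' @param params base `min_params`
#' @param constant name of the constant to vary
#' @param values values to substitute
#' @param lengths cell lengths (um) to simulate
#' @param D a `min_diffusion`
#' @param totals a `min_totals`
#' @param t_end,burn_in simulation horizon (s)
#' @return data.frame of descriptors per (value, length)
#' @export
sweep_constant <- function(params, constant, values,
                           lengths = c(2.8, 3.0), D = reference_diffusion(),
                           totals = reference_totals(), t_end = 140,
                           burn_in = 40) {
  stopifnot(constant %in% c("k_D", "k_dD", "k_dE", "k_de", "k_ADP_ATP"))
  out <- NULL
  for (v in values) {
    p <- params; p[[constant]] <- v
    p <- do.call(min_params, p[c("k_D", "k_dD", "k_dE", "k_de", "k_ADP_ATP")])
    for (L in lengths) {
      cfg <- sim_config(length = L, t_end = t_end, burn_in = burn_in,
                        totals = totals)
      m <- kymo_metrics(simulate_min(p, cfg, D),
                        window = c(burn_in, t_end))
      out <- rbind(out, data.frame(constant = constant, value = v,
                                   length_um = L, period_s = m$period,
                                   lambda_N = m$lambda_N,
                                   I_ratio = m$I_ratio,
                                   pattern_class = m$pattern_class))
    }
  }
  out
}
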
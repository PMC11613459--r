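# minwave

Simulation and analysis of MinD/MinE pole-to-pole oscillations in
*Escherichia coli*.

The Min system positions the bacterial division septum: MinD and MinE
oscillate between the cell poles, and the time-averaged MinD concentration
gradient — high at the poles, low at midcell — relieves MinC inhibition of
FtsZ-ring assembly only at the center. `minwave` is for quantitative
biologists and modelers who want to (i) simulate this oscillation with a
minimal 1D reaction-diffusion model, (ii) screen kinetic rate constants
for oscillatory regimes, (iii) quantify concentration gradients with the
same descriptors used on live-cell data, and (iv) run the measurement-side
algorithms (photobleaching correction, midcell intensity fractions,
two-sided exponential gradient fits) on fluorescence profile series.

## The model

Five species on the 1D cell axis — cytosolic MinD-ADP (c_DD), MinD-ATP
(c_DT) and MinE (c_E); membrane-bound MinD (c_d) and MinDE (c_de), all in
molecules/µm — evolve by

```
dc_DD/dt = D_D  ∇²c_DD − k_ADP→ATP c_DD + k_de c_de
dc_DT/dt = D_D  ∇²c_DT + k_ADP→ATP c_DD − (k_D + k_dD c_d) c_DT
dc_E/dt  = D_E  ∇²c_E  + k_de c_de − k_dE c_d c_E
dc_d/dt  = D_d  ∇²c_d  + (k_D + k_dD c_d) c_DT − k_dE c_d c_E
dc_de/dt = D_de ∇²c_de + k_dE c_d c_E − k_de c_de
```

with no-flux boundaries, integrated by explicit forward Euler
(dx = 0.2 µm, dt = 3.125e-5 s, compiled inner loop). The oscillating
gradient is summarized by the period, the decay constant λ_N of the
exponential fit I(x) = a·exp(−λ_N x) + c to the merged pole profile on the
normalized cell length, and I_Ratio = I_min/I_max, the relative MinD level
at midcell. A linear-stability screen (eigenvalues of the reaction
Jacobian minus D·q² at the pole-to-pole mode q = π/L) feeds a four-filter
random-parameter search for oscillatory kinetics.

## Worked example

```r
library(minwave)

cfg  <- sim_config(length = 3.0)              # 140 s, 0.2-µm grid
kymo <- simulate_min(reference_params(), cfg) # ~1 s, compiled loop
m    <- kymo_metrics(kymo)                    # analysis window 40-140 s
str(m[c("period", "pattern_class", "lambda_N", "I_ratio")])
#> List of 4
#>  $ period       : num 17.4
#>  $ pattern_class: chr "pole_to_pole"
#>  $ lambda_N     : num 2.1
#>  $ I_ratio      : num 0.493
```

A 3.0-µm cell under the reference kinetics oscillates pole-to-pole with a
17.4-s period (multiples of the 0.15625-s frame interval); the merged
pole profile decays with λ_N ≈ 2.10 on the normalized length, and the
midcell MinD level is ≈ 49% of the polar maximum. Longer cells steepen
the gradient and deplete midcell MinD:

```r
sapply(c(2.6, 3.8, 4.6), function(L) {
  k <- simulate_min(reference_params(), sim_config(length = L))
  unlist(kymo_metrics(k)[c("period", "lambda_N", "I_ratio")])
})
#>            [,1]      [,2]      [,3]
#> period   20.312 16.145833 16.500000
#> lambda_N  1.409  2.858361  2.882051
#> I_ratio   0.586  0.384160  0.330936
```

Screening random kinetics (the linear filter is cheap; full simulation of
survivors dominates):

```r
set.seed(1)
cfg <- screen_config(n_sets = 200, count_semantics = "survivors")
res <- run_screen(cfg)
res$funnel   # survivor counts after each filter
```

The reference kinetic set ships as a parameter CSV:

```r
sets <- read_parameter_sets(system.file("extdata",
          "reference_parameter_set.csv", package = "minwave"))
parameter_row(sets, 2827)$params
#> Min kinetic parameters:
#>   k_D       = 1.66 1/s
#>   k_dD      = 0.22 um/s
#>   k_dE      = 0.82 um/s
#>   k_de      = 0.33 1/s
#>   k_ADP_ATP = 1.09 1/s
```

Measurement-side analysis of a profile series (tidy CSV with columns
`cell_id, frame, time_s, x_norm, intensity, length_um`):

```r
series <- read_profile_series("profiles.csv")
corr   <- photobleach_normalize(series)     # removes fitted exp(-b t) decay
center_fraction(corr$series)                # intensity within ±100 nm of midcell
estimate_iratio_experimental(corr$series)   # two-sided exponential I_Ratio
```

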
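---
title: "Modeling and measuring Min-protein concentration gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and measuring Min-protein concentration gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

The MinD and MinE proteins of *Escherichia coli* oscillate from pole to
pole, and their time-averaged concentration profile — high at the poles,
low at midcell — licenses assembly of the division septum at the cell
center. `minwave` implements a one-dimensional five-species
reaction-diffusion model of this oscillation, the linear-stability
machinery used to screen kinetic rate constants, the descriptors that
quantify an oscillating gradient (period, the normalized decay constant
$\lambda_N$, and the midcell-to-pole intensity ratio $I_{Ratio}$), and the
algorithms used on measured fluorescence profiles (photobleaching
correction, center fraction, a two-sided exponential $I_{Ratio}$
estimator, biexponential snapshot correction). Synthetic-data generators
with machine-readable ground truth make every analysis stage testable
without microscopy data.

## The reaction-diffusion model

Five species live on the 1D cell axis: cytosolic MinD-ADP ($c_{DD}$) and
MinD-ATP ($c_{DT}$), cytosolic MinE ($c_E$), membrane-bound MinD-ATP
($c_d$), and the membrane-bound MinDE complex ($c_{de}$). Concentrations
are linear densities in molecules/µm. The reactions are

1. spontaneous membrane attachment of MinD-ATP (rate $k_D$, 1/s),
2. recruitment of cytosolic MinD-ATP by membrane-bound MinD ($k_{dD}$, µm/s),
3. recruitment of cytosolic MinE by membrane-bound MinD, forming MinDE
   ($k_{dE}$, µm/s),
4. MinE-stimulated ATP hydrolysis releasing MinD-ADP and MinE to the
   cytosol ($k_{de}$, 1/s),
5. cytosolic nucleotide exchange recharging MinD-ADP to MinD-ATP
   ($k_{ADP \to ATP}$, 1/s).

Each species diffuses with its own coefficient; cytosolic diffusion
($D_D = 16$, $D_E = 10$ µm²/s) is fast compared with membrane diffusion
($D_d = D_{de} = 0.2$ µm²/s), which is what allows cytosolic gradients to
form at all. Total MinD and MinE are conserved. The reference copy numbers
are 2,205 MinD and 1,580 MinE molecules per cell at the 2.84-µm median
cell length; when other lengths are simulated the totals are scaled
proportionally so the *concentration* is fixed (linear densities 776.4 and
556.3 molecules/µm are length-invariant).

The reference kinetic set (`reference_params()`) is
$k_D = 1.66$, $k_{dD} = 0.22$, $k_{dE} = 0.82$, $k_{de} = 0.33$,
$k_{ADP\to ATP} = 1.09$ (units as above). Because the second-order
constants act on products of linear densities, their µm/s units combine
with molecules/µm to give molecules/µm/s, consistent with the first-order
terms.

## Numerical scheme

`simulate_min()` integrates the equations by explicit forward Euler with a
central-difference Laplacian on a cell-centered grid of
$n = \mathrm{round}(L / \Delta x)$ points, $\Delta x = 0.2$ µm, no-flux
boundaries via mirrored ghost points, and $\Delta t = 3.125\times10^{-5}$ s
(40-fold below the diffusive stability bound
$\Delta x^2 / 2 D_{max} = 1.25\times10^{-3}$ s). Frames are stored every
0.15625 s $= 5000\,\Delta t$, so detected periods are multiples of the
frame interval, and runs last 140 s with the first 40 s discarded as
burn-in. The inner loop is compiled (Rcpp); a 140-s run at $L = 3$ µm
takes on the order of a second.

The integrator monitors the largest single-step density change of any
species relative to the current maximum density and warns above 5%; the
denominator is the maximum rather than the local value because species
start at exactly zero. Reference runs stay below ~2%.

The initial condition concentrates all MinD in one half of the cell, half
of it membrane-bound and half cytosolic, with MinE uniform. The cytosolic
half is assigned to ATP-bound MinD: the model does not say which cytosolic
form starts, but nucleotide exchange turns MinD-ADP over within
$\sim 1/k_{ADP\to ATP} \approx 1$ s, so the long-run attractor is
unaffected; the choice only fixes the initial transient and the phase.

```{r}
library(minwave)
cfg <- sim_config(length = 3.0)
kymo <- simulate_min(reference_params(), cfg)
kymo_metrics(kymo)
```

## Steady state and the linear-stability screen

The uniform steady state is found by reducing the five stationarity
conditions plus two mass constraints to a single equation in the membrane
MinD density $c_d$: every other species follows algebraically, and the
remaining MinD mass balance is bracketed on $[0, \text{MinD density}]$,
scanned for sign changes (4,096 points) and polished with `uniroot()`.
This is deterministic and oracle-checkable; if several roots exist all are
returned and flagged (physically relevant kinetic sets in our experience
have a single positive root). Residuals are at machine precision.

Linearizing about the steady state gives
$\partial_t \delta u = (A - D q^2)\, \delta u$ for a spatial perturbation
$\propto e^{iqx}$, with $A$ the 5×5 reaction Jacobian. The screen
evaluates the eigenvalues of $A_q$ at the pole-to-pole mode $q = \pi/L$
(wavelength $2L$, the least-oscillating mode compatible with no-flux
boundaries).

**Choice of verdict.** Two criteria are implemented in
`classify_instability()`. The strict Hopf-and-Turing reading — leading
eigenvalue with positive real part *and* nonzero imaginary part at
$q = \pi/L$ — turns out to reject essentially every randomly sampled
kinetic set (none of 3,000 draws pass) *including the reference set*,
whose full simulation nevertheless oscillates stably: at $q = \pi/3$
µm⁻¹ its unstable eigenvalue is purely real (0.729), and the temporal
rotation of the unstable mode only appears at much smaller wavenumbers.
The default criterion, `"divergence"`, therefore requires only a positive
real part of the leading eigenvalue at $q = \pi/L$: the pole-to-pole mode
grows, and the full nonlinear simulation — which the screen feeds — is
the arbiter of whether the growth resolves into a sustained oscillation.
Under this criterion roughly 2.5% of random draws pass, and about 29% of
the passers go on to show spatiotemporal patterns in full simulation,
which matches the screening yield the pipeline is designed around. The
strict variant remains available via `criterion = "hopf_turing"` (it is
satisfied, for example, by the reference kinetics on a long domain, where
$q$ is small).

Steady states with negative components are classified unphysical and
non-oscillatory; ties between a real and a complex eigenvalue at equal
real part go to the complex pair (the permissive direction for a screen).

## Oscillation descriptors

`detect_period()` finds, per grid point, the local temporal maxima of the
normalized membrane-bound MinD intensity $I = c_d + c_{de}$ in the 40–140-s
window. A grid point is accepted only when consecutive peak amplitudes
change by less than 5% (a dampening filter); its period is the mean
inter-peak interval. Peaks live on the frame grid — no sub-frame
interpolation — so periods are multiples of 0.15625 s. Across grid points
the package aggregates by the **median**: on an odd cell-centered grid one
point sits exactly at midcell, is visited by both half-waves each cycle,
and oscillates at *twice* the pole frequency with equal peak amplitudes.
It therefore passes the 5% filter while carrying half the period, and a
mean would be biased low by ~4% (its two neighbours, whose alternate peaks
differ by ~5%, are rejected by exactly that filter). The median ignores
the single degenerate grid point; the mean remains available via
`aggregate = "mean"`.

`pole_profiles()` collects the profiles at the times when the spatial
maximum peaks at the left or right pole. True peak times fall between
frames, and nearest-frame sampling leaves a spurious 0.2–0.6% left/right
asymmetry purely from sampling phase (the half-cycle is generally not an
integer number of frames); the profiles are therefore interpolated
quadratically in time at the sub-frame peak by default, after which the
left and mirrored-right profiles of the reference oscillation agree to
better than 0.01%. Each profile is normalized to its own maximum, the
right profile is mirrored, and the two are averaged into the merged
profile ("merging" is not otherwise specified; averaging preserves the
symmetry and the per-profile difference is reported alongside).

`fit_gradient()` fits $I(x) = a e^{-\lambda_N x} + c$ by nonlinear least
squares (`minpack.lm::nlsLM`, log-linear start values) on the
sub-interval from the profile maximum to the profile minimum, on the
normalized length. A profile whose spatial peak-to-trough range is below
1% of its mean has no gradient to speak of and returns $\lambda_N = 0$ by
convention — this operationalizes "oscillation in time but not in space"
seen in short cells. `compute_iratio()` reads
$I_{max} = I(x{=}0)$ and $I_{min} = I(x{=}0.5)$ off the merged profile
(linear interpolation between grid points) and is defined only for
pole-to-pole patterns.

`classify_pattern()` follows the temporal peaks of the spatial maximum and
the cell half each peak occupies: `pole_to_pole` when at least 90% of
consecutive peaks alternate sides across the window, `late_onset` when
that holds only over the trailing half, `none` when no grid point
oscillates in time, `irregular` otherwise. The 90% tolerance and the
half-split at $L/2$ are package choices (the pattern classes are defined
by example, not by rule); they are strict enough to reject single-pole and
erratic cases while tolerating one missed alternation in a 100-s window.

`fit_biphasic()` describes $\lambda_N$ versus length by a rising linear
segment followed by a plateau, choosing the breakpoint that minimizes the
total residual sum of squares, and falls back to a single constant when
BIC prefers it (exactly constant data short-circuit to the constant
model).

## The screening pipeline

`run_screen()` chains four filters: F1 linear instability at the
pole-to-pole mode of the 3.0-µm reference length; F2 a nonzero period at
more than one simulated length (1.6–4.6 µm in 0.2-µm steps by default);
F3 period ≥ 15 s and a pole-to-pole pattern at the 2.8- and 3.0-µm focus
lengths; F4 $1.2 \le \lambda_N \le 3$ there. Filters are monotone — each
is evaluated only on the survivors of the previous one. F3/F4 require
both focus lengths by default (`require_both = FALSE` relaxes to either);
the source text does not resolve and/or, and the conjunction is the
stricter, more reproducible reading. Two counting semantics are provided
because the published funnel is ambiguous about whether 5,000 sets were
drawn or collected: `"draws"` screens exactly `n_sets` samples, while
`"survivors"` (matching a funnel whose 5,000 all enter full simulation)
keeps sampling until `n_sets` pass F1.

Rate constants are sampled as $10^N$, $N \sim \mathcal{N}(0, 3)$,
independently for $k_D$, $k_{dD}$, $k_{dE}$ and $k_{ADP\to ATP}$, with
$k_{de}$ fixed at 0.33 1/s and diffusion at the reference values.

## Measurement-side algorithms

These operate on tidy per-cell profile series (columns `frame`, `time_s`,
`x_norm`, `intensity`, `length_um`) as produced by medial-axis projection
of time-lapse movies; segmentation itself is out of scope.

**Photobleaching normalization.** Frames are min-shifted to zero, the
per-frame totals $S_{T_j}$ are fitted with $a e^{-bt}$, and the fitted
decay is divided out so corrected totals are trend-free. The source
formula multiplies by $e^{-\hat b T_j}$, which *deepens* a decay with
$\hat b > 0$ rather than removing it; since the stated purpose is decay
removal we treat the sign as a typo, implement the corrective direction,
and keep the printed form behind `printed_sign = TRUE`.

**Center fraction.** The midcell zone spans ±100 nm of midcell,
i.e. $[0.5 - 0.1/L,\ 0.5 + 0.1/L]$ on the normalized axis. Zone
boundaries are linearly interpolated, zone and total intensity integrated
by the trapezoidal rule, and the fraction averaged over the first 20
frames.

**Two-sided $I_{Ratio}$ estimator.** Frames are split into left- and
right-peaked groups by 2-means clustering on the intensity slopes at
$x = 0.2$ and $0.8$ (local linear regression over ±0.05; the window width
is unstated upstream and exposed as a parameter). The clustering is
initialized deterministically from the extreme-slope frames, removing RNG
sensitivity. Frames whose slope magnitude falls in the pooled first
quartile are excluded as too flat (pooled, not per-group — the
per-group alternative is a one-line change). Each group is smoothed by
Gaussian-kernel regression (bandwidth: `bw.nrd0` of the pooled positions
unless given) to locate the peak $m_i$; a two-sided exponential
$d_i e^{-\lambda_i |x - m_i|}$ is then fitted per group, the decay rates
pooled into the frame-count-weighted mean $\lambda'$, and amplitudes
refitted with $\lambda'$ fixed (amplitudes only; offsets are not refit).
$I_{min}$ is the intensity at the closed-form intersection of the two
refitted curves, $I_{max}$ the maximum of the fitted curves — the fitted
rather than the kernel-smoothed maximum, because boundary bias of kernel
regression at a pole peak would otherwise contaminate an estimator whose
other ingredient ($I_{min}$) is fit-based. The estimator is scale
invariant, and errors out when the frames do not span both pole states.

**Biexponential snapshot correction.** For snapshot series indexed by
exposure round $k$, a reference decay (constant true signal) is fitted
with $f(k) = a_1 e^{-b_1 k} + a_2 e^{-b_2 k}$; cell intensities are
divided by $\hat f(k)$ and regressed linearly on time within each cell's
division bracket, giving per-cell growth slopes and population means. A
constant reference (no bleaching) short-circuits the degenerate fit.
`molecules_from_intensity()` pins a fitted intensity-versus-time line to a
calibration anchor (e.g. 2,205 molecules at the mid-doubling-time
snapshot) to convert intensities to molecule counts, and multiplies by the
center fraction for midcell-zone counts.

## Synthetic data

`make_kymograph()` builds
$I(x,t) = m_L(t)\,g(x) + (1 - m_L(t))\,g(1{-}x)$ with
$g(x) = a e^{-\lambda x} + c$ and a cosine envelope of period $T$ — an
idealized standing-wave oscillation with closed-form truth
($\lambda_N = \lambda$,
$I_{Ratio} = (a e^{-\lambda/2} + c)/(a + c)$). `make_profile_series()`
emulates measured series: alternating-pole gradients, multiplicative
bleaching $e^{-bt}$, additive Gaussian noise. `make_snapshot_series()`
produces linearly growing totals under biexponential bleaching plus the
reference decay. Defaults follow the measured reference conditions:
gradient $a = 0.96$, $\lambda = 2.89$, $c = 0.17$; period 46 s (the
experimental median); 12-s frames; 2.84-µm cells. Noise is additive
Gaussian, matching the least-squares assumptions of the analysis stages —
shot noise, uneven illumination, cell-shape effects and segmentation
errors of real microscopy are *not* emulated, so passing recovery tests
demonstrates correctness of the estimators, not robustness to every
feature of real data. Every generator requires a seed, restores the
caller's RNG state, and attaches its truth record for the test harness.

## Problem sizes and tolerances used in the tests

The test suite runs the full reference simulations (140 s at 2.6–4.6 µm)
for the regression checks; the screening-yield check uses a desk-scale
proxy — 200 stability-passing sets simulated at four lengths
(1.6/2.6/3.6/4.6 µm) for 60 s — whose pass fraction band was measured
across seeds beforehand. Parameter-recovery checks use 100 replicates
(gradient fits), 50 replicates ($I_{Ratio}$), and noiseless
50-point series (biexponential). Stochastic recovery bounds are asserted
on the replicate mean plus a ≥95% within-tolerance quantile, since
individual replicates sit ~2 estimator standard deviations from the
bound by construction.

## Known limitations

* The model is strictly 1D with fixed totals: no membrane geometry,
  MinD nucleation, stochastic kinetics, or growth during a run
  (lengths are simulated independently).
* Simulated periods are 5–10× shorter than measured ones under the
  reference kinetics; the minimal five-reaction scheme reproduces the
  *shape* descriptors ($\lambda_N$, $I_{Ratio}$) and their length trends,
  not absolute timescales.
* The steady-state reduction assumes strictly positive rate constants;
  exact zeros (e.g. a switched-off attachment pathway) are handled as
  limits with tiny rates.
* `fit_biphasic()` assumes at most one breakpoint.
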
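---
title: "Min oscillations and cell-size control: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Min oscillations and cell-size control: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minsize)
```

# The scientific question

In *E. coli*, the MinCDE system oscillates pole to pole and, averaged over
time, leaves the mid-cell membrane least occupied by the division inhibitor
MinC, which travels with membrane-bound MinD.  FtsZ can therefore nucleate a
stable septal ring only near mid-cell, and only once the cell is long enough
for the oscillation to clear that site for a sufficient fraction of time.
`minsize` implements the computational chain that turns this idea into
testable predictions: a 1-d reaction–diffusion model of the MinD/MinE
oscillation, an occupancy score that maps the MinE/MinD expression ratio to
a ring-permissive cell length, induction kinetics for *minE* overexpression,
a generational growth recursion predicting the transient delay of ring
formation and the monotonic rise of birth size, a synthetic mother-machine
data generator, and the single-cell trace statistics used to analyse such
data.

# The 1-d Min model

Five species are tracked as linear densities (molecules/µm) along the cell
axis: cytosolic MinD:ADP (`c_DD`), cytosolic MinD:ATP (`c_DT`), cytosolic
MinE (`c_E`), membrane-bound MinD (`m_d`) and the membrane-bound MinDE
complex (`m_de`).  The reactions are the established cooperative-recruitment
scheme: nucleotide exchange converts `c_DD` to `c_DT` at rate `k_exchange`;
`c_DT` binds the membrane at a basal rate `sigma_D` plus a cooperative rate
`sigma_dD (m_d + m_de)`; cytosolic MinE is recruited onto membrane MinD at
rate `sigma_E m_d c_E`, forming `m_de`; and the complex hydrolyses and
detaches at `sigma_de`, releasing MinD:ADP and MinE back to the cytosol.
Both boundaries are reflecting (no flux).  MinC is not modelled explicitly:
it co-localizes with membrane MinD, so "MinCD occupancy" is the sum
`m_d + m_de`.

## Parameters and the 1-d reduction

The defaults are the literature volume/surface rate constants of the
cooperative Min model, converted to effective 1-d units for a cylindrical
cell of radius r = 0.5 µm: a surface rate `s` (µm/s) acting on a volume
concentration becomes `(2/r)·s` (1/s) acting on a linear density, and a
bimolecular volume rate `k` (µm³/s) becomes `k/(πr²)` (µm/s per
molecule/µm).

| parameter | default | units | origin |
|---|---|---|---|
| `D_D`, `D_E` | 2.5 | µm²/s | cytosolic diffusion |
| `D_m` | 0 | µm²/s | membrane species immobile |
| `sigma_D` | 0.1 | 1/s | (2/r)·0.025 µm/s |
| `sigma_dD` | 1.91e-3 | µm/s per molec/µm | 0.0015 µm³/s / (πr²) |
| `sigma_E` | 0.118 | µm/s per molec/µm | 0.093 µm³/s / (πr²) |
| `sigma_de` | 0.7 | 1/s | complex hydrolysis/detachment |
| `k_exchange` | 1 | 1/s | ADP→ATP exchange |
| `dens_D`, `dens_E` | 1000, 350 | molec/µm | wild-type ratio 0.35 |

At these defaults a 4 µm cell oscillates pole to pole with a period of
≈ 40.5 s, the canonical in vivo timescale, and the period changes by < 0.2%
when the grid is refined twofold.

## Numerics

Method of lines with second-order central differences and ghost-cell
no-flux boundaries; fixed-step classical RK4 with
`dt = min(0.4 dx²/max(D), 0.5/rate_max)`, where `rate_max` carries a 4×
safety factor on the bimolecular rates because local densities transiently
exceed their spatial means severalfold.  Two structural properties are
engineered to hold at machine precision rather than merely to tolerance:

* **Conservation.**  Each reaction flux is computed once and moved between
  species, and the discrete Laplacian telescopes, so MinD and MinE totals
  drift only by accumulated rounding (≈ 1e-14 relative over 600 s, against
  a declared tolerance of 1e-6; exceeding it aborts the run).
* **Symmetry.**  The Laplacian is evaluated as `(left + right) − 2·centre`;
  because IEEE addition commutes, a mirror-symmetric state remains
  bit-exactly mirror-symmetric.  Oscillations therefore require the seeded
  1% asymmetric perturbation applied to the initial MinD:ATP profile
  (`initialize_fields()`), and the symmetric run is a sharp regression test.

Negative densities more negative than −1e-12·`dens_D` abort the
integration; smaller undershoots are clipped to zero and counted.  A 200 s
burn-in discards the symmetry-breaking transient before any statistic is
computed.  Default resolution is dx = 0.05 µm with 1 s sampling; the length
scans use dx = 0.1 µm and 400–800 s, which the grid-convergence test shows
is period-accurate to ≈ 0.1%.

# Mid-cell occupancy and the optimal length

The paper-level statistic is the fraction of time a w = 0.5 µm window at
mid-cell holds fewer membrane-bound MinD molecules than a threshold θ.  The
threshold is expressed relative to the spatially uniform expectation (the
window's share of all membrane-bound molecules at that instant), making it
portable across lengths and expression ratios.  The default is θ = 0.5:
measured across lengths, the deepest wild-type mid-cell dip of this model
reaches ≈ 0.44× the uniform expectation, so 0.5 cleanly separates the
"swept clear" phase of the oscillation from the occupied phase, whereas a
much stricter threshold (e.g. 0.2) classifies every sample as occupied at
every length and carries no information.

Three optimal-length criteria are implemented: `argmax_free_time` (the
default; ties break toward the smaller length), `min_length_above` (the
smallest length whose free-time fraction reaches `f_min`), and
`argmin_avg_occupancy` (the length at which the time-averaged relative
mid-cell occupancy is smallest — the "minimal average MinCD concentration"
criterion).  The last remains well defined near the oscillation boundary,
where amplitudes shrink below any fixed threshold, and is therefore used for
the ratio scan.  A parabolic refinement between grid lengths is reported
alongside the raw grid optimum; the quoted uncertainty is always the scan's
length spacing.

## The oscillatory window and the scan range

Raising `dens_E` at fixed `dens_D` (the *minE*-overexpression direction)
destabilizes the oscillation: both direct simulation and linear stability
analysis of the dispersion relation locate the upper boundary of the
oscillatory window at ≈ 1.12× the wild-type ratio for these kinetics (the
window in `dens_E` is roughly 156–381 molecules/µm at `dens_D` = 1000).
Within the window the permissive length rises steeply and monotonically as
the boundary is approached — from ≈ 3.3 µm to ≈ 4.9 µm over multipliers
1.00–1.10 — and is well described by a linear first-order map (R² ≈ 0.92 to
0.97 depending on the perturbation seed).  The packaged ratio scan
(`analysis/02_ratio_scan.R`, and `t4` of `scripts/acceptance.R`) therefore
covers multipliers 1.00–1.10 in steps of 0.02 over lengths 2.5–7 µm; this
is the "small range of change" over which a first-order linear description
of size versus ratio is meaningful in this model.  Beyond the boundary the
homogeneous state is stable, mid-cell is never cleared, and no optimum
exists — the wide threefold scan shipped alongside documents exactly this.
Mapping the full experimentally accessible threefold expression range onto
model densities would require a mechanism (e.g. persistent membrane-bound
MinE) outside this five-species scheme; the linear map is therefore treated
as a first-order approximation to be extrapolated, which is also how the
generational model consumes it.

# Induction kinetics and the generational recursion

MinE rises after induction as a sigmoid
`MinE(t) = MinE_init + (MinE_final − MinE_init) / (1 + exp(−(t − t_c)/t_s))`
with half-rise time `t_c` and timescale `t_s`; with MinD constant the
relative ratio is `R/R_0(t) = MinE(t)/MinE_init`.  Two printed-form caveats
are preserved deliberately: the curve does not pass exactly through
`MinE_init` at t = 0 (the sigmoid's offset is the stated approximation),
and one timescale past `t_c` the added amount reaches `1/(1+e^{-1}) ≈ 0.731`
of its maximum, slightly above the "about two thirds" description.  Times
may be specified in minutes or in generations; generation units are
converted with the uninduced doubling time and re-converted once against
the realized mean cycle time.

Each generation g samples the ratio once at its start, sets the permissive
length through the linear map `L_stable = a + b·(R/R_0)`, grows
exponentially at rate α until reaching it after
`T_z = log(L_stable/L_0)/α` (clamped at 0 for cells born beyond it — the
ring then forms immediately), grows a further fixed time τ, and divides in
half: `L_0(g+1) = ½ L_0(g) e^{α(T_z+τ)}`.  At constant ratio the recursion
has the fixed point `L_0* = ½ L_stable e^{ατ}` with cycle time exactly
`ln 2/α`, reached from any starting size below `L_stable` in a single
generation; under a sigmoid ratio rise `T_z` is transiently elevated and
returns to baseline while `L_0` increases monotonically to a higher
plateau.  These are the two qualitative signatures the experiments show.

Defaults: α = ln 2/25 min⁻¹ (25-minute doubling, rich medium at 32 °C) and
τ = 18.75 min, so the uninduced ring forms at the end of the first quarter
of the cycle, as observed for uninduced cells.  The default length map
(a = 2.4, b = 0.6 µm per unit R/R₀) is calibrated to the experimental
magnitudes — 3.0 µm permissive length uninduced rising to 4.2 µm at a
threefold ratio, a ≈ 40% increase — because the simulation-derived map
lives on the model's own (narrow) ratio scale.  The chained pipeline
(`run_pipeline(use_sim_map = TRUE)`) instead carries the simulation map
with the induction plateau expressed on the model scale; both routes are
exposed and the choice is recorded in the resolved configuration.

## Sister cells

Sisters inherit near-equal Min concentrations, so both ring at the same
`L_stable` and divide at `L_stable·e^{ατ}`; a sister born at fraction `f`
of the mother therefore adds `L_stable·e^{ατ} − f·L_mother`, giving exactly
`Δ_A − Δ_B = −(f_A − f_B)·L_mother`.  The regression of the added-length
difference on the birth-fraction difference across pairs has slope
`−mean(L_mother)`, which the analysis checks against its standard error.

# The synthetic mother-machine generator

`generate_lineage()` emulates the measurement design: old-pole lineages
imaged at 1-min cadence, 39 lineages × 16 generations by default with
induction at generation 8.  Per cycle, α, τ and `L_stable` carry
multiplicative lognormal noise (means as above; CVs 7%, 7% and 5% — the
source measurements report only SDs of derived quantities, so these are
chosen as typical single-cell variabilities and are configurable), division
fractions are truncated-normal around ½ (SD 0.035), and the FtsZ ring
intensity accumulates piecewise-linearly to a plateau with its rate change
at 65% of the maximum, reached exactly at the configured ring-stabilization
time, plus Gaussian noise (SD 20 on a 1000 a.u. plateau) and a constant
background (100 a.u.).  In the noiseless limit the generator reproduces
`run_generations()` exactly (asserted to 1e-12), which makes the analysis
functions testable by round trip.

What the generator does **not** emulate: pixel-level imaging and
segmentation error, filamentous or multi-ring cells, asymmetric Min
partitioning at division, photobleaching, and correlated noise between
sisters or across generations.  Passing round-trip tests therefore
demonstrates correctness of the estimators under the generative model, not
robustness to every artefact of real microscopy data.

# Trace analysis conventions

Ring timing takes each cycle's own background-corrected maximum as
reference and linearly interpolates the first 65% crossing; the cell length
at that moment is interpolated exponentially (consistent with exponential
growth); the post-ring interval and the size ratio `S_D/S_z` use the
division time and length from the cycle record rather than the last imaging
frame.  Shifting the threshold to 0.5 or 0.8 shifts the timing but leaves
the generation of peak delay unchanged, which the suite asserts.  Cycles
whose corrected intensity never exceeds zero are excluded and counted,
mirroring experimental dropout.  Aggregates are means with SEM = SD/√n per
generation relative to induction; single-record bins report `NA` rather
than zero SEM.  Adder statistics (OLS of added length on birth length) are
reported, never asserted, on noisy data: the pure threshold-length model is
a sizer with respect to division noise (slope −1), and the suite pins that
limit on noiseless lineages, while induction-driven co-variation can push
the population slope positive.

# Problem sizes and runtime

The shipped analyses are sized for a single CPU: the headline oscillation
run is one 600 s simulation at dx = 0.05 µm (≈ 5 s); the ratio scan is
6 multipliers × 10 lengths at dx = 0.1 µm and 800 s (≈ 1.5 min); the
synthetic dataset is 624 cycles (≈ 2 s); the full test suite runs in about
a minute.  Larger scans only refine the length resolution; they do not
change any conclusion shown here.

# Known limitations

* The 1-d reduction compresses radial geometry into effective rate
  constants; absolute optimal lengths are therefore parameterization-
  dependent and only the qualitative shape of the ratio–size map should be
  compared with measurements.
* The five-species scheme loses oscillations above ≈ 1.12× the wild-type
  MinE/MinD ratio, so the linear ratio–size map is an in-window fit used as
  a first-order extrapolation elsewhere.
* The generational model samples the ratio once per cycle; continuous
  growth-coupled Min simulation is out of scope.
* Division is exactly symmetric in the recursion (factor ½); stochastic
  partitioning lives only in the synthetic-data generator.
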
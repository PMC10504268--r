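# minsize

Min-protein oscillations and cell-size control in *Escherichia coli*: a
simulation and analysis toolkit for the mechanism by which the MinE/MinD
expression ratio sets the cell length at which a stable FtsZ (Z-)ring can
form, and thereby the division size.

It is written for quantitative microbiologists and biophysicists who study
cell-size homeostasis with mother-machine time-lapse data and want the full
computational chain in one tested package:

1. **`mindyn`** — a deterministic 1-d reaction–diffusion model of the
   MinD/MinE pole-to-pole oscillation (five species: cytosolic MinD:ADP,
   MinD:ATP, MinE; membrane MinD and MinDE), integrated by a conservative
   RK4 method-of-lines scheme (Rcpp) with no-flux boundaries.
2. **`occupancy`** — mid-cell occupancy scoring: the fraction of time a
   0.5 µm window at mid-cell is free of membrane-bound MinD (the MinC
   proxy), the optimal (division-permissive) cell length per condition, and
   the linear map from the MinE/MinD ratio to that length.
3. **`sizemodel`** — arabinose-induction kinetics
   `MinE(t) = MinE_i + (MinE_f − MinE_i)/(1 + e^{−(t−t_c)/t_s})`, the
   four-parameter logistic dose–response `R(C)`, and the generational
   recursion `T_z(g) = α⁻¹ log(L_stable(g)/L_0(g))`,
   `L_0(g+1) = ½ L_0(g) e^{α(T_z(g)+τ)}`, plus the sister-cell prediction
   `Δ_A − Δ_B = −(f_A − f_B) L_mother`.
4. **`synthdata`** — a synthetic mother-machine generator (exponentially
   growing lineages at 1-min cadence, two-slope ring-intensity accumulation
   with its rate change at 65% of maximum, near-symmetric noisy division).
5. **`traceanalysis`** — the single-cell measurement pipeline:
   65%-threshold ring timing, sizes at ring formation and division,
   per-generation aggregates (mean ± SEM), sister-pair regression, adder
   statistics and growth-parameter recovery.

The scripts under `analysis/` chain these stages as a narrative workflow
and write their tables under `results/`.

## Worked example

```r
library(minsize)

# 1. wild-type Min oscillation in a 4 um cell
sim <- simulate_min(min_params(), min_grid(4, dx = 0.05), t_end = 600, seed = 0)
detect_period(sim$pole_signal, 1, burn_in = 200)
#> [1] 40.48363
```

The pole-to-pole period is ≈ 40 s, the canonical in vivo timescale, and the
time-averaged membrane profile (`time_average_profile(sim, 200)`) dips at
mid-cell — the site a stable Z-ring can occupy.

```r
# 2. permissive length vs MinE/MinD ratio (model's oscillatory window)
scan <- scan_ratios(min_params(), seq(1, 1.10, 0.02), seq(2.5, 7, 0.5),
                    criterion = "argmin_avg_occupancy",
                    t_end = 800, dx = 0.1, seed = 1)
scan$optima$L_opt_refined
#> [1] 3.305398 3.440372 3.686135 4.023720 4.513175 4.862285
c(scan$fit_slope, scan$fit_R2)
#> [1] 16.2006157  0.9685591
```

The permissive length rises monotonically with the MinE/MinD ratio and is
well fitted by a linear first-order map over this small range of change
(above ≈ 1.12× wild type the oscillation is lost; see the methods
vignette).

```r
# 3. generational prediction after minE induction (threefold ratio rise)
traj <- run_generations(20)
round(traj[c(1, 3, 9, 21), c("g", "ratio_rel", "Tz_min", "L0_um")], 2)
#>     g ratio_rel Tz_min L0_um
#> 1   0      1.24   7.93  2.52
#> 3   2      2.08   9.43  2.81
#> 9   8      3.00   6.28  3.53
#> 21 20      3.00   6.25  3.53
```

The ring-formation time `T_z` rises transiently (7.9 → 9.4 min) and
returns to its uninduced baseline (6.25 min) within a few generations,
while the birth length climbs monotonically to a plateau 40% higher — the
two single-cell signatures of the mechanism.  The synthetic mother-machine
dataset (`generate_lineage()`) reproduces this recursion exactly in its
noiseless limit, and `analyze_cycles()` / `aggregate_by_generation()`
recover it from the noisy traces:

```r
# 4. sister-cell test on 121 synthetic pairs
pairs <- generate_sister_pairs(lineage_config(seed = 7), n_pairs = 121)
st <- sister_pair_stats(pairs)
c(slope = st$slope, predicted = st$predicted_slope, se = st$slope_se)
#>     slope predicted        se
#> -6.200756 -5.018161  0.643831
```

The smaller-born sister adds more length; the regression slope agrees with
the model's prediction `−mean(L_mother)` within three standard errors.

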
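#!/usr/bin/env Rscript
# Optimal (division-permissive) cell length as a function of the MinE/MinD
# expression ratio.  Two scans:
#   (a) the operative scan over the model's oscillatory window (multipliers
#       1.00-1.10), where the mid-cell depletion is well defined and the
#       optimal length rises; a linear first-order map is fitted there;
#   (b) a wide threefold scan (multipliers 1->3), reported for completeness:
#       the homogeneous state of this model restabilizes above ~1.12x wild
#       type, so most of that range has no oscillation and no optimum.
# Writes results/ratio_scan.csv, results/ratio_scan_wide.csv,
# results/lopt_fit.json.

library(minsize)
dir.create("results", showWarnings = FALSE)

cat("Scan (a): multipliers 1.00-1.10, lengths 2.5-7 um, dx = 0.1 um, 800 s\n")
scan <- scan_ratios(min_params(), ratio_multipliers = seq(1, 1.10, 0.02),
                    lengths = seq(2.5, 7, 0.5),
                    criterion = "argmin_avg_occupancy",
                    t_end = 800, dx = 0.1, seed = 1)
print(scan$optima)
cat(sprintf("Linear map: L_opt = %.2f + %.2f x (R/R0), R^2 = %.3f ",
            scan$fit_intercept, scan$fit_slope, scan$fit_R2))
cat(sprintf("(resolution %.2f um)\n", scan$resolution))
cat("The permissive length rises monotonically with the MinE/MinD ratio\n")
cat("within the oscillatory window -- the first-order linear description\n")
cat("holds over this small range of change.\n\n")

write.csv(scan$table, "results/ratio_scan.csv", row.names = FALSE)
write.csv(scan$optima, "results/ratio_scan_optima.csv", row.names = FALSE)
jsonlite::write_json(list(a = scan$fit_intercept, b = scan$fit_slope,
                          R2 = scan$fit_R2, resolution = scan$resolution,
                          criterion = scan$criterion),
                     "results/lopt_fit.json", auto_unbox = TRUE, digits = NA)

cat("Scan (b): multipliers 1->3 (threefold), same lengths\n")
wide <- lapply(seq(1, 3, length.out = 6), function(m) {
  res <- suppressWarnings(
    optimal_length(with_ratio(min_params(), m), seq(2.5, 7, 0.5),
                   criterion = "argmin_avg_occupancy",
                   t_end = 400, dx = 0.1, seed = 1))
  cbind(ratio_multiplier = m, res$scan,
        L_opt = res$L_opt, L_opt_refined = res$L_opt_refined)
})
wide <- do.call(rbind, wide)
write.csv(wide, "results/ratio_scan_wide.csv", row.names = FALSE)
opt_by_ratio <- unique(wide[, c("ratio_multiplier", "L_opt")])
print(opt_by_ratio, row.names = FALSE)
n_dead <- sum(!is.finite(opt_by_ratio$L_opt))
cat(sprintf(
  "%d of %d multipliers in the threefold scan have no oscillation and no\n",
  n_dead, nrow(opt_by_ratio)))
cat("optimum: the oscillatory window of this parameterization ends near\n")
cat("1.12x wild type, so the linear ratio-size map is an extrapolation\n")
cat("beyond that point.\n")
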
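#!/usr/bin/env Rscript
# Induction kinetics and the generational growth recursion: the relative
# MinE/MinD ratio trajectory after arabinose induction, and the predicted
# per-generation ring-formation time T_z and birth length L_0.
# Writes results/induction_curve.csv and results/generations.csv.

library(minsize)
dir.create("results", showWarnings = FALSE)

induction <- induction_params() # threefold rise, t_c = 50 min, t_s = 25 min
times <- seq(-50, 400, by = 1)
curve <- data.frame(time_min = times,
                    ratio_rel = ratio_trajectory(induction, times))
write.csv(curve, "results/induction_curve.csv", row.names = FALSE)
cat(sprintf("Ratio trajectory: 1.00 before induction, %.2f at t_c = %g min, ",
            ratio_trajectory(induction, induction$t_c), induction$t_c))
cat(sprintf("plateau %.2f\n", induction$minE_final / induction$minE_initial))

growth <- growth_params()
traj <- run_generations(20, growth, induction)
write.csv(traj, "results/generations.csv", row.names = FALSE)

Tz_base <- 0.25 * log(2) / growth$alpha # quarter-cycle uninduced baseline
peak <- which.max(traj$Tz_min) - 1
cat(sprintf("T_z: baseline %.2f min, peaks at %.2f min in generation %d,\n",
            Tz_base, max(traj$Tz_min), peak))
cat(sprintf("back within 1%% of baseline by generation %d.\n",
            min(traj$g[abs(traj$Tz_min - Tz_base) / Tz_base < 0.01 &
                         traj$g > peak])))
cat(sprintf("Birth length rises monotonically: %.2f -> %.2f um (+%.0f%%).\n",
            traj$L0_um[1], traj$L0_um[21],
            100 * (traj$L0_um[21] / traj$L0_um[1] - 1)))
cat("The ring-formation delay is transient while the birth size settles at\n")
cat("a permanently higher plateau, as the recursion predicts.\n")
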
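#!/usr/bin/env Rscript
# Single-cell trace analysis of the synthetic mother-machine dataset:
# 65%-threshold ring timing per cycle, per-generation aggregates (means +/-
# SEM relative to induction), adder statistics and growth-parameter recovery.
# Reads results/cycles.csv + results/intensity.csv (run 04 first; they are
# regenerated here if absent).  Writes results/ring_timing.csv,
# results/generation_aggregates.csv, results/adder_stats.json,
# results/recovered_params.json.

library(minsize)
dir.create("results", showWarnings = FALSE)

config <- lineage_config(seed = 7)
if (!file.exists("results/cycles.csv")) {
  synth <- generate_lineage(config)
  cycles <- synth$cycles; intensity <- synth$intensity
} else {
  cycles <- read.csv("results/cycles.csv")
  intensity <- read.csv("results/intensity.csv")
}

an <- analyze_cycles(cycles, intensity, threshold_fraction = 0.65,
                     background_mean = config$background_mean)
write.csv(an$timing, "results/ring_timing.csv", row.names = FALSE)
cat(sprintf("Ring timing for %d cycles (%d excluded).\n", nrow(an$timing),
            an$n_excluded))

agg <- aggregate_by_generation(an$timing)
write.csv(agg, "results/generation_aggregates.csv", row.names = FALSE)
t65 <- agg[agg$metric == "t65" & agg$generation_rel >= -2, ]
cat("Mean time to 65% ring intensity by generation (min):\n")
print(data.frame(generation = t65$generation_rel,
                 t65 = round(t65$mean, 2), sem = round(t65$sem, 2)),
      row.names = FALSE)
cat("The ring-formation delay rises after induction and relaxes back while\n")
cat("birth size remains permanently larger -- the single-cell signature.\n")

add <- adder_stats(an$timing)
jsonlite::write_json(add, "results/adder_stats.json", auto_unbox = TRUE,
                     digits = NA)
cat(sprintf("Added-vs-birth-length slope: %.2f +/- %.2f (r = %.2f, n = %d)\n",
            add$slope, add$slope_se, add$pearson_r, add$n))

rec <- recover_growth_params(cycles, intensity,
                             background_mean = config$background_mean)
jsonlite::write_json(list(alpha = rec$alpha, tau = rec$tau,
                          L_stable_by_generation = rec$L_stable_by_generation),
                     "results/recovered_params.json", auto_unbox = TRUE,
                     digits = NA)
cat(sprintf("Recovered alpha = %.4f /min (configured %.4f), tau = %.1f min ",
            rec$alpha$estimate, config$alpha_mean, rec$tau$estimate))
cat(sprintf("(configured %.1f).\n", config$tau_mean))
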
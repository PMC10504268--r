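test_that("background correction is plain subtraction, unclipped", {
  expect_equal(background_correct(c(10, 12), 3), c(7, 9))
  expect_equal(background_correct(c(5, 5), 5), c(0, 0))
  expect_equal(background_correct(c(2, 8), 0), c(2, 8))
  expect_equal(background_correct(c(1, 2), 5), c(-4, -3)) # negatives kept
})

test_that("ring timing interpolates the 65% crossing", {
  tt <- 0:10
  ramp <- seq(0, 100, by = 10)
  len <- 2 * exp(0.028 * tt)
  rt <- ring_formation_time(tt, ramp, len)
  expect_equal(rt$t65, 6.5)
  expect_equal(rt$S_z_est, 2 * exp(0.028 * 6.5), tolerance = 1e-12)
  rt2 <- ring_formation_time(tt, ramp, len, threshold_fraction = 1)
  expect_equal(rt2$t65, 10) # time of the maximum
  expect_error(ring_formation_time(tt, rep(-1, 11), len), "background")
})

test_that("the analysis recovers the generator's ring-stabilization times", {
  cfg <- noiseless_config()
  g <- generate_lineage(cfg)
  an <- analyze_cycles(g$cycles, g$intensity)
  expect_equal(an$n_excluded, 0)
  expect_lt(max(abs(an$timing$t65 - an$timing$Tz_true_min)),
            cfg$sampling_interval)
  # post-ring interval uses the exact division time from the record
  expect_lt(max(abs(an$timing$post_interval - cfg$tau_mean)),
            cfg$sampling_interval)
})

test_that("per-generation aggregates follow the SEM convention", {
  timing <- data.frame(generation_rel = c(0, 0, 1), t65 = c(4, 6, 5))
  agg <- aggregate_by_generation(timing, metrics = "t65")
  g0 <- agg[agg$generation_rel == 0, ]
  expect_equal(g0$mean, 5)
  expect_equal(g0$sd, sd(c(4, 6)))
  expect_equal(g0$sem, sd(c(4, 6)) / sqrt(2)) # = 1
  g1 <- agg[agg$generation_rel == 1, ]
  expect_equal(g1$mean, 5)
  expect_true(is.na(g1$sem)) # single record: flagged, not zero
})

test_that("aggregated noiseless lineages show the rise-then-return shape", {
  cfg <- noiseless_config(n_lineages = 3)
  g <- generate_lineage(cfg)
  an <- analyze_cycles(g$cycles, g$intensity)
  agg <- aggregate_by_generation(an$timing, metrics = c("t65", "S0_um"))
  t65 <- agg[agg$metric == "t65", ]
  t65 <- t65[order(t65$generation_rel), ]
  post <- t65[t65$generation_rel >= 0, ]
  expect_gt(max(post$mean), post$mean[1])            # transient rise
  expect_lt(post$mean[nrow(post)], max(post$mean))   # and return
  s0 <- agg[agg$metric == "S0_um", ]
  s0 <- s0[order(s0$generation_rel), ]
  expect_true(all(diff(s0$mean[s0$generation_rel >= 0]) >= -1e-9))
})

test_that("shifting the ring threshold shifts but does not reshape timing", {
  cfg <- lineage_config(n_lineages = 6, n_generations = 12,
                        induction_start_gen = 6, seed = 3)
  g <- generate_lineage(cfg)
  peak_gen <- sapply(c(0.5, 0.65, 0.8), function(f) {
    an <- analyze_cycles(g$cycles, g$intensity, threshold_fraction = f,
                         background_mean = cfg$background_mean)
    agg <- aggregate_by_generation(an$timing, metrics = "t65")
    agg <- agg[agg$generation_rel >= 0, ]
    agg$generation_rel[which.max(agg$mean)]
  })
  expect_equal(peak_gen[1], peak_gen[2])
  expect_equal(peak_gen[3], peak_gen[2])
})

test_that("sister statistics match the model and its symmetries", {
  cfg <- noiseless_config(division_fraction_sd = 0.06, tau_mean = 10)
  pairs <- generate_sister_pairs(cfg, n_pairs = 60)
  st <- sister_pair_stats(pairs)
  expect_equal(st$slope, -mean(pairs$L_mother), tolerance = 1e-9)
  # swapping the sister labels negates both axes: slope unchanged
  swapped <- data.frame(pair_id = pairs$pair_id, L_mother = pairs$L_mother,
                        f_A = pairs$f_B, f_B = pairs$f_A,
                        delta_A = pairs$delta_B, delta_B = pairs$delta_A)
  st2 <- sister_pair_stats(swapped)
  expect_equal(st2$slope, st$slope, tolerance = 1e-12)
  # equal fractions give identically zero differences and a degenerate fit
  eq <- generate_sister_pairs(noiseless_config(), n_pairs = 10)
  expect_equal(eq$delta_A - eq$delta_B, rep(0, 10), tolerance = 1e-10)
  expect_true(sister_pair_stats(eq)$degenerate)
})

test_that("adder statistics distinguish adder and sizer limits", {
  set.seed(5)
  S0 <- runif(200, 2, 4)
  adder <- data.frame(S0_um = S0, SD_um = S0 + 3 + rnorm(200, 0, 1e-8))
  a <- adder_stats(adder)
  expect_equal(a$slope, 0, tolerance = 1e-6)
  expect_lt(abs(a$pearson_r), 0.2)
  sizer <- data.frame(S0_um = S0, SD_um = rep(6, 200))
  s <- adder_stats(sizer)
  expect_equal(s$slope, -1, tolerance = 1e-12)
  # threshold-length lineages with division noise only are sizers
  cfg <- noiseless_config(division_fraction_sd = 0.03, n_generations = 40,
                          induction_start_gen = Inf)
  g <- generate_lineage(cfg)
  m <- adder_stats(g$cycles)
  expect_equal(m$slope, -1, tolerance = 1e-6)
})

test_that("growth parameters are recovered from lineage data", {
  cfg <- noiseless_config(n_lineages = 2)
  g <- generate_lineage(cfg)
  rec <- recover_growth_params(g$cycles, g$intensity)
  expect_equal(rec$alpha$estimate, cfg$alpha_mean, tolerance = 1e-10)
  expect_lt(abs(rec$tau$estimate - cfg$tau_mean), cfg$sampling_interval)
  base_gen <- rec$L_stable_by_generation
  pre <- base_gen[base_gen$generation_rel < 0, ]
  expect_equal(mean(pre$mean), l_stable(cfg$growth, 1),
               tolerance = 0.05)
  # 5% biological noise, 100 cycles: recovery within 5%
  cfgn <- lineage_config(n_lineages = 10, n_generations = 10,
                         alpha_cv = 0.05, tau_cv = 0.05, lstable_cv = 0.05,
                         induction_start_gen = Inf, seed = 12)
  gn <- generate_lineage(cfgn)
  recn <- recover_growth_params(gn$cycles, gn$intensity,
                                background_mean = cfgn$background_mean)
  expect_lt(abs(recn$alpha$estimate - cfgn$alpha_mean) / cfgn$alpha_mean, 0.05)
  expect_lt(abs(recn$tau$estimate - cfgn$tau_mean) / cfgn$tau_mean, 0.05)
})

test_that("degenerate cycles are skipped with a logged reason", {
  cfg <- noiseless_config(n_lineages = 1, n_generations = 12)
  g <- generate_lineage(cfg)
  # strip one cycle's series to two samples: it must be skipped, not crash
  keep <- !(g$intensity$generation == 2 & g$intensity$time_min > 1)
  intensity <- g$intensity[keep, ]
  expect_message(rec <- recover_growth_params(g$cycles, intensity),
                 "skipped")
  expect_equal(rec$n_skipped, 1L)
})
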
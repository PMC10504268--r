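test_that("the induction sigmoid obeys its midpoint and limit identities", {
  p <- induction_params(minE_initial = 2, minE_final = 8, t_c = 40, t_s = 10)
  expect_equal(minE_at(p$t_c, p), 2 + (8 - 2) / 2)
  expect_equal(minE_at(p$t_c + 50 * p$t_s, p), 8, tolerance = 1e-9)
  # one timescale past the half-rise: 1/(1+e^-1) of the added amount
  expect_equal(minE_at(p$t_c + p$t_s, p), 2 + 6 / (1 + exp(-1)))
  expect_error(induction_params(minE_initial = 3, minE_final = 1))
})

test_that("the relative ratio trajectory is monotone and normalized", {
  p <- induction_params(minE_initial = 1, minE_final = 3, t_c = 50, t_s = 25)
  expect_equal(ratio_trajectory(p, -1e6), 1, tolerance = 1e-12)
  expect_equal(ratio_trajectory(p, p$t_c), 2) # midpoint of 1 -> 3
  tt <- seq(-100, 400, by = 7)
  expect_true(all(diff(ratio_trajectory(p, tt)) >= 0))
  p0 <- induction_params(minE_initial = 1)
  p0$minE_initial <- 0
  expect_error(ratio_trajectory(p0, 0), "minE_initial")
})

test_that("the dose-response logistic evaluates the printed constants", {
  p <- dose_response_params() # fitted RT-qPCR curve constants
  expect_equal(dose_response(p$inflection, p), 2.878 + 179.63 / 2) # 92.693
  expect_equal(dose_response(0, p),
               2.878 + 179.63 / (1 + exp(0.182 / 0.158)))
  expect_true(all(diff(dose_response(seq(0, 1, 0.05), p)) > 0))
  flat <- dose_response_params(offset = 5, amplitude = 0)
  expect_equal(dose_response(c(0, 0.3, 1), flat), rep(5, 3))
})

test_that("noiseless dose-response data are refitted exactly", {
  p <- dose_response_params()
  C <- seq(0, 1, length.out = 8)
  fit <- fit_dose_response(C, dose_response(C, p))
  expect_equal(fit$params$amplitude, p$amplitude, tolerance = 1e-6)
  expect_equal(fit$params$inflection, p$inflection, tolerance = 1e-6)
  expect_equal(fit$params$offset, p$offset, tolerance = 1e-4)
  expect_equal(fit$params$scale, p$scale, tolerance = 1e-6)
  expect_false(fit$unidentifiable)
})

test_that("flat dose-response data are flagged unidentifiable", {
  C <- seq(0, 1, length.out = 8)
  fit <- fit_dose_response(C, rep(5, 8) + c(-1, 1) * 1e-9)
  expect_lt(abs(fit$params$amplitude), 0.01)
  expect_true(fit$unidentifiable)
})

test_that("fit uncertainties cover the generating parameters", {
  p <- dose_response_params()
  C <- seq(0, 1, length.out = 12)
  truth <- dose_response(C, p)
  hits <- 0
  set.seed(2024)
  n_rep <- 100
  for (i in seq_len(n_rep)) {
    fit <- tryCatch(fit_dose_response(C, truth + rnorm(length(C), 0, 2)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    ok <- abs(fit$params$amplitude - p$amplitude) <=
      3 * fit$stderr["amplitude"] &&
      abs(fit$params$inflection - p$inflection) <=
      3 * fit$stderr["inflection"]
    if (isTRUE(unname(ok))) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("time to ring formation follows the growth law with its clamp", {
  expect_equal(time_to_ring(3, 3, 0.03), 0)
  expect_equal(time_to_ring(2, 4, log(2)), 1) # one doubling at alpha = ln 2
  expect_equal(time_to_ring(5, 4, 0.03), 0)   # clamped
  expect_error(time_to_ring(-1, 4, 0.03))
  expect_error(time_to_ring(2, 4, 0))
})

test_that("a constant ratio pins the trajectory to the fixed point", {
  gp <- growth_params()
  flat <- induction_params(minE_initial = 1, minE_final = 1, t_c = 0, t_s = 1)
  tr <- run_generations(6, gp, flat)
  L0_star <- 0.5 * l_stable(gp, 1) * exp(gp$alpha * gp$tau)
  expect_equal(tr$L0_um, rep(L0_star, 7), tolerance = 1e-12)
  expect_equal(tr$cycle_min, rep(log(2) / gp$alpha, 7), tolerance = 1e-12)
  # fixed-point identity alpha * (Tz + tau) = log 2
  expect_equal(gp$alpha * (tr$Tz_min[1] + gp$tau), log(2), tolerance = 1e-12)
})

test_that("any starting size below L_stable converges in one generation", {
  gp <- growth_params()
  flat <- induction_params(minE_initial = 1, minE_final = 1, t_c = 0, t_s = 1)
  L0_star <- 0.5 * l_stable(gp, 1) * exp(gp$alpha * gp$tau)
  for (L0 in c(1, 1.7, 2.4, 2.9)) {
    tr <- run_generations(3, gp, flat, L_0_init = L0)
    expect_equal(tr$L0_um[2], L0_star, tolerance = 1e-12)
  }
})

test_that("the division recursion identity holds exactly", {
  tr <- run_generations(10)
  gp <- growth_params()
  lhs <- tr$L0_um[-1]
  rhs <- 0.5 * tr$L0_um[-11] * exp(gp$alpha * tr$cycle_min[-11])
  expect_equal(lhs, rhs, tolerance = 1e-12)
  # and where Tz > 0 also the L_stable form
  pos <- which(tr$Tz_min[-11] > 0)
  expect_equal(lhs[pos],
               0.5 * tr$L_stable_um[pos] * exp(gp$alpha * gp$tau),
               tolerance = 1e-12)
})

test_that("sigmoid induction yields transient Tz and monotone birth size", {
  tr <- run_generations(20)
  base_Tz <- 0.25 * log(2) / growth_params()$alpha # quarter-cycle baseline
  expect_gt(max(tr$Tz_min), tr$Tz_min[1])          # transient rise
  expect_lt(abs(tr$Tz_min[21] - base_Tz) / base_Tz, 0.01) # returns to baseline
  expect_true(all(diff(tr$L0_um) >= -1e-12))       # monotone birth size
  expect_gt(tr$L0_um[21] / tr$L0_um[1], 1.1)       # higher plateau
})

test_that("generation-unit induction times are converted self-consistently", {
  gp <- growth_params()
  tr_min <- run_generations(12, gp,
                            induction_params(t_c = 50, t_s = 25, unit = "min"))
  tr_gen <- run_generations(12, gp,
                            induction_params(t_c = 2, t_s = 1,
                                             unit = "generation"))
  # two generations at ~25 min/generation: same order of magnitude dynamics
  expect_equal(which.max(tr_gen$Tz_min), which.max(tr_min$Tz_min),
               tolerance = 1)
})

test_that("sister deltas follow the closed form", {
  gp <- growth_params(lopt_a = 4, lopt_b = 0) # L_stable = 4 regardless of ratio
  s <- sister_delta(0.5, 5, gp)
  expect_equal(s$delta_A, s$delta_B)
  s2 <- sister_delta(0.6, 5, gp)
  expect_equal(s2$delta_A - s2$delta_B, -(0.6 - 0.4) * 5) # = -1 um
  # linearity: slope over a pair set with common mother length is -L_mother
  fs <- seq(0.35, 0.65, 0.05)
  d <- sapply(fs, function(f) {
    s <- sister_delta(f, 5, gp)
    s$delta_A - s$delta_B
  })
  fit <- lm(d ~ I(fs - (1 - fs)))
  expect_equal(unname(coef(fit)[2]), -5, tolerance = 1e-12)
  # oracle equivalence: each sister's single-cycle addition from the
  # generational recursion
  for (f in c(0.4, 0.55)) {
    s <- sister_delta(f, 5, gp)
    for (side in c(1, 2)) {
      fi <- if (side == 1) f else 1 - f
      tr <- run_generations(1, gp,
                            induction_params(minE_initial = 1, minE_final = 1,
                                             t_c = 0, t_s = 1),
                            L_0_init = fi * 5)
      added <- tr$L0_um[1] * exp(gp$alpha * tr$cycle_min[1]) - tr$L0_um[1]
      expect_equal(if (side == 1) s$delta_A else s$delta_B, added,
                   tolerance = 1e-12)
    }
  }
})
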
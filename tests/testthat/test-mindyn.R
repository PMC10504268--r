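test_that("parameter and grid constructors validate their inputs", {
  expect_error(min_params(dens_D = 0), "dens_D")
  expect_error(min_params(dens_E = -1), "dens_E")
  expect_error(min_params(sigma_de = -0.1), "rates")
  p <- with_ratio(min_params(), 2)
  expect_equal(p$dens_E, 700)
  expect_equal(p$dens_D, 1000)

  g <- min_grid(4, dx = 0.05)
  expect_equal(g$n_x, 80L)
  expect_equal(g$dx * g$n_x, g$L)
  expect_equal(g$x[1], g$dx / 2)
  expect_equal(g$x[g$n_x], g$L - g$dx / 2)
})

test_that("initial fields are symmetric, seeded and exactly conserved", {
  p <- min_params()
  g <- min_grid(4, dx = 0.1)
  f0 <- initialize_fields(p, g, perturbation = 0)
  expect_equal(unclass(f0), unclass(f0[rev(seq_len(g$n_x)), ]),
               ignore_attr = TRUE) # mirror symmetric
  expect_equal(sum(f0[, c("c_DD", "c_DT", "m_d", "m_de")]) * g$dx,
               p$dens_D * g$L)

  f1 <- initialize_fields(p, g, seed = 42, perturbation = 0.01)
  f2 <- initialize_fields(p, g, seed = 42, perturbation = 0.01)
  expect_identical(f1, f2)
  f3 <- initialize_fields(p, g, seed = 43, perturbation = 0.01)
  expect_false(identical(f1, f3))
  # renormalized construction: MinD total exact to machine precision
  expect_equal(sum(f1[, c("c_DD", "c_DT", "m_d", "m_de")]) * g$dx,
               p$dens_D * g$L, tolerance = 1e-14)
})

test_that("the right-hand side vanishes without active reaction channels", {
  p <- min_params(k_exchange = 0, sigma_D = 0)
  g <- min_grid(2, dx = 0.1)
  f <- initialize_fields(p, g, perturbation = 0) # uniform cytosol, bare membrane
  d <- min_rhs(f, p, g)
  expect_equal(max(abs(d)), 0)
})

test_that("the right-hand side conserves MinD and MinE exactly", {
  p <- min_params()
  g <- min_grid(3, dx = 0.1)
  set.seed(7)
  f <- matrix(runif(g$n_x * 5, 0, 500), g$n_x, 5,
              dimnames = list(NULL, c("c_DD", "c_DT", "c_E", "m_d", "m_de")))
  d <- min_rhs(f, p, g)
  scale <- max(abs(d))
  expect_lt(abs(sum(d[, c("c_DD", "c_DT", "m_d", "m_de")])) / scale, 1e-12)
  expect_lt(abs(sum(d[, c("c_E", "m_de")])) / scale, 1e-12)
})

test_that("single-interval derivatives equal hand-written mass-action terms", {
  p <- min_params()
  g <- min_grid(1, n_x = 1)
  set.seed(11)
  y <- runif(5, 10, 800)
  f <- matrix(y, 1, 5,
              dimnames = list(NULL, c("c_DD", "c_DT", "c_E", "m_d", "m_de")))
  d <- min_rhs(f, p, g)
  # hand evaluation of the five mass-action expressions
  att <- (p$sigma_D + p$sigma_dD * (y[4] + y[5])) * y[2]
  erec <- p$sigma_E * y[4] * y[3]
  det <- p$sigma_de * y[5]
  exch <- p$k_exchange * y[1]
  expect_equal(as.numeric(d),
               c(-exch + det, exch - att, -erec + det,
                 att - erec, erec - det))
})

test_that("a reaction-free configuration stays static with empty mid-cell", {
  p <- min_params(k_exchange = 0, sigma_D = 0)
  g <- min_grid(3, dx = 0.1)
  out <- simulate_min(p, g, t_end = 30, perturbation = 0)
  expect_equal(max(abs(out$membrane_occupancy)), 0)
  expect_equal(max(abs(out$midcell_signal)), 0)
})

test_that("mirror-symmetric initial data stay mirror-symmetric", {
  p <- min_params()
  g <- min_grid(4, dx = 0.1)
  out <- simulate_min(p, g, t_end = 60, perturbation = 0)
  occ <- out$membrane_occupancy
  mirrored <- occ[, rev(seq_len(ncol(occ)))]
  denom <- max(abs(occ), 1e-300)
  expect_lt(max(abs(occ - mirrored)) / denom, 1e-8)
})

test_that("mass conservation and positivity hold over a long run", {
  out <- quick_sim()
  expect_lt(out$conservation_drift, 1e-6)
  expect_gte(min(out$membrane_occupancy), -1e-12 * out$params$dens_D)
})

test_that("one-cell integration matches an independent adaptive ODE solve", {
  skip_if_not_installed("deSolve")
  p <- min_params()
  g <- min_grid(1, n_x = 1)
  init <- matrix(c(200, 800, 350, 0, 0), 1, 5,
                 dimnames = list(NULL,
                                 c("c_DD", "c_DT", "c_E", "m_d", "m_de")))
  out <- simulate_min(p, g, t_end = 30, sample_dt = 1, init = init)
  ref <- deSolve::lsoda(y = as.numeric(init), times = 0:30,
                        func = oracle_ode_rhs, parms = p,
                        rtol = 1e-11, atol = 1e-9)
  # final state of all five species, and the sampled membrane sum over time
  for (k in 1:5)
    expect_equal(out$final_state[1, k], unname(ref[31, k + 1]),
                 tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(as.numeric(out$membrane_occupancy[, 1]),
               as.numeric(ref[, 5] + ref[, 6]), tolerance = 1e-6)
})

test_that("detect_period finds dominant periods and rejects flat signals", {
  t <- seq(0, 600)
  expect_equal(detect_period(5 + sin(2 * pi * t / 40), 1, burn_in = 0), 40,
               tolerance = 1 / 40) # within one sample
  expect_true(is.na(detect_period(rep(3, 601), 1)))
  mixed <- 10 + sin(2 * pi * t / 40) + 0.1 * sin(2 * pi * t / 13)
  expect_equal(detect_period(mixed, 1, burn_in = 0), 40, tolerance = 1 / 40)
  expect_error(detect_period(1:10, 1, burn_in = 20), "burn_in")
})

test_that("wild-type cells oscillate pole-to-pole on the ~40 s timescale", {
  out <- quick_sim()
  per <- detect_period(out$pole_signal, out$sample_dt, burn_in = 200)
  expect_false(is.na(per))
  expect_gt(per, 20)
  expect_lt(per, 80)
  s <- out$pole_signal[out$sample_times >= 200]
  expect_gte((max(s) - min(s)) / mean(s), 0.05)
})

test_that("the detected period is grid-converged", {
  per_coarse <- detect_period(quick_sim()$pole_signal, 1, burn_in = 200)
  fine <- simulate_min(min_params(), min_grid(4, dx = 0.05), t_end = 600,
                       seed = 0)
  per_fine <- detect_period(fine$pole_signal, 1, burn_in = 200)
  expect_lt(abs(per_fine - per_coarse) / per_fine, 0.02)
})

test_that("time averages behave for static and symmetric dynamics", {
  p <- min_params(k_exchange = 0, sigma_D = 0, sigma_dD = 0, sigma_E = 0)
  g <- min_grid(3, dx = 0.1)
  init <- initialize_fields(p, g, perturbation = 0)
  init[, "m_d"] <- 100 * sin(pi * g$x / g$L) # static: no reactions, D_m = 0
  out <- simulate_min(p, g, t_end = 20, init = init)
  avg <- time_average_profile(out)
  expect_equal(avg, out$membrane_occupancy[1, ], tolerance = 1e-9,
               ignore_attr = TRUE)
  # symmetric dynamics give a mirror-symmetric average
  sym <- simulate_min(min_params(), min_grid(4, dx = 0.1), t_end = 60,
                      perturbation = 0)
  avg2 <- time_average_profile(sym)
  expect_equal(avg2, rev(avg2), tolerance = 1e-8)
})

test_that("the average MinCD profile at the optimal length dips at mid-cell", {
  out <- simulate_min(min_params(), min_grid(3.5, dx = 0.1), t_end = 400,
                      seed = 0)
  prof <- time_average_profile(out, burn_in = 200)
  n <- length(prof)
  central <- prof[ceiling(0.4 * n):floor(0.6 * n)]
  outer <- prof[c(1:ceiling(0.2 * n), floor(0.8 * n):n)]
  expect_lt(min(central), min(outer))          # minimum sits centrally
  expect_gt(max(outer), max(prof[ceiling(0.2 * n):floor(0.8 * n)])) # polar maxima
})
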
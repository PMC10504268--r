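#' Kinetic parameters of the 1-d Min reaction-diffusion model
#'
#' Constructs the parameter set of the reduced five-species MinD/MinE
#' membrane-oscillation model.  The model follows the established
#' Huang-type parameterization of the Min system, reduced to one spatial
#' dimension: cytosolic and membrane-bound species are both represented as
#' linear densities (molecules/um), and literature volume/surface rate
#' constants are converted to effective 1-d rates using the surface-to-volume
#' geometry of a cylindrical cell of radius r = 0.5 um
#' (`geometry_factor = 2/r` for the basal binding rate; `1/(pi r^2)` for the
#' bimolecular rates).  The defaults below are those effective 1-d values.
#'
#' @param D_D cytosolic MinD diffusion coefficient (um^2/s).
#' @param D_E cytosolic MinE diffusion coefficient (um^2/s).
#' @param D_m membrane-species diffusion coefficient (um^2/s); the default 0
#'   corresponds to immobile membrane-bound complexes.
#' @param sigma_D basal MinD membrane-binding rate, effective 1-d units (1/s);
#'   default `geometry_factor * 0.025 um/s`.
#' @param sigma_dD cooperative MinD recruitment rate
#'   (um/s per molecule/um); default `0.0015 um^3/s / (pi r^2)`.
#' @param sigma_E MinE recruitment rate onto membrane-bound MinD
#'   (um/s per molecule/um); default `0.093 um^3/s / (pi r^2)`.
#' @param sigma_de hydrolysis/detachment rate of the membrane MinDE complex
#'   (1/s).
#' @param k_exchange cytosolic MinD ADP->ATP nucleotide-exchange rate (1/s).
#' @param dens_D total MinD linear density (molecules/um).
#' @param dens_E total MinE linear density (molecules/um).  The wild-type
#'   MinE/MinD ratio is `dens_E/dens_D` (0.35 by default); *minE*
#'   overexpression is modelled by raising `dens_E` only.
#' @param geometry_factor surface-to-volume conversion used in the 1-d
#'   reduction (1/um); recorded for provenance, default `2/0.5`.
#'
#' @return An object of class `min_params` (a named list).
#' @examples
#' p <- min_params()
#' p$dens_E / p$dens_D # wild-type MinE/MinD ratio
#' @export
min_params <- function(D_D = 2.5, D_E = 2.5, D_m = 0,
                       sigma_D = 4 * 0.025,
                       sigma_dD = 0.0015 / (pi * 0.25),
                       sigma_E = 0.093 / (pi * 0.25),
                       sigma_de = 0.7, k_exchange = 1,
                       dens_D = 1000, dens_E = 350,
                       geometry_factor = 2 / 0.5) {
  p <- list(D_D = D_D, D_E = D_E, D_m = D_m, sigma_D = sigma_D,
            sigma_dD = sigma_dD, sigma_E = sigma_E, sigma_de = sigma_de,
            k_exchange = k_exchange, dens_D = dens_D, dens_E = dens_E,
            geometry_factor = geometry_factor)
  rates <- unlist(p[c("D_D", "D_E", "D_m", "sigma_D", "sigma_dD", "sigma_E",
                      "sigma_de", "k_exchange")])
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates and diffusivities must be finite and >= 0")
  if (!is.finite(p$dens_D) || p$dens_D <= 0)
    stop("dens_D must be > 0")
  if (!is.finite(p$dens_E) || p$dens_E <= 0)
    stop("dens_E must be > 0 (the MinE/MinD ratio must be finite and positive)")
  class(p) <- "min_params"
  p
}

#' Rescale the MinE/MinD ratio of a parameter set
#'
#' Multiplies `dens_E` by `multiplier`, leaving `dens_D` untouched.  This
#' mirrors *minE* overexpression from an inducible promoter against native
#' *minD* expression.
#'
#' @param params a [min_params()] object.
#' @param multiplier relative ratio `R/R_0 >= 0` (1 = wild type).
#' @return A new `min_params` object.
#' @export
with_ratio <- function(params, multiplier) {
  stopifnot(inherits(params, "min_params"), multiplier > 0)
  params$dens_E <- params$dens_E * multiplier
  params
}

#' Cell-centred 1-d grid
#'
#' Discretizes a cell of length `L` into `n_x` equal intervals with
#' cell-centred coordinates and reflecting (no-flux) boundaries at 0 and `L`.
#' Exactly one of `n_x` or `dx` must be given; when `dx` is given, `n_x` is
#' `round(L/dx)` so the grid tiles the domain exactly.
#'
#' @param L cell length (um).
#' @param n_x number of grid intervals.
#' @param dx target spacing (um); default 0.05.
#' @return An object of class `min_grid` with fields `L`, `n_x`, `dx`, `x`.
#' @examples
#' g <- min_grid(4)
#' g$n_x # 80 intervals of 0.05 um
#' @export
min_grid <- function(L, n_x = NULL, dx = 0.05) {
  stopifnot(is.finite(L), L > 0)
  if (is.null(n_x)) n_x <- max(3L, as.integer(round(L / dx)))
  n_x <- as.integer(n_x)
  stopifnot(n_x >= 1)
  dx <- L / n_x
  g <- list(L = L, n_x = n_x, dx = dx, x = (seq_len(n_x) - 0.5) * dx)
  class(g) <- "min_grid"
  g
}

#' Initial fields for a Min simulation
#'
#' Cytosolic MinD (all in the ATP form) and MinE start spatially uniform at
#' the configured totals; membrane species start empty.  A seeded random
#' multiplicative perturbation of relative magnitude `perturbation` is
#' applied to the cytosolic MinD:ATP profile and then renormalized so the
#' MinD total is conserved exactly.  The perturbation breaks the mirror
#' symmetry of the deterministic equations, without which pole-to-pole
#' oscillations cannot develop.
#'
#' @param params a [min_params()] object.
#' @param grid a [min_grid()] object.
#' @param seed integer seed for the perturbation (default 0).
#' @param perturbation relative magnitude in `[0, 1)`; default 0.01.
#' @return A matrix with `n_x` rows and columns
#'   `c_DD`, `c_DT`, `c_E`, `m_d`, `m_de` (class `min_fields`).
#' @export
initialize_fields <- function(params, grid, seed = 0, perturbation = 0.01) {
  stopifnot(inherits(params, "min_params"), inherits(grid, "min_grid"),
            perturbation >= 0, perturbation < 1)
  n <- grid$n_x
  f <- matrix(0, n, 5,
              dimnames = list(NULL, c("c_DD", "c_DT", "c_E", "m_d", "m_de")))
  f[, "c_DT"] <- params$dens_D
  f[, "c_E"] <- params$dens_E
  if (perturbation > 0) {
    # local RNG scope: do not disturb the caller's RNG stream
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    u <- stats::runif(n, -1, 1)
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    prof <- f[, "c_DT"] * (1 + perturbation * u)
    # renormalize: MinD total exact by construction
    f[, "c_DT"] <- prof * (params$dens_D * n / sum(prof))
  }
  class(f) <- c("min_fields", class(f))
  f
}

#' Time derivative of the Min fields
#'
#' Evaluates the five coupled reaction-diffusion equations of the reduced
#' Min model (second-order central differences, no-flux boundaries):
#' \deqn{\partial_t c_{DD} = D_D \nabla^2 c_{DD} - k_{exch} c_{DD} + \sigma_{de} m_{de}}
#' \deqn{\partial_t c_{DT} = D_D \nabla^2 c_{DT} + k_{exch} c_{DD} - [\sigma_D + \sigma_{dD}(m_d+m_{de})] c_{DT}}
#' \deqn{\partial_t c_E = D_E \nabla^2 c_E - \sigma_E m_d c_E + \sigma_{de} m_{de}}
#' \deqn{\partial_t m_d = D_m \nabla^2 m_d + [\sigma_D + \sigma_{dD}(m_d+m_{de})] c_{DT} - \sigma_E m_d c_E}
#' \deqn{\partial_t m_{de} = D_m \nabla^2 m_{de} + \sigma_E m_d c_E - \sigma_{de} m_{de}}
#' The reaction terms move mass between species, so the spatial integrals of
#' total MinD and total MinE have exactly zero time derivative.
#'
#' @param fields an `n_x` x 5 fields matrix (see [initialize_fields()]).
#' @param params a [min_params()] object.
#' @param grid a [min_grid()] object.
#' @return A matrix of the same shape containing time derivatives.
#' @export
min_rhs <- function(fields, params, grid) {
  stopifnot(nrow(fields) == grid$n_x, ncol(fields) == 5)
  .min_rhs_cpp(unclass(fields), grid$dx, unlist(params[c(
    "D_D", "D_E", "D_m", "sigma_D", "sigma_dD", "sigma_E",
    "sigma_de", "k_exchange")]))
}

#' Simulate the 1-d Min oscillation
#'
#' Integrates the five-species Min model with a fixed-step RK4 scheme
#' (method of lines; step `0.4 dx^2 / max(D)` capped by the fastest reaction
#' rate) and samples the membrane occupancy `m_d + m_de` on a uniform
#' schedule.  MinD and MinE totals are monitored; a relative drift above
#' `conservation_tol` aborts the run, as do non-finite values or negative
#' densities below `-1e-12 * dens_D` (smaller undershoots are clipped to zero
#' and counted in `n_clipped`).
#'
#' @param params a [min_params()] object.
#' @param grid a [min_grid()] object.
#' @param t_end simulated time (s).
#' @param sample_dt sampling interval (s), default 1.
#' @param seed seed for the initial perturbation.
#' @param perturbation initial symmetry-breaking magnitude, default 0.01.
#' @param init optional fields matrix overriding [initialize_fields()].
#' @param pole_window,mid_window widths (um) of the pole and mid-cell
#'   integration windows for the extracted signals, default 0.5.
#' @param conservation_tol maximum tolerated relative drift of the MinD/MinE
#'   totals, default 1e-6.
#' @return An object of class `min_sim` with elements `sample_times` (s),
#'   `membrane_occupancy` (time x space matrix, molecules/um), `x`, `grid`,
#'   `params`, `pole_signal` and `midcell_signal` (molecules in the windows),
#'   `final_state`, `conservation_drift`, `n_clipped`.
#' @examples
#' \donttest{
#' out <- simulate_min(min_params(), min_grid(4, dx = 0.1), t_end = 300)
#' detect_period(out$pole_signal, out$sample_dt, burn_in = 150)
#' }
#' @export
simulate_min <- function(params, grid, t_end, sample_dt = 1, seed = 0,
                         perturbation = 0.01, init = NULL,
                         pole_window = 0.5, mid_window = 0.5,
                         conservation_tol = 1e-6) {
  stopifnot(inherits(params, "min_params"), inherits(grid, "min_grid"),
            t_end > 0, sample_dt > 0)
  if (is.null(init))
    init <- initialize_fields(params, grid, seed = seed,
                              perturbation = perturbation)
  stopifnot(nrow(init) == grid$n_x)
  # diffusion stability bound; reaction bound from the fastest linear rate
  Dmax <- max(params$D_D, params$D_E, params$D_m)
  dt_diff <- if (Dmax > 0) 0.4 * grid$dx^2 / Dmax else Inf
  # local densities can transiently exceed the spatial mean severalfold, so
  # the bimolecular rates carry a safety factor in the step bound
  rate_max <- max(params$sigma_de, params$k_exchange,
                  4 * params$sigma_E * max(params$dens_D, params$dens_E),
                  4 * params$sigma_dD * max(params$dens_D, params$dens_E))
  dt_react <- if (rate_max > 0) 0.5 / rate_max else Inf
  dt_max <- min(dt_diff, dt_react, sample_dt)
  raw <- .min_integrate_cpp(unclass(init), grid$dx, unlist(params[c(
    "D_D", "D_E", "D_m", "sigma_D", "sigma_dD", "sigma_E",
    "sigma_de", "k_exchange")]), t_end, sample_dt, dt_max,
    1e-12 * params$dens_D)
  if (raw$conservation_drift > conservation_tol)
    stop(sprintf(
      "integration failure: conservation drift %.3g exceeds %.3g (step size %g)",
      raw$conservation_drift, conservation_tol, raw$dt))
  occ <- raw$occupancy
  out <- list(
    sample_times = raw$times,
    membrane_occupancy = occ,
    x = grid$x,
    sample_dt = sample_dt,
    grid = grid,
    params = params,
    pole_signal = .window_sum(occ, grid, 0, pole_window / 2),
    midcell_signal = .window_sum(occ, grid, grid$L / 2, mid_window / 2),
    final_state = raw$final_state,
    conservation_drift = raw$conservation_drift,
    n_clipped = raw$n_clipped,
    dt = raw$dt
  )
  class(out) <- "min_sim"
  out
}

# Overlap-weighted integral of the occupancy matrix over [center-h, center+h],
# clipped to the domain; returns molecules per sample.
.window_sum <- function(occ, grid, center, h) {
  lo <- max(0, center - h)
  hi <- min(grid$L, center + h)
  edges_lo <- (seq_len(grid$n_x) - 1) * grid$dx
  edges_hi <- seq_len(grid$n_x) * grid$dx
  w <- pmax(0, pmin(edges_hi, hi) - pmax(edges_lo, lo))
  as.numeric(occ %*% w)
}

#' Detect the dominant oscillation period of a signal
#'
#' Computes the autocorrelation of the post-burn-in signal and returns the
#' lag of its first local maximum above `floor` (refined by parabolic
#' interpolation of the autocorrelation peak).  A signal whose relative
#' amplitude `(max - min)/mean` after burn-in is below `min_amplitude` is
#' deemed non-oscillatory and yields `NA`.
#'
#' @param signal numeric vector sampled at `sample_dt`.
#' @param sample_dt sampling interval (s).
#' @param burn_in initial time span to discard (s).
#' @param min_amplitude relative amplitude floor, default 0.05.
#' @param acf_floor minimum autocorrelation for an accepted peak, default 0.2.
#' @return Period in seconds, or `NA_real_` when no oscillation is detected.
#' @examples
#' t <- seq(0, 600)
#' detect_period(5 + sin(2 * pi * t / 40), 1, burn_in = 0) # ~40
#' @export
detect_period <- function(signal, sample_dt, burn_in = 0,
                          min_amplitude = 0.05, acf_floor = 0.2) {
  stopifnot(sample_dt > 0)
  n_skip <- floor(burn_in / sample_dt)
  if (n_skip >= length(signal))
    stop("burn_in must be shorter than the signal duration")
  s <- signal[(n_skip + 1):length(signal)]
  m <- mean(s)
  if (!is.finite(m) || m == 0) return(NA_real_)
  if ((max(s) - min(s)) / m < min_amplitude) return(NA_real_)
  lag_max <- length(s) - 2L
  ac <- stats::acf(s, lag.max = lag_max, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  # first interior local maximum of the acf above the floor
  for (k in seq(2, length(ac) - 1)) {
    if (ac[k] >= ac[k - 1] && ac[k] > ac[k + 1] && ac[k] > acf_floor) {
      # parabolic refinement around the peak (lags are 0-based)
      denom <- ac[k - 1] - 2 * ac[k] + ac[k + 1]
      shift <- if (denom < 0) 0.5 * (ac[k - 1] - ac[k + 1]) / denom else 0
      return(((k - 1) + shift) * sample_dt)
    }
  }
  NA_real_
}

#' Time-averaged membrane occupancy profile
#'
#' Arithmetic mean of the sampled membrane occupancy over all samples after
#' `burn_in`, i.e. the average MinCD profile a time-lapse would accumulate.
#'
#' @param sim a `min_sim` object from [simulate_min()].
#' @param burn_in seconds to discard, default 0.
#' @return Numeric vector over the grid (molecules/um).
#' @export
time_average_profile <- function(sim, burn_in = 0) {
  keep <- sim$sample_times >= burn_in
  if (!any(keep)) stop("burn_in must be shorter than the simulated duration")
  colMeans(sim$membrane_occupancy[keep, , drop = FALSE])
}
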
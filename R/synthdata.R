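#' Configuration for the synthetic mother-machine generator
#'
#' Defines the statistical structure of simulated single-cell lineages:
#' exponential growth at rate `alpha`, ring stabilization when the cell
#' reaches the ratio-dependent permissive length, a fixed post-ring interval
#' `tau`, near-symmetric division, and a two-slope FtsZ ring-intensity
#' accumulation whose rate changes at 65% of the cycle's plateau.  Rates and
#' lengths carry multiplicative lognormal noise (positive quantities); the
#' intensity carries additive Gaussian noise on top of a constant background.
#'
#' @param n_lineages number of independent mother-machine lineages (default
#'   39, the number of analysed traces per condition).
#' @param n_generations generations per lineage (default 16).
#' @param alpha_mean,alpha_cv growth-rate mean (1/min) and coefficient of
#'   variation; defaults `log(2)/25` and 0.07.
#' @param tau_mean,tau_cv post-ring interval mean (min) and CV; defaults
#'   18.75 and 0.07.
#' @param division_fraction_sd SD of the daughter fraction around 0.5
#'   (truncated to (0.05, 0.95)); default 0.035.
#' @param lstable_cv per-cycle CV of the permissive length; default 0.05.
#' @param induction_start_gen generation (1-based) at whose birth the
#'   induction clock starts; default 8.  Use `Inf` for no induction.
#' @param induction an [induction_params()] object (minutes).
#' @param growth a [growth_params()] object supplying `alpha`/`tau` *means*
#'   are taken from `alpha_mean`/`tau_mean`; only its `lopt_a`, `lopt_b` map
#'   is used here.
#' @param sampling_interval imaging cadence (min), default 1.
#' @param ring_plateau cycle-maximal ring intensity (a.u.), default 1000.
#' @param ring_rate_pre,ring_rate_post accumulation rates (a.u./min) before
#'   and after the 65% point; `NULL` (default) derives them so the 65%
#'   crossing falls exactly at the configured ring-stabilization time and the
#'   plateau is reached at division.
#' @param intensity_noise_sd additive Gaussian intensity noise (a.u.),
#'   default 20.
#' @param background_mean constant background added to intensities (a.u.),
#'   default 100.
#' @param seed RNG seed.
#' @return An object of class `lineage_config`.
#' @export
lineage_config <- function(n_lineages = 39, n_generations = 16,
                           alpha_mean = log(2) / 25, alpha_cv = 0.07,
                           tau_mean = 18.75, tau_cv = 0.07,
                           division_fraction_sd = 0.035, lstable_cv = 0.05,
                           induction_start_gen = 8,
                           induction = induction_params(),
                           growth = growth_params(),
                           sampling_interval = 1,
                           ring_plateau = 1000, ring_rate_pre = NULL,
                           ring_rate_post = NULL, intensity_noise_sd = 20,
                           background_mean = 100, seed = 1) {
  stopifnot(n_lineages >= 1, n_generations >= 1, alpha_cv >= 0, tau_cv >= 0,
            lstable_cv >= 0, division_fraction_sd >= 0,
            sampling_interval > 0, intensity_noise_sd >= 0)
  structure(as.list(environment()), class = "lineage_config")
}

# lognormal draw with mean m and coefficient of variation cv (cv = 0 -> m)
.rlnorm_mean_cv <- function(n, m, cv) {
  if (cv == 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

# truncated normal via rejection (narrow tails; loop is cheap)
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= lo | out >= hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lo | out[bad] >= hi]
  }
  out
}

# ring intensity at times t (minutes from birth): two-slope accumulation with
# the rate change at the 65% point, reached at time Tz; plateau at division
.ring_intensity <- function(t, Tz, cycle, plateau, rate_pre, rate_post) {
  knee <- 0.65 * plateau
  if (is.null(rate_pre))
    rate_pre <- if (Tz > 0) knee / Tz else Inf
  if (is.null(rate_post))
    rate_post <- if (cycle > Tz) (plateau - knee) / (cycle - Tz) else 0
  ifelse(t <= Tz,
         if (is.finite(rate_pre)) rate_pre * t else knee,
         pmin(knee + rate_post * (t - Tz), plateau))
}

#' Generate synthetic mother-machine lineages
#'
#' Simulates `n_lineages` independent old-pole lineages for
#' `n_generations` cycles each.  Per cycle the growth rate, post-ring
#' interval and permissive length are drawn around their configured means,
#' the cell grows exponentially from its birth length, the ring stabilizes at
#' the permissive length (time from the growth recursion, clamped at 0 for
#' cells born beyond it), and division occurs a time `tau` later at fraction
#' `f ~ N(0.5, division_fraction_sd)` truncated.  The ring-intensity series
#' embeds the configured stabilization time as its 65%-of-plateau crossing.
#' With all CVs and noise set to zero the per-generation records reproduce
#' [run_generations()] exactly.
#'
#' @param config a [lineage_config()].
#' @return List of two data frames: `cycles` (one row per cell cycle:
#'   lineage_id, generation, generation_rel, birth_time_min, S0_um,
#'   Tz_true_min, Sz_true_um, division_time_min, SD_um, daughter_fraction,
#'   clamped) and `intensity` (lineage_id, generation, time_min, length_um,
#'   ring_intensity).
#' @export
generate_lineage <- function(config = lineage_config()) {
  stopifnot(inherits(config, "lineage_config"))
  set.seed(as.integer(config$seed))
  cyc_rows <- vector("list", config$n_lineages * config$n_generations)
  int_rows <- vector("list", length(cyc_rows))
  n_clamped <- 0L
  k <- 0L
  for (lin in seq_len(config$n_lineages)) {
    growth0 <- config$growth
    # uninduced fixed point as the ancestral birth length
    S0 <- 0.5 * l_stable(growth0, 1) * exp(config$alpha_mean * config$tau_mean)
    t_birth <- 0
    t_induction <- NA_real_   # wall time at which induction starts
    for (g in seq_len(config$n_generations)) {
      if (is.finite(config$induction_start_gen) &&
          g == config$induction_start_gen)
        t_induction <- t_birth
      alpha <- .rlnorm_mean_cv(1, config$alpha_mean, config$alpha_cv)
      tau <- .rlnorm_mean_cv(1, config$tau_mean, config$tau_cv)
      t_ind <- if (is.na(t_induction)) -Inf else t_birth - t_induction
      r <- if (is.finite(t_ind)) ratio_trajectory(config$induction, t_ind)
           else 1
      Lst <- l_stable(growth0, r) *
        .rlnorm_mean_cv(1, 1, config$lstable_cv)
      clamped <- S0 >= Lst
      Tz <- time_to_ring(S0, Lst, alpha)
      cycle <- Tz + tau
      Sz <- S0 * exp(alpha * Tz)
      SD <- S0 * exp(alpha * cycle)
      f <- .rtruncnorm(1, 0.5, config$division_fraction_sd, 0.05, 0.95)
      times <- seq(0, cycle, by = config$sampling_interval)
      inten <- .ring_intensity(times, Tz, cycle, config$ring_plateau,
                               config$ring_rate_pre, config$ring_rate_post) +
        config$background_mean +
        stats::rnorm(length(times), 0, config$intensity_noise_sd)
      k <- k + 1L
      cyc_rows[[k]] <- data.frame(
        lineage_id = lin, generation = g,
        generation_rel = g - config$induction_start_gen,
        birth_time_min = t_birth, S0_um = S0, Tz_true_min = Tz,
        Sz_true_um = Sz, division_time_min = t_birth + cycle, SD_um = SD,
        daughter_fraction = f, clamped = clamped)
      int_rows[[k]] <- data.frame(
        lineage_id = lin, generation = g, time_min = times,
        length_um = S0 * exp(alpha * times), ring_intensity = inten)
      if (clamped) n_clamped <- n_clamped + 1L
      S0 <- f * SD
      t_birth <- t_birth + cycle
    }
  }
  cycles <- do.call(rbind, cyc_rows[seq_len(k)])
  if (n_clamped > 0.1 * nrow(cycles))
    warning(sprintf(
      "configuration implies S0 >= L_stable in %d of %d cycles (clamp path dominates)",
      n_clamped, nrow(cycles)))
  list(cycles = cycles, intensity = do.call(rbind, int_rows[seq_len(k)]))
}

#' Generate sister-cell pairs
#'
#' Each pair: a mother of length `L_mother` divides at fraction `f_A`; both
#' sisters are followed for one full cycle under the same relative ratio,
#' each with its own draws of growth rate, post-ring interval and permissive
#' length.  In noiseless mode the added lengths obey
#' `delta_A - delta_B = -(f_A - f_B) * L_mother` exactly.
#'
#' @param config a [lineage_config()] (noise and map parameters are reused).
#' @param n_pairs number of pairs, >= 1 (default 121, the number of measured
#'   pairs).
#' @param ratio_rel relative ratio common to both sisters, default 1.
#' @return Data frame: pair_id, L_mother, f_A, f_B, delta_A, delta_B.
#' @export
generate_sister_pairs <- function(config = lineage_config(), n_pairs = 121,
                                  ratio_rel = 1) {
  stopifnot(n_pairs >= 1)
  set.seed(as.integer(config$seed) + 1L)
  growth0 <- config$growth
  Lst0 <- l_stable(growth0, ratio_rel)
  Ldiv0 <- Lst0 * exp(config$alpha_mean * config$tau_mean)
  L_mother <- Ldiv0 * .rlnorm_mean_cv(n_pairs, 1, config$lstable_cv)
  f_A <- .rtruncnorm(n_pairs, 0.5, config$division_fraction_sd, 0.05, 0.95)
  one_cycle <- function(S0) {
    alpha <- .rlnorm_mean_cv(n_pairs, config$alpha_mean, config$alpha_cv)
    tau <- .rlnorm_mean_cv(n_pairs, config$tau_mean, config$tau_cv)
    Lst <- Lst0 * .rlnorm_mean_cv(n_pairs, 1, config$lstable_cv)
    Tz <- time_to_ring(S0, Lst, alpha)
    S0 * exp(alpha * (Tz + tau)) - S0
  }
  delta_A <- one_cycle(f_A * L_mother)
  delta_B <- one_cycle((1 - f_A) * L_mother)
  data.frame(pair_id = seq_len(n_pairs), L_mother = L_mother,
             f_A = f_A, f_B = 1 - f_A,
             delta_A = delta_A, delta_B = delta_B)
}

#' Generate replicated dose-response measurements
#'
#' Evaluates the four-parameter logistic at the given concentrations and adds
#' Gaussian measurement noise per replicate.
#'
#' @param p a [dose_response_params()].
#' @param concentrations arabinose concentrations (% w/v), >= 0.
#' @param noise_sd Gaussian noise SD (response units), default 0.
#' @param n_reps replicates per concentration, default 3.
#' @param seed RNG seed.
#' @return Data frame: C, R, replicate.
#' @export
generate_dose_response <- function(p = dose_response_params(),
                                   concentrations = seq(0, 1, length.out = 8),
                                   noise_sd = 0, n_reps = 3, seed = 1) {
  stopifnot(all(concentrations >= 0), n_reps >= 1, noise_sd >= 0)
  set.seed(as.integer(seed))
  d <- expand.grid(replicate = seq_len(n_reps), C = concentrations)
  d$R <- dose_response(d$C, p) + stats::rnorm(nrow(d), 0, noise_sd)
  d[, c("C", "R", "replicate")]
}
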
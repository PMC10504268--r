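#' Mid-cell occupancy scoring configuration
#'
#' @param window_w width of the scoring window (um), default 0.5 (comparable
#'   to the Z-ring width scale).
#' @param threshold_mode `"fraction_of_spatial_mean"` (default): the window
#'   counts as free when it holds less than `theta` times the molecules it
#'   would hold if all membrane-bound MinD were spread uniformly along the
#'   cell; `"absolute"`: `theta` is a molecule count.
#' @param theta threshold; default 0.5 (the deepest wild-type mid-cell dip of
#'   the model reaches ~0.44x the uniform expectation, so 0.5 separates the
#'   oscillation's "swept clear" phase from the occupied phase).
#' @param burn_in seconds of simulation discarded before scoring, default 200.
#' @return An object of class `occupancy_config`.
#' @export
occupancy_config <- function(window_w = 0.5,
                             threshold_mode = c("fraction_of_spatial_mean",
                                                "absolute"),
                             theta = 0.5, burn_in = 200) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(window_w > 0, theta >= 0, burn_in >= 0)
  structure(list(window_w = window_w, threshold_mode = threshold_mode,
                 theta = theta, burn_in = burn_in),
            class = "occupancy_config")
}

#' Windowed membrane occupancy time series
#'
#' Integrates the membrane occupancy over a window of width `window_w`
#' centred at `center`, per sample.  Partial grid intervals are weighted by
#' their overlap with the window.
#'
#' @param sim a `min_sim` object from [simulate_min()].
#' @param center window centre (um); defaults to mid-cell.
#' @param window_w window width (um), default 0.5.
#' @return Numeric vector, molecules in the window per sample.
#' @export
windowed_occupancy <- function(sim, center = sim$grid$L / 2, window_w = 0.5) {
  h <- window_w / 2
  if (center - h < -1e-9 || center + h > sim$grid$L + 1e-9)
    stop("window [", center - h, ", ", center + h,
         "] lies outside the domain [0, ", sim$grid$L, "]")
  .window_sum(sim$membrane_occupancy, sim$grid, center, h)
}

#' Fraction of time a window is free of MinCD
#'
#' The fraction of post-burn-in samples in which the windowed occupancy lies
#' strictly below the threshold `theta`.  This is the model's proxy for the
#' time during which mid-cell is unoccupied by the FtsZ-inhibiting MinCD
#' complex.
#'
#' @param series occupancy time series (molecules).
#' @param theta threshold; scalar, or a vector of per-sample thresholds (used
#'   by the fraction-of-spatial-mean mode).
#' @param burn_in seconds discarded, default 0.
#' @param sample_dt sampling interval of `series` (s), default 1.
#' @return Fraction in `[0, 1]`.
#' @examples
#' free_time_fraction(c(1, 3, 5, 7), theta = 4) # 0.5
#' @export
free_time_fraction <- function(series, theta, burn_in = 0, sample_dt = 1) {
  n_skip <- floor(burn_in / sample_dt)
  if (n_skip >= length(series))
    stop("no samples remain after burn-in")
  keep <- (n_skip + 1):length(series)
  s <- series[keep]
  th <- if (length(theta) == 1) theta else theta[keep]
  mean(s < th)
}

# Occupancy scoring shared by optimal_length/scan_ratios.  Returns the
# free-time fraction, the mean relative mid-cell occupancy (time average of
# window count / uniform expectation), the occupancy series and the
# time-averaged profile.
score_midcell <- function(sim, config = occupancy_config()) {
  occ_series <- windowed_occupancy(sim, window_w = config$window_w)
  L <- sim$grid$L
  if (config$threshold_mode == "fraction_of_spatial_mean") {
    total_mem <- as.numeric(sim$membrane_occupancy %*%
                              rep(sim$grid$dx, sim$grid$n_x))
    uniform_expect <- total_mem * config$window_w / L
    theta_series <- config$theta * uniform_expect
  } else {
    uniform_expect <- rep(NA_real_, length(occ_series))
    theta_series <- rep(config$theta, length(occ_series))
  }
  keep <- sim$sample_times >= config$burn_in
  rel <- if (config$threshold_mode == "fraction_of_spatial_mean")
    mean(occ_series[keep] / uniform_expect[keep]) else NA_real_
  list(
    free_time_fraction = free_time_fraction(occ_series, theta_series,
                                            burn_in = config$burn_in,
                                            sample_dt = sim$sample_dt),
    rel_mean_occupancy = rel,
    occupancy_series = occ_series,
    avg_profile = time_average_profile(sim, burn_in = config$burn_in)
  )
}

# Optimal-length selection from a scan table; exported for testability of the
# selection rules independent of the PDE.
#' Select the optimal length from a scan table
#'
#' @param lengths scanned lengths (um), strictly increasing.
#' @param fractions free-time fraction per length (used by
#'   `argmax_free_time` / `min_length_above`).
#' @param criterion `"argmax_free_time"` (ties broken toward the smallest
#'   length), `"min_length_above"` (smallest length with fraction >= `f_min`,
#'   `NA` if none), or `"argmin_avg_occupancy"` (argmin of `rel_occupancy`).
#' @param f_min threshold for `min_length_above`, default 0.5.
#' @param rel_occupancy mean relative mid-cell occupancy per length (used by
#'   `argmin_avg_occupancy`).
#' @param refine if `TRUE` also return a parabolic refinement of the optimum
#'   between grid lengths.
#' @return List with `L_opt` (grid value, `NA` when not found), `L_opt_refined`
#'   and `uncertainty` (the local grid spacing).
#' @export
select_optimal_length <- function(lengths, fractions,
                                  criterion = c("argmax_free_time",
                                                "min_length_above",
                                                "argmin_avg_occupancy"),
                                  f_min = 0.5, rel_occupancy = NULL,
                                  refine = TRUE) {
  criterion <- match.arg(criterion)
  stopifnot(length(lengths) >= 3, all(diff(lengths) > 0))
  spacing <- c(diff(lengths)[1], diff(lengths))
  not_found <- list(L_opt = NA_real_, L_opt_refined = NA_real_,
                    uncertainty = NA_real_)
  pick <- function(y, maximize) {
    ok <- is.finite(y)
    if (!any(ok)) return(not_found)
    yy <- ifelse(ok, y, if (maximize) -Inf else Inf)
    k <- if (maximize) which.max(yy) else which.min(yy)
    ref <- lengths[k]
    if (refine && k > 1 && k < length(lengths) &&
        all(is.finite(y[(k - 1):(k + 1)]))) {
      s <- if (maximize) 1 else -1
      denom <- s * (y[k - 1] - 2 * y[k] + y[k + 1])
      if (denom < 0)
        ref <- lengths[k] +
          0.5 * s * (y[k - 1] - y[k + 1]) / denom * spacing[k]
    }
    list(L_opt = lengths[k], L_opt_refined = ref, uncertainty = spacing[k])
  }
  switch(criterion,
    argmax_free_time = {
      if (all(!is.finite(fractions)) || max(fractions, na.rm = TRUE) <= 0) {
        warning("degenerate scan: all free-time fractions are zero")
        return(not_found)
      }
      pick(fractions, maximize = TRUE)
    },
    min_length_above = {
      ok <- which(is.finite(fractions) & fractions >= f_min)
      if (!length(ok)) {
        if (all(!is.finite(fractions)) || max(fractions, na.rm = TRUE) <= 0)
          warning("degenerate scan: all free-time fractions are zero")
        return(not_found)
      }
      k <- min(ok)
      list(L_opt = lengths[k], L_opt_refined = lengths[k],
           uncertainty = spacing[k])
    },
    argmin_avg_occupancy = {
      stopifnot(!is.null(rel_occupancy))
      # a flat profile (rel occupancy ~1 everywhere) means no pattern: not found
      if (all(!is.finite(rel_occupancy)) ||
          min(rel_occupancy, na.rm = TRUE) > 0.95) {
        warning("degenerate scan: no mid-cell depletion at any length")
        return(not_found)
      }
      pick(rel_occupancy, maximize = FALSE)
    })
}

#' Optimal (division-permissive) cell length for a parameter set
#'
#' Runs one Min simulation per candidate length, scores the mid-cell window,
#' and selects the optimal length by the chosen criterion.  The reported
#' uncertainty is the local length-grid spacing (the sampling resolution of
#' the scan).
#'
#' @param params a [min_params()] object.
#' @param lengths candidate cell lengths (um), >= 3, strictly increasing.
#' @param config an [occupancy_config()].
#' @param criterion,f_min see [select_optimal_length()].
#' @param t_end,sample_dt,dx,seed simulation settings per length (one fixed
#'   seed schedule, `seed + index - 1`, so scans are reproducible).
#' @param refine parabolically refine the optimum between grid lengths.
#' @return List with `L_opt`, `L_opt_refined`, `uncertainty`, `criterion` and
#'   a `scan` data frame (length_um, free_time_fraction, rel_mean_occupancy).
#' @export
optimal_length <- function(params, lengths, config = occupancy_config(),
                           criterion = "argmax_free_time", f_min = 0.5,
                           t_end = 800, sample_dt = 1, dx = 0.1, seed = 0,
                           refine = TRUE) {
  stopifnot(length(lengths) >= 3, all(diff(lengths) > 0))
  ft <- rel <- rep(NA_real_, length(lengths))
  for (j in seq_along(lengths)) {
    sim <- tryCatch(
      simulate_min(params, min_grid(lengths[j], dx = dx), t_end = t_end,
                   sample_dt = sample_dt, seed = seed + j - 1,
                   mid_window = config$window_w),
      error = function(e) NULL)
    if (is.null(sim)) next
    sc <- score_midcell(sim, config)
    ft[j] <- sc$free_time_fraction
    rel[j] <- sc$rel_mean_occupancy
  }
  sel <- select_optimal_length(lengths, ft, criterion = criterion,
                               f_min = f_min, rel_occupancy = rel,
                               refine = refine)
  c(sel, list(criterion = criterion,
              scan = data.frame(length_um = lengths,
                                free_time_fraction = ft,
                                rel_mean_occupancy = rel)))
}

#' Scan MinE/MinD ratios for the optimal length (dose-length map)
#'
#' For each ratio multiplier (relative MinE/MinD expression, raised through
#' the MinE density only, as in *minE* overexpression), finds the optimal
#' length and fits the linear first-order map
#' `L_opt = a + b * multiplier` by least squares.
#'
#' @param base wild-type / anchor [min_params()].
#' @param ratio_multipliers multipliers >= 1, strictly increasing.
#' @param lengths candidate lengths (um) shared by all multipliers.
#' @param config an [occupancy_config()].
#' @param criterion,f_min,t_end,sample_dt,dx,seed,refine passed to
#'   [optimal_length()].
#' @param use_refined fit the linear map on the refined optima (default) or
#'   the raw grid optima.
#' @return An object of class `ratio_scan`: list with `table` (one row per
#'   ratio x length), `optima` (ratio_multiplier, L_opt, L_opt_refined,
#'   uncertainty), `fit_intercept`, `fit_slope`, `fit_R2`, `resolution`.
#' @export
scan_ratios <- function(base, ratio_multipliers, lengths,
                        config = occupancy_config(),
                        criterion = "argmax_free_time", f_min = 0.5,
                        t_end = 800, sample_dt = 1, dx = 0.1, seed = 0,
                        refine = TRUE, use_refined = TRUE) {
  stopifnot(all(ratio_multipliers >= 1), all(diff(ratio_multipliers) > 0))
  optima <- data.frame(ratio_multiplier = ratio_multipliers,
                       L_opt = NA_real_, L_opt_refined = NA_real_,
                       uncertainty = NA_real_)
  tabs <- vector("list", length(ratio_multipliers))
  for (i in seq_along(ratio_multipliers)) {
    res <- optimal_length(with_ratio(base, ratio_multipliers[i]), lengths,
                          config = config, criterion = criterion,
                          f_min = f_min, t_end = t_end,
                          sample_dt = sample_dt, dx = dx,
                          seed = seed + 1000 * (i - 1), refine = refine)
    optima$L_opt[i] <- res$L_opt
    optima$L_opt_refined[i] <- res$L_opt_refined
    optima$uncertainty[i] <- res$uncertainty
    tabs[[i]] <- cbind(ratio_multiplier = ratio_multipliers[i], res$scan,
                       is_optimal = res$scan$length_um %in% res$L_opt)
  }
  y <- if (use_refined) optima$L_opt_refined else optima$L_opt
  ok <- is.finite(y)
  if (sum(ok) < 2)
    stop("cannot fit: fewer than 2 valid optimal lengths in the ratio scan")
  fit <- stats::lm(y[ok] ~ optima$ratio_multiplier[ok])
  b <- unname(stats::coef(fit)[2])
  r2 <- if (stats::var(y[ok]) == 0) NA_real_ else summary(fit)$r.squared
  structure(list(table = do.call(rbind, tabs), optima = optima,
                 fit_intercept = unname(stats::coef(fit)[1]),
                 fit_slope = b, fit_R2 = r2,
                 resolution = stats::median(optima$uncertainty, na.rm = TRUE),
                 criterion = criterion),
            class = "ratio_scan")
}
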
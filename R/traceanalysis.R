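#' Background-correct an intensity series
#'
#' Subtracts the mean background illumination; values may go negative and are
#' kept (clipping would bias the 65% threshold).
#'
#' @param intensity numeric vector.
#' @param background_mean scalar background level.
#' @return Corrected vector.
#' @export
background_correct <- function(intensity, background_mean) {
  intensity - background_mean
}

#' Ring-formation timing of one cell cycle
#'
#' Finds the first time the background-corrected ring intensity reaches
#' `threshold_fraction` of the cycle's maximum (linear interpolation between
#' samples), the cell length at that moment (exponential interpolation,
#' consistent with exponential growth), the remaining time to division and
#' the size ratio `S_D / S_z`.
#'
#' @param time_min sample times from birth (min), >= 3 samples.
#' @param intensity ring intensity at those times (a.u.).
#' @param length_um cell length at those times (um).
#' @param threshold_fraction threshold as a fraction of the cycle maximum,
#'   default 0.65 (the point at which the accumulation rate visibly changes
#'   in uninduced cells; other choices shift but do not reshape the
#'   dynamics).
#' @param background_mean background level subtracted first, default 0.
#' @return List with `t65` (min from birth), `S_z_est` (um),
#'   `post_interval` (min), `size_ratio`; or an error of class `no_ring`
#'   when the corrected maximum is not positive.
#' @examples
#' ring_formation_time(0:10, seq(0, 100, 10), 2 * exp(0.02 * 0:10))$t65 # 6.5
#' @export
ring_formation_time <- function(time_min, intensity, length_um,
                                threshold_fraction = 0.65,
                                background_mean = 0) {
  stopifnot(length(time_min) >= 3,
            length(intensity) == length(time_min),
            length(length_um) == length(time_min),
            threshold_fraction > 0, threshold_fraction <= 1)
  corrected <- background_correct(intensity, background_mean)
  M <- max(corrected)
  if (M <= 0)
    stop(structure(class = c("no_ring", "error", "condition"),
                   list(message = "ring intensity never exceeds background",
                        call = sys.call())))
  thr <- threshold_fraction * M
  k <- which(corrected >= thr)[1]
  t65 <- if (k == 1) time_min[1] else {
    # linear interpolation between the bracketing samples
    t0 <- time_min[k - 1]; t1 <- time_min[k]
    y0 <- corrected[k - 1]; y1 <- corrected[k]
    t0 + (thr - y0) / (y1 - y0) * (t1 - t0)
  }
  # exponential interpolation of length at t65
  S_z <- exp(stats::approx(time_min, log(length_um), xout = t65)$y)
  t_end <- time_min[length(time_min)]
  S_D <- length_um[length(length_um)]
  list(t65 = t65, S_z_est = S_z, post_interval = t_end - t65,
       size_ratio = S_D / S_z)
}

#' Ring timing for a table of cell cycles
#'
#' Applies [ring_formation_time()] to every cycle of a generator-format
#' dataset (`cycles` + long `intensity` tables as produced by
#' [generate_lineage()] or read from CSV).  Cycles whose ring never exceeds
#' background are excluded and counted.
#'
#' @param cycles cycle table (must carry lineage_id, generation,
#'   generation_rel, S0_um, SD_um, division_time_min, birth_time_min).
#' @param intensity long intensity table (lineage_id, generation, time_min,
#'   length_um, ring_intensity).
#' @param threshold_fraction,background_mean see [ring_formation_time()].
#' @return List with `timing` (cycles joined with t65, S_z_est,
#'   post_interval, size_ratio, cycle_min) and `n_excluded`.
#' @export
analyze_cycles <- function(cycles, intensity, threshold_fraction = 0.65,
                           background_mean = 0) {
  key <- interaction(intensity$lineage_id, intensity$generation, drop = TRUE)
  groups <- split(intensity, key)
  out <- cycles
  out$t65 <- out$S_z_est <- out$post_interval <- out$size_ratio <- NA_real_
  n_excluded <- 0L
  for (grp in groups) {
    i <- which(out$lineage_id == grp$lineage_id[1] &
                 out$generation == grp$generation[1])
    if (!length(i)) next
    rt <- tryCatch(
      ring_formation_time(grp$time_min, grp$ring_intensity, grp$length_um,
                          threshold_fraction, background_mean),
      error = function(e) NULL)
    if (is.null(rt)) { n_excluded <- n_excluded + 1L; next }
    out$t65[i] <- rt$t65
    out$S_z_est[i] <- rt$S_z_est
    # division time and length come from the cycle record, which is more
    # precise than the last imaging frame
    cyc_dur <- out$division_time_min[i] - out$birth_time_min[i]
    out$post_interval[i] <- cyc_dur - rt$t65
    out$size_ratio[i] <- out$SD_um[i] / rt$S_z_est
  }
  out$cycle_min <- out$division_time_min - out$birth_time_min
  if (n_excluded > 0)
    message(n_excluded, " cycle(s) excluded: no ring above background")
  list(timing = out, n_excluded = n_excluded)
}

#' Per-generation aggregates of the single-cell metrics
#'
#' Means, SDs and standard errors (SD/sqrt(n)) of the ring-timing metrics by
#' generation relative to induction (negative = pre-induction).
#'
#' @param timing the `timing` table from [analyze_cycles()] (needs
#'   `generation_rel` plus the metric columns).
#' @param metrics metric columns to aggregate.
#' @return Long data frame: generation_rel, metric, mean, sd, sem, n.
#'   Bins with a single record carry `sem = NA` (flagged, not zero).
#' @export
aggregate_by_generation <- function(timing,
                                    metrics = c("t65", "S_z_est",
                                                "post_interval", "size_ratio",
                                                "cycle_min", "S0_um")) {
  stopifnot(nrow(timing) >= 1, "generation_rel" %in% names(timing))
  metrics <- intersect(metrics, names(timing))
  rows <- list()
  for (m in metrics) {
    sp <- split(timing[[m]], timing$generation_rel)
    for (gname in names(sp)) {
      v <- sp[[gname]][is.finite(sp[[gname]])]
      n <- length(v)
      if (n == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        generation_rel = as.numeric(gname), metric = m,
        mean = mean(v), sd = if (n > 1) stats::sd(v) else NA_real_,
        sem = if (n > 1) stats::sd(v) / sqrt(n) else NA_real_, n = n)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$metric, out$generation_rel), ]
}

#' Sister-pair statistics
#'
#' Computes per pair the added-length difference `delta_A - delta_B` and the
#' birth-fraction difference `f_A - f_B`, bins them into equal-count bins
#' (mean +/- SD per bin) and fits the ordinary least-squares regression whose
#' slope the growth model predicts to be `-mean(L_mother)`.
#'
#' @param pairs data frame with f_A, f_B, delta_A, delta_B (and L_mother,
#'   optional, used only for the reported prediction).
#' @param n_bins number of equal-count bins, default 8.
#' @return List with `slope`, `slope_se`, `intercept`, `predicted_slope`
#'   (`-mean(L_mother)` or NA), `bins` (data frame x_mean, y_mean, y_sd, n),
#'   and `degenerate` (TRUE when the x variance vanishes, in which case the
#'   regression fields are NA).
#' @export
sister_pair_stats <- function(pairs, n_bins = 8) {
  stopifnot(nrow(pairs) >= 2)
  x <- pairs$f_A - pairs$f_B
  y <- pairs$delta_A - pairs$delta_B
  pred <- if ("L_mother" %in% names(pairs)) -mean(pairs$L_mother) else NA_real_
  if (stats::var(x) == 0)
    return(list(slope = NA_real_, slope_se = NA_real_, intercept = NA_real_,
                predicted_slope = pred, bins = NULL, degenerate = TRUE))
  fit <- stats::lm(y ~ x)
  se <- .slope_se(x, stats::residuals(fit))
  n_bins <- max(1, min(n_bins, floor(length(x) / 2)))
  grp <- cut(rank(x, ties.method = "first"), breaks = n_bins, labels = FALSE)
  bins <- do.call(rbind, lapply(split(seq_along(x), grp), function(i)
    data.frame(x_mean = mean(x[i]), y_mean = mean(y[i]),
               y_sd = if (length(i) > 1) stats::sd(y[i]) else NA_real_,
               n = length(i))))
  list(slope = unname(stats::coef(fit)[2]), slope_se = se,
       intercept = unname(stats::coef(fit)[1]),
       predicted_slope = pred, bins = bins, degenerate = FALSE)
}

#' Adder statistics
#'
#' OLS regression of added length `S_D - S_0` on birth length `S_0`; slope 0
#' is a perfect adder, slope -1 a perfect sizer (division at a fixed
#' threshold).  Reported, not asserted: the statistic summarizes whatever
#' correlation structure the data carry.
#'
#' @param cycles table with S0_um and SD_um.
#' @return List with `slope`, `slope_se`, `pearson_r`, `n`, `degenerate`.
#' @export
adder_stats <- function(cycles) {
  stopifnot(nrow(cycles) >= 3)
  S0 <- cycles$S0_um
  added <- cycles$SD_um - S0
  if (stats::var(S0) == 0)
    return(list(slope = NA_real_, slope_se = NA_real_, pearson_r = NA_real_,
                n = length(S0), degenerate = TRUE))
  fit <- stats::lm(added ~ S0)
  list(slope = unname(stats::coef(fit)[2]),
       slope_se = .slope_se(S0, stats::residuals(fit)),
       pearson_r = stats::cor(S0, added), n = length(S0),
       degenerate = FALSE)
}

#' Recover growth parameters from lineage data
#'
#' Inverts the generative model: the growth rate from per-cycle exponential
#' fits of length against time, `tau` as the mean interval from the 65%
#' crossing to division, and the per-generation permissive length as the mean
#' length at the crossing.  Confidence intervals are normal approximations.
#'
#' @param cycles,intensity generator-format tables.
#' @param threshold_fraction,background_mean see [ring_formation_time()].
#' @param conf confidence level, default 0.95.
#' @return List with `alpha` (estimate, se, ci), `tau` (likewise),
#'   `L_stable_by_generation` (data frame generation_rel, mean, se, n) and
#'   `n_skipped` (cycles with fewer than 3 length samples).
#' @export
recover_growth_params <- function(cycles, intensity,
                                  threshold_fraction = 0.65,
                                  background_mean = 0, conf = 0.95) {
  stopifnot(nrow(cycles) >= 10)
  key <- interaction(intensity$lineage_id, intensity$generation, drop = TRUE)
  groups <- split(intensity, key)
  alphas <- numeric(0)
  n_skipped <- 0L
  for (grp in groups) {
    ok <- is.finite(grp$length_um) & grp$length_um > 0
    if (sum(ok) < 3 || stats::var(grp$time_min[ok]) == 0) {
      n_skipped <- n_skipped + 1L
      next
    }
    cf <- stats::.lm.fit(cbind(1, grp$time_min[ok]), log(grp$length_um[ok]))
    alphas <- c(alphas, cf$coefficients[2])
  }
  if (n_skipped > 0)
    message(n_skipped, " cycle(s) skipped in growth-rate fits (<3 usable ",
            "length samples)")
  if (!length(alphas)) stop("no cycle had enough length samples")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  summ <- function(v) {
    m <- mean(v)
    se <- if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
    list(estimate = m, se = se, ci = c(m - z * se, m + z * se),
         n = length(v))
  }
  an <- analyze_cycles(cycles, intensity, threshold_fraction,
                       background_mean)$timing
  Lst <- aggregate_by_generation(an, metrics = "S_z_est")
  Lst <- data.frame(generation_rel = Lst$generation_rel, mean = Lst$mean,
                    se = Lst$sem, n = Lst$n)
  list(alpha = summ(alphas),
       tau = summ(an$post_interval[is.finite(an$post_interval)]),
       L_stable_by_generation = Lst, n_skipped = n_skipped)
}

# standard error of an OLS slope from the regressor and residuals (avoids
# summary.lm's perfect-fit warning on noiseless data)
.slope_se <- function(x, res) {
  n <- length(x)
  if (n <= 2) return(NA_real_)
  sqrt(sum(res^2) / (n - 2) / sum((x - mean(x))^2))
}
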
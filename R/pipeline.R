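#' Default end-to-end pipeline configuration
#'
#' The nested configuration consumed by [run_pipeline()]: Min model kinetics,
#' the ratio/length scan, induction kinetics, growth parameters, the
#' synthetic-lineage generator and the analysis settings.  The shipped
#' default (inst/extdata/pipeline_default.yaml) runs a reduced-resolution
#' demonstration of the whole chain.
#'
#' @param path YAML file to read; `NULL` (default) loads the packaged
#'   default configuration.
#' @return A validated nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "pipeline_default.yaml",
                        package = "minsize", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  validate_pipeline_config(raw)
}

# allowed keys per section; unknown keys are rejected with their location
.config_schema <- list(
  model = c("D_D", "D_E", "D_m", "sigma_D", "sigma_dD", "sigma_E",
            "sigma_de", "k_exchange", "dens_D", "dens_E", "geometry_factor"),
  scan = c("ratio_multipliers", "lengths", "criterion", "t_end", "dx",
           "use_sim_map"),
  occupancy = c("window_w", "threshold_mode", "theta", "burn_in"),
  induction = c("minE_initial", "minE_final", "t_c", "t_s", "unit"),
  growth = c("alpha", "tau", "lopt_a", "lopt_b"),
  synth = c("n_lineages", "n_generations", "alpha_cv", "tau_cv",
            "division_fraction_sd", "lstable_cv", "induction_start_gen",
            "ring_plateau", "intensity_noise_sd", "background_mean"),
  analysis = c("threshold_fraction", "g_max"),
  run = c("seed", "out_dir")
)

#' Validate a raw pipeline configuration
#'
#' Rejects unknown sections or keys (reporting their location) and fills in
#' defaults for everything omitted.
#'
#' @param raw nested list (e.g. from `yaml::read_yaml()`).
#' @return Validated `pipeline_config` list.
#' @export
validate_pipeline_config <- function(raw) {
  stopifnot(is.list(raw))
  bad_sec <- setdiff(names(raw), names(.config_schema))
  if (length(bad_sec))
    stop("unknown config section(s): ", paste(bad_sec, collapse = ", "))
  for (sec in names(raw)) {
    bad <- setdiff(names(raw[[sec]]), .config_schema[[sec]])
    if (length(bad))
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
  }
  defaults <- list(
    model = list(),
    scan = list(ratio_multipliers = c(1, 1.04, 1.08),
                lengths = seq(2.5, 6, 0.5),
                criterion = "argmin_avg_occupancy", t_end = 400, dx = 0.1,
                use_sim_map = FALSE),
    occupancy = list(window_w = 0.5, threshold_mode = "fraction_of_spatial_mean",
                     theta = 0.5, burn_in = 200),
    induction = list(minE_initial = 1, minE_final = 3, t_c = 50, t_s = 25,
                     unit = "min"),
    growth = list(alpha = log(2) / 25, tau = 18.75, lopt_a = 2.4,
                  lopt_b = 0.6),
    synth = list(n_lineages = 10, n_generations = 12, alpha_cv = 0.07,
                 tau_cv = 0.07, division_fraction_sd = 0.035,
                 lstable_cv = 0.05, induction_start_gen = 6,
                 ring_plateau = 1000, intensity_noise_sd = 20,
                 background_mean = 100),
    analysis = list(threshold_fraction = 0.65, g_max = 10),
    run = list(seed = 1, out_dir = "results")
  )
  cfg <- defaults
  for (sec in names(raw))
    cfg[[sec]] <- utils::modifyList(defaults[[sec]], raw[[sec]])
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write a pipeline configuration to YAML
#' @param config a `pipeline_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the chained analysis pipeline
#'
#' Executes, in order: the MinE/MinD ratio scan of the reaction-diffusion
#' model; the linear fit of the optimal length against the ratio; the
#' generational growth recursion under the configured induction; the
#' synthetic mother-machine generator; and the single-cell trace analysis.
#' All intermediate tables are written as CSV/JSON into `out_dir` together
#' with the resolved configuration, and every stage is seeded from the
#' single run seed (stage i uses `seed + 1000*i`).
#'
#' When `scan$use_sim_map` is TRUE the generational model and the generator
#' use the simulation-derived length map with the induction expressed on the
#' model's ratio scale; otherwise they use the configured `growth` map.
#'
#' @param config a `pipeline_config` (see [pipeline_config()]).
#' @param out_dir output directory, overriding `config$run$out_dir`.
#' @param seed seed overriding `config$run$seed`.
#' @return Invisibly, a list with the scan, trajectory, synthetic data and
#'   analysis results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         seed = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir)) config$run$out_dir <- out_dir
  if (!is.null(seed)) config$run$seed <- seed
  out_dir <- config$run$out_dir
  seed <- config$run$seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_pipeline_config(config, file.path(out_dir, "resolved_config.yaml"))

  params <- do.call(min_params, config$model)
  occ <- do.call(occupancy_config, config$occupancy)

  # stage 1: ratio scan + linear map
  scan <- scan_ratios(params, config$scan$ratio_multipliers,
                      config$scan$lengths, config = occ,
                      criterion = config$scan$criterion,
                      t_end = config$scan$t_end, dx = config$scan$dx,
                      seed = seed + 1000)
  utils::write.csv(scan$table, file.path(out_dir, "ratio_scan.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(a = scan$fit_intercept, b = scan$fit_slope, R2 = scan$fit_R2,
         resolution = scan$resolution, criterion = scan$criterion),
    file.path(out_dir, "lopt_fit.json"), auto_unbox = TRUE, digits = NA)

  # stage 2: generational trajectory
  growth <- do.call(growth_params, config$growth)
  if (isTRUE(config$scan$use_sim_map)) {
    growth$lopt_a <- scan$fit_intercept
    growth$lopt_b <- scan$fit_slope
    # induction plateau on the model ratio scale: top of the scanned range
    config$induction$minE_final <- config$induction$minE_initial *
      max(config$scan$ratio_multipliers)
  }
  induction <- do.call(induction_params, config$induction)
  traj <- run_generations(config$analysis$g_max, growth, induction)
  utils::write.csv(traj, file.path(out_dir, "generations.csv"),
                   row.names = FALSE)

  # stage 3: synthetic lineages
  synth_cfg <- do.call(lineage_config, c(
    config$synth,
    list(alpha_mean = growth$alpha, tau_mean = growth$tau,
         induction = induction, growth = growth, seed = seed + 3000)))
  synth <- generate_lineage(synth_cfg)
  utils::write.csv(synth$cycles, file.path(out_dir, "cycles.csv"),
                   row.names = FALSE)
  utils::write.csv(synth$intensity, file.path(out_dir, "intensity.csv"),
                   row.names = FALSE)

  # stage 4: trace analysis
  an <- analyze_cycles(synth$cycles, synth$intensity,
                       threshold_fraction = config$analysis$threshold_fraction,
                       background_mean = config$synth$background_mean)
  agg <- aggregate_by_generation(an$timing)
  utils::write.csv(an$timing, file.path(out_dir, "ring_timing.csv"),
                   row.names = FALSE)
  utils::write.csv(agg, file.path(out_dir, "generation_aggregates.csv"),
                   row.names = FALSE)

  pairs <- generate_sister_pairs(synth_cfg)
  sis <- sister_pair_stats(pairs)
  utils::write.csv(pairs, file.path(out_dir, "pairs.csv"), row.names = FALSE)
  add <- adder_stats(an$timing)
  jsonlite::write_json(
    list(sister_slope = sis$slope, sister_slope_se = sis$slope_se,
         sister_predicted_slope = sis$predicted_slope,
         adder_slope = add$slope, adder_slope_se = add$slope_se,
         adder_r = add$pearson_r, n_cycles = nrow(an$timing),
         n_excluded = an$n_excluded),
    file.path(out_dir, "summary_stats.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(scan = scan, trajectory = traj, synth = synth,
                 analysis = an, aggregates = agg, pairs = pairs,
                 sister = sis, adder = add))
}
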
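#' Pipeline configuration
#'
#' Assembles and validates the full set of pipeline parameters with
#' defaults matching the assay protocol: 30 s baseline window, 10 s
#' response tail, 7-point 3-fold dilution series topping at 0.5 mM,
#' censoring at log10(EC50) = -2 triggered by non-convergence or an EC50
#' above the top tested concentration, Bartlett gate at alpha 0.05.
#'
#' @param out_dir Output directory for all stage products.
#' @param traces,plate_map,ligand_table Input file paths (defaults: the
#'   files [run_simulate()] writes into \code{out_dir}).
#' @param baseline_s,response_tail_s Trace windows (s).
#' @param top_conc,fold,n_points Dilution protocol (molar, fold, count).
#' @param censor_value,censor_trigger EC50 censoring convention.
#' @param fit_mode Hill fitting mode, see [fit_dose_response()].
#' @param alpha_bartlett Bartlett gate level for test selection.
#' @param label_map Significance label thresholds.
#' @param n_bio Biological replicates to simulate.
#' @param noise_sd,kinetic_tau Simulation noise (fluorescence units) and
#'   rise time constant (s).
#' @param seed Integer seed for all pipeline randomness.
#' @return Object of class \code{"pipeline_config"} (a validated list).
#' @export
pipeline_config <- function(out_dir = "orpharm_out",
                            traces = file.path(out_dir, "traces.csv"),
                            plate_map = file.path(out_dir, "plate_map.csv"),
                            ligand_table = file.path(out_dir,
                                                     "ligand_panel.csv"),
                            baseline_s = 30, response_tail_s = 10,
                            top_conc = 5e-4, fold = 3, n_points = 7,
                            censor_value = -2,
                            censor_trigger = c("nonconvergence", "above_top"),
                            fit_mode = "pooled",
                            alpha_bartlett = 0.05,
                            label_map = c("****" = 1e-4, "***" = 1e-3,
                                          "**" = 1e-2, "*" = 5e-2),
                            n_bio = 3, noise_sd = 5, kinetic_tau = 10,
                            seed = 1) {
  cfg <- list(out_dir = out_dir, traces = traces, plate_map = plate_map,
              ligand_table = ligand_table, baseline_s = baseline_s,
              response_tail_s = response_tail_s, top_conc = top_conc,
              fold = fold, n_points = n_points, censor_value = censor_value,
              censor_trigger = censor_trigger, fit_mode = fit_mode,
              alpha_bartlett = alpha_bartlett, label_map = label_map,
              n_bio = n_bio, noise_sd = noise_sd, kinetic_tau = kinetic_tau,
              seed = as.integer(seed))
  if (cfg$top_conc <= 0) {
    stop("pipeline_config: top_conc must be > 0", call. = FALSE)
  }
  if (cfg$fold <= 1) {
    stop("pipeline_config: fold must be > 1", call. = FALSE)
  }
  if (cfg$n_points < 1 || cfg$n_bio < 1) {
    stop("pipeline_config: n_points and n_bio must be >= 1", call. = FALSE)
  }
  if (cfg$baseline_s <= 0 || cfg$response_tail_s <= 0) {
    stop("pipeline_config: window lengths must be > 0", call. = FALSE)
  }
  if (cfg$noise_sd < 0 || cfg$kinetic_tau <= 0) {
    stop("pipeline_config: noise_sd must be >= 0, kinetic_tau > 0",
         call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Read/write a pipeline configuration
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return \code{read_pipeline_config} returns a \code{pipeline_config}.
#' @export
write_pipeline_config <- function(config, path) {
  lst <- unclass(config)
  lst$label_map <- as.list(lst$label_map)  # keep names through YAML
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$label_map <- unlist(raw$label_map)
  raw$censor_trigger <- unlist(raw$censor_trigger)
  do.call(pipeline_config, raw)
}

# short content hash of the config, stamped into output headers; paths are
# excluded so identical analyses hash identically wherever they are written
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  keep <- setdiff(names(config),
                  c("out_dir", "traces", "plate_map", "ligand_table"))
  yaml::write_yaml(unclass(config)[keep], tmp)
  substr(unname(tools::md5sum(tmp)), 1, 8)
}

# one CSV dialect throughout: comma-separated, "." decimal, header row,
# empty cell = missing, "#"-prefixed provenance header lines
write_stage_csv <- function(df, path, config) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# orpharm %s config %s",
                     as.character(utils::packageVersion("orpharm")),
                     config_hash(config)), con)
  utils::write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a pipeline CSV file
#'
#' Reads the package's strict delimited dialect (comma, header row,
#' empty cell = missing, leading \code{#} provenance lines).
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_stage_csv <- function(path) {
  if (!file.exists(path)) {
    stop("read_stage_csv: missing file ", path,
         " - run the prerequisite pipeline stage first", call. = FALSE)
  }
  utils::read.csv(path, comment.char = "#", na.strings = "")
}

#' Default simulation ground truth
#'
#' A broadly tuned wild-type receptor over a mixed agonist/weak/
#' non-agonist/inhibitor panel, used by [run_simulate()] when no truth is
#' supplied. EC50s span 1 uM - 0.1 mM within the tested range, plus one
#' non-saturating ligand (EC50 above the 0.5 mM top concentration) and
#' one inhibitor.
#'
#' @param noise_sd,kinetic_tau Passed to [ground_truth()].
#' @return A [ground_truth()] object.
#' @export
default_truth <- function(noise_sd = 5, kinetic_tau = 10) {
  ligands <- data.frame(
    ligand_id = c("eugenol", "carvone", "citronellol", "geraniol",
                  "benzaldehyde", "octanol", "caffeine", "vuaa1"),
    log_ec50 = c(-6, -5.5, -5, -4.5, -4, -3.5, 0, -4.5),
    amplitude = c(1.2, 1.0, 0.8, 0.9, 0.6, 0.5, 0.05, -0.4),
    slope = c(1.2, 1.0, 1.0, 1.1, 0.9, 1.0, 1.0, 1.0)
  )
  ground_truth("WT", ligands, kinetic_tau = kinetic_tau,
               noise_sd = noise_sd)
}

#' Run the simulation stage
#'
#' Simulates a multi-plate assay and a descriptor panel, writing
#' traces.csv, plate_map.csv, ground_truth.yaml and ligand_panel.csv to
#' the configured output directory. Deterministic under a fixed config.
#'
#' @param config A [pipeline_config()].
#' @param truth Optional [ground_truth()]; default [default_truth()].
#' @return (invisibly) list of written file paths.
#' @export
run_simulate <- function(config, truth = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(truth)) {
    truth <- default_truth(noise_sd = config$noise_sd,
                           kinetic_tau = config$kinetic_tau)
  }
  conc <- make_dilution_series(config$top_conc, config$fold, config$n_points)
  sim <- simulate_assay(truth, n_bio = config$n_bio, concentrations = conc,
                        seed = config$seed)
  dp <- simulate_descriptor_panel(
    n_ligands = 54,
    informative_weights = c(polar_surface_area = -1.0,
                            water_solubility = -0.6),
    noise_sd = 0.5, n_missing = 6, seed = config$seed + 1L
  )
  paths <- list(
    traces = config$traces, plate_map = config$plate_map,
    ligand_table = config$ligand_table,
    ground_truth = file.path(config$out_dir, "ground_truth.yaml"),
    config = file.path(config$out_dir, "config.yaml")
  )
  write_stage_csv(sim$traces, paths$traces, config)
  write_stage_csv(sim$plate_map, paths$plate_map, config)
  write_stage_csv(dp$panel, paths$ligand_table, config)
  yaml::write_yaml(
    list(receptor = unname(truth$receptor_id),
         ligands = sim$truth[!duplicated(sim$truth$ligand_id),
                             c("ligand_id", "log_ec50", "amplitude", "slope")],
         kinetic_tau = truth$kinetic_tau, noise_sd = truth$noise_sd,
         descriptor_weights = as.list(dp$truth$weights),
         descriptor_missing = dp$truth$missing_ligands,
         seed = config$seed),
    paths$ground_truth)
  write_pipeline_config(config, paths$config)
  invisible(paths)
}

#' Run the trace-processing and dose-response stage
#'
#' Reads the trace and plate-map files, computes biological-replicate
#' measurements, fits censored Hill curves and writes measurements.csv
#' and fits.csv.
#'
#' @param config A [pipeline_config()].
#' @return (invisibly) list(measurements, fits, paths).
#' @export
run_fit <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  traces <- read_stage_csv(config$traces)
  plate_map <- read_stage_csv(config$plate_map)
  meas <- process_traces(traces, plate_map,
                         addition_time = config$baseline_s,
                         baseline_s = config$baseline_s,
                         tail_s = config$response_tail_s)
  drs <- fit_dose_response(meas, mode = config$fit_mode,
                           censor_value = config$censor_value,
                           censor_trigger = config$censor_trigger)
  fits <- as.data.frame(drs)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(measurements = file.path(config$out_dir, "measurements.csv"),
                fits = file.path(config$out_dir, "fits.csv"))
  write_stage_csv(meas, paths$measurements, config)
  write_stage_csv(fits, paths$fits, config)
  invisible(list(measurements = meas, fits = fits, drs = drs,
                 paths = paths))
}

#' Run the tuning stage
#'
#' Builds per-receptor tuning profiles and sparseness from fits.csv,
#' writes tuning.csv (ligands ordered by the reference receptor) and
#' sparseness.csv. When more than one receptor is present, mutants are
#' compared to the reference with the ANOVA/Dunnett vs Brown-Forsythe
#' selection logic and comparisons.csv is written too.
#'
#' @param config A [pipeline_config()].
#' @param reference_receptor Receptor ordering the tuning curve
#'   (default: first receptor in the fits table).
#' @return (invisibly) list(tuning, sparseness, comparisons, paths).
#' @export
run_tune <- function(config, reference_receptor = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  fits <- read_stage_csv(file.path(config$out_dir, "fits.csv"))
  receptors <- unique(fits$receptor_id)
  if (is.null(reference_receptor)) reference_receptor <- receptors[1]
  profiles <- lapply(receptors, function(r) tuning_profile(fits, r))
  curve <- build_tuning_curve(profiles, reference_receptor)
  sparseness <- data.frame(
    receptor_id = vapply(profiles, `[[`, character(1), "receptor_id"),
    n_ligands = vapply(profiles, `[[`, numeric(1), "n"),
    sparseness = vapply(profiles, `[[`, numeric(1), "sparseness")
  )
  paths <- list(tuning = file.path(config$out_dir, "tuning.csv"),
                sparseness = file.path(config$out_dir, "sparseness.csv"))
  write_stage_csv(curve, paths$tuning, config)
  write_stage_csv(sparseness, paths$sparseness, config)

  comparisons <- NULL
  if (length(receptors) > 1) {
    groups <- lapply(receptors, function(r) {
      fits$log_ec50[fits$receptor_id == r]
    })
    names(groups) <- receptors
    keep <- vapply(groups, function(g) sum(is.finite(g)) >= 2, logical(1))
    if (sum(keep) > 1 && keep[[reference_receptor]]) {
      comparisons <- compare_to_wildtype(groups[keep], reference_receptor,
                                         alpha_bartlett = config$alpha_bartlett,
                                         censor_value = config$censor_value,
                                         label_map = config$label_map)
      paths$comparisons <- file.path(config$out_dir, "comparisons.csv")
      write_stage_csv(as.data.frame(unclass(comparisons)),
                      paths$comparisons, config)
    }
  }
  invisible(list(tuning = curve, sparseness = sparseness,
                 comparisons = comparisons, paths = paths))
}

#' Run the descriptor-regression stage
#'
#' Filters the ligand panel to descriptor-complete rows and ranks all
#' 1- and 2-descriptor OLS models of the activity index, writing
#' regression_ranking.csv (and the exclusion report).
#'
#' @param config A [pipeline_config()].
#' @return (invisibly) list(ranking, paths).
#' @export
run_regress <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  panel <- read_stage_csv(config$ligand_table)
  ranking <- rank_descriptor_models(panel)
  paths <- list(ranking = file.path(config$out_dir, "regression_ranking.csv"),
                excluded = file.path(config$out_dir,
                                     "regression_excluded.csv"))
  write_stage_csv(as.data.frame(unclass(ranking)), paths$ranking, config)
  write_stage_csv(attr(ranking, "excluded"), paths$excluded, config)
  invisible(list(ranking = ranking, paths = paths))
}

#' Run the full pipeline
#'
#' simulate, fit, tune, regress in order.
#'
#' @param config A [pipeline_config()].
#' @param truth Optional simulation ground truth.
#' @return (invisibly) list of per-stage results.
#' @export
run_all <- function(config, truth = NULL) {
  sim <- run_simulate(config, truth)
  fit <- run_fit(config)
  tune <- run_tune(config)
  reg <- run_regress(config)
  invisible(list(simulate = sim, fit = fit, tune = tune, regress = reg))
}
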
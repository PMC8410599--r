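#' Ground-truth receptor tuning for simulation
#'
#' Bundles the forward-model parameters of one receptor over a ligand
#' panel: per-ligand Hill parameters (log10 EC50 in molar, saturating
#' amplitude in deltaF/F units — negative for inhibitors — and Hill
#' slope), the fluorescence rise time constant and the per-sample
#' additive noise level. These are the quantities the downstream fitting
#' stages try to recover.
#'
#' @param receptor_id Receptor label.
#' @param ligands data.frame with columns \code{ligand_id},
#'   \code{log_ec50}, \code{amplitude}, \code{slope}.
#' @param kinetic_tau Time constant (s) of the single-exponential
#'   fluorescence approach to steady state after ligand addition.
#' @param noise_sd Additive Gaussian noise sd per fluorescence sample
#'   (arbitrary fluorescence units).
#' @param baseline_f Noise-free baseline fluorescence of a well at plate
#'   scale 1 (arbitrary units).
#' @return Object of class \code{"ground_truth"}.
#' @export
ground_truth <- function(receptor_id, ligands, kinetic_tau = 10,
                         noise_sd = 0, baseline_f = 1000) {
  stopifnot(is.data.frame(ligands),
            all(c("ligand_id", "log_ec50", "amplitude", "slope") %in%
                  names(ligands)))
  if (any(ligands$slope <= 0)) {
    stop("ground_truth: every Hill slope must be > 0", call. = FALSE)
  }
  if (kinetic_tau <= 0 || noise_sd < 0 || baseline_f <= 0) {
    stop("ground_truth: kinetic_tau and baseline_f must be > 0, noise_sd >= 0",
         call. = FALSE)
  }
  if (anyDuplicated(ligands$ligand_id)) {
    stop("ground_truth: duplicated ligand_id", call. = FALSE)
  }
  structure(
    list(receptor_id = receptor_id,
         ligands = ligands[c("ligand_id", "log_ec50", "amplitude", "slope")],
         kinetic_tau = kinetic_tau, noise_sd = noise_sd,
         baseline_f = baseline_f),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth for receptor ", x$receptor_id, ": ",
      nrow(x$ligands), " ligands, tau = ", x$kinetic_tau,
      " s, noise sd = ", x$noise_sd, "\n", sep = "")
  invisible(x)
}

#' Lay out one assay plate
#'
#' Builds a plate map in the assay's standard design: for each ligand a
#' descending dilution series with four technical-replicate wells per
#' concentration, one positive-control condition (wild-type receptor +
#' cognate ligand at the top concentration, four wells) and one
#' negative-control condition (calcium indicator transfected alone, four
#' wells).
#'
#' @param plate_id Plate label.
#' @param receptor_id Receptor assayed on this plate.
#' @param ligand_ids Ligands assayed on this plate.
#' @param concentrations Dilution series (molar), e.g.
#'   \code{make_dilution_series(5e-4, 3, 7)}.
#' @param positive_control list(receptor_id=, ligand_id=,
#'   concentration=): the per-plate reference condition used for
#'   response normalization.
#' @param n_technical Technical replicates per condition.
#' @return data.frame with one row per well: \code{plate_id},
#'   \code{well_id}, \code{receptor_id}, \code{ligand_id},
#'   \code{concentration}, \code{role}, \code{technical_replicate}.
#' @export
make_plate_layout <- function(plate_id, receptor_id, ligand_ids,
                              concentrations,
                              positive_control = list(
                                receptor_id = receptor_id,
                                ligand_id = ligand_ids[1],
                                concentration = max(concentrations)),
                              n_technical = 4) {
  if (any(diff(concentrations) >= 0)) {
    stop("make_plate_layout: concentrations must be strictly decreasing",
         call. = FALSE)
  }
  rows <- list()
  for (lig in ligand_ids) {
    for (conc in concentrations) {
      rows[[length(rows) + 1]] <- data.frame(
        receptor_id = receptor_id, ligand_id = lig, concentration = conc,
        role = "experimental", technical_replicate = seq_len(n_technical)
      )
    }
  }
  rows[[length(rows) + 1]] <- data.frame(
    receptor_id = positive_control$receptor_id,
    ligand_id = positive_control$ligand_id,
    concentration = positive_control$concentration,
    role = "positive_control", technical_replicate = seq_len(n_technical)
  )
  rows[[length(rows) + 1]] <- data.frame(
    receptor_id = "GCaMP_only", ligand_id = "none", concentration = 0,
    role = "negative_control", technical_replicate = seq_len(n_technical)
  )
  layout <- do.call(rbind, rows)
  layout <- cbind(
    plate_id = plate_id,
    well_id = sprintf("%s_W%03d", plate_id, seq_len(nrow(layout))),
    layout
  )
  rownames(layout) <- NULL
  layout
}

#' Simulate fluorescence traces for one plate
#'
#' Forward model: each well reads a constant baseline
#' \code{baseline_f * plate_scale} until ligand addition, then rises (or
#' falls, for inhibitors) single-exponentially with time constant
#' \code{kinetic_tau} towards
#' \code{baseline_f * plate_scale * (1 + hill_response(c))}; i.i.d.
#' Gaussian noise of sd \code{noise_sd} is added to every sample.
#' Negative-control wells receive no ligand response. The multiplicative
#' plate scale emulates plate-to-plate variation in transfection
#' efficiency and cell count, which the control normalization is designed
#' to remove.
#'
#' @param truth A [ground_truth()] object.
#' @param layout A plate map from [make_plate_layout()] (single plate).
#' @param plate_scale Multiplicative fluorescence scale of this plate, > 0.
#' @param timing list(baseline_s, read_s, sample_hz): 30 s baseline, 2 min
#'   post-addition read, 1 Hz sampling by default.
#' @param seed Integer seed; identical seed and parameters give
#'   bit-identical output.
#' @return list with \code{traces} (long data.frame: plate_id, well_id,
#'   time_s, fluorescence), \code{plate_map} (the layout), and
#'   \code{truth} (per-ligand true parameter table).
#' @export
simulate_plate <- function(truth, layout, plate_scale = 1,
                           timing = list(baseline_s = 30, read_s = 120,
                                         sample_hz = 1),
                           seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  if (plate_scale <= 0) {
    stop("simulate_plate: plate_scale must be > 0", call. = FALSE)
  }
  if (timing$baseline_s <= 0 || timing$read_s <= 0 || timing$sample_hz <= 0) {
    stop("simulate_plate: timing values must be positive", call. = FALSE)
  }
  exper <- layout$role %in% c("experimental", "positive_control")
  unknown <- setdiff(layout$ligand_id[exper], truth$ligands$ligand_id)
  if (length(unknown) > 0) {
    stop("simulate_plate: layout references ligands absent from truth: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  unknown_rec <- setdiff(layout$receptor_id[exper], truth$receptor_id)
  if (length(unknown_rec) > 0) {
    stop("simulate_plate: layout references receptors absent from truth: ",
         paste(unknown_rec, collapse = ", "), call. = FALSE)
  }

  dt <- 1 / timing$sample_hz
  t_add <- timing$baseline_s
  times <- seq(0, timing$baseline_s + timing$read_s - dt, by = dt)
  set.seed(seed)

  f0 <- truth$baseline_f * plate_scale
  n_wells <- nrow(layout)
  lig_idx <- match(layout$ligand_id, truth$ligands$ligand_id)

  trace_list <- vector("list", n_wells)
  for (w in seq_len(n_wells)) {
    role <- layout$role[w]
    dff_inf <- 0
    if (role %in% c("experimental", "positive_control")) {
      p <- truth$ligands[lig_idx[w], ]
      dff_inf <- hill_response(layout$concentration[w], p$log_ec50,
                               p$amplitude, p$slope)
    }
    rise <- ifelse(times < t_add, 0,
                   dff_inf * (1 - exp(-(times - t_add) / truth$kinetic_tau)))
    f <- f0 * (1 + rise)
    if (truth$noise_sd > 0) {
      f <- f + stats::rnorm(length(times), sd = truth$noise_sd)
    }
    trace_list[[w]] <- data.frame(
      plate_id = layout$plate_id[w], well_id = layout$well_id[w],
      time_s = times, fluorescence = f
    )
  }
  truth_tab <- cbind(receptor_id = truth$receptor_id, truth$ligands,
                     kinetic_tau = truth$kinetic_tau,
                     noise_sd = truth$noise_sd, plate_scale = plate_scale)
  list(traces = do.call(rbind, trace_list), plate_map = layout,
       truth = truth_tab)
}

#' Simulate a multi-plate assay (one plate per biological replicate)
#'
#' Runs [simulate_plate()] once per biological replicate with a distinct
#' plate scale, reproducing the study design in which the four technical
#' replicates on a plate average into a single biological replicate and
#' plates differ by a multiplicative transfection-efficiency scale.
#'
#' @param truth A [ground_truth()] object.
#' @param ligand_ids Ligands to assay (default: all ligands in the truth).
#' @param n_bio Number of biological replicates (plates).
#' @param concentrations Dilution series (default the assay protocol:
#'   7 points, 3-fold, 0.5 mM top).
#' @param positive_control Passed to [make_plate_layout()]; default uses
#'   the truth's highest-amplitude ligand at the top concentration.
#' @param plate_scales Numeric vector of per-plate scales; by default
#'   drawn lognormal(0, 0.25), a realistic transfection variability.
#' @param timing,seed As in [simulate_plate()].
#' @return list(traces, plate_map, truth) with all plates row-bound.
#' @export
simulate_assay <- function(truth, ligand_ids = truth$ligands$ligand_id,
                           n_bio = 3,
                           concentrations = make_dilution_series(5e-4, 3, 7),
                           positive_control = NULL,
                           plate_scales = NULL,
                           timing = list(baseline_s = 30, read_s = 120,
                                         sample_hz = 1),
                           seed = 1) {
  set.seed(seed)
  if (is.null(plate_scales)) {
    plate_scales <- stats::rlnorm(n_bio, meanlog = 0, sdlog = 0.25)
  }
  stopifnot(length(plate_scales) == n_bio)
  if (is.null(positive_control)) {
    best <- truth$ligands$ligand_id[which.max(truth$ligands$amplitude)]
    positive_control <- list(receptor_id = truth$receptor_id,
                             ligand_id = best,
                             concentration = max(concentrations))
  }
  # one sub-seed per plate so plates are independent but reproducible
  plate_seeds <- sample.int(.Machine$integer.max - 1L, n_bio)
  sims <- vector("list", n_bio)
  for (b in seq_len(n_bio)) {
    layout <- make_plate_layout(
      plate_id = sprintf("P%02d", b), receptor_id = truth$receptor_id,
      ligand_ids = ligand_ids, concentrations = concentrations,
      positive_control = positive_control
    )
    sims[[b]] <- simulate_plate(truth, layout, plate_scale = plate_scales[b],
                                timing = timing, seed = plate_seeds[b])
  }
  truth_tab <- do.call(rbind, lapply(seq_len(n_bio), function(b) {
    cbind(sims[[b]]$truth, plate_id = sprintf("P%02d", b))
  }))
  list(traces = do.call(rbind, lapply(sims, `[[`, "traces")),
       plate_map = do.call(rbind, lapply(sims, `[[`, "plate_map")),
       truth = truth_tab)
}

#' Simulate a ligand descriptor panel with planted linear truth
#'
#' Generates a panel of ligands with 11 physicochemical descriptor
#' columns and an activity index that is a planted linear function of a
#' chosen subset of descriptors plus Gaussian noise:
#' \code{activity = intercept + sum(weight * descriptor) + noise}.
#' A chosen number of ligands get at least one missing descriptor value,
#' emulating panels whose published property tables are incomplete.
#'
#' @param n_ligands Panel size.
#' @param informative_weights Named numeric vector mapping descriptor
#'   names (from \code{descriptor_names}) to true coefficients.
#' @param noise_sd Gaussian noise sd on the activity index.
#' @param n_missing Number of ligands carrying at least one missing
#'   descriptor value; must be < \code{n_ligands}.
#' @param intercept True intercept.
#' @param descriptor_names The 11 descriptor column names.
#' @param seed Integer seed.
#' @return list(panel = data.frame(ligand_id, 11 descriptors,
#'   activity_index), truth = list(weights, intercept, missing_ligands,
#'   seed)).
#' @export
simulate_descriptor_panel <- function(n_ligands, informative_weights = NULL,
                                      noise_sd = 0, n_missing = 0,
                                      intercept = 0,
                                      descriptor_names = orpharm_descriptors(),
                                      seed = 1) {
  if (n_missing >= n_ligands) {
    stop("simulate_descriptor_panel: n_missing must be < n_ligands",
         call. = FALSE)
  }
  if (!is.null(informative_weights)) {
    bad <- setdiff(names(informative_weights), descriptor_names)
    if (length(bad) > 0) {
      stop("simulate_descriptor_panel: unknown descriptor(s) in weights: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  set.seed(seed)
  p <- length(descriptor_names)
  X <- matrix(stats::rnorm(n_ligands * p), n_ligands, p,
              dimnames = list(NULL, descriptor_names))
  w <- stats::setNames(numeric(p), descriptor_names)
  w[names(informative_weights)] <- informative_weights
  activity <- intercept + drop(X %*% w)
  if (noise_sd > 0) {
    activity <- activity + stats::rnorm(n_ligands, sd = noise_sd)
  }
  panel <- data.frame(ligand_id = sprintf("ligand_%02d", seq_len(n_ligands)),
                      X, activity_index = activity,
                      check.names = FALSE)
  missing_ligands <- character(0)
  if (n_missing > 0) {
    miss_rows <- sample.int(n_ligands, n_missing)
    for (r in miss_rows) {
      k <- sample.int(p, sample(1:3, 1))  # 1-3 missing fields per ligand
      panel[r, descriptor_names[k]] <- NA_real_
    }
    missing_ligands <- panel$ligand_id[sort(miss_rows)]
  }
  list(panel = panel,
       truth = list(weights = w, intercept = intercept,
                    missing_ligands = missing_ligands, seed = seed))
}

#' Default physicochemical descriptor set
#'
#' The 11 generic ligand descriptors used across the package: polar
#' surface area, logP, water solubility, hydrogen-bond donors and
#' acceptors, molecular weight, rotatable bonds, heavy atoms, aromatic
#' rings, vapour pressure and density.
#'
#' @return Character vector of 11 descriptor names.
#' @export
orpharm_descriptors <- function() {
  c("polar_surface_area", "logP", "water_solubility", "h_bond_donors",
    "h_bond_acceptors", "molecular_weight", "rotatable_bonds",
    "heavy_atoms", "aromatic_rings", "vapour_pressure", "density")
}
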
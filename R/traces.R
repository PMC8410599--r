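#' Baseline fluorescence of a well
#'
#' Arithmetic mean fluorescence over the 30 s (by default) immediately
#' before ligand addition, the half-open window
#' \code{[addition_time - baseline_s, addition_time)}.
#'
#' @param time_s,fluorescence Sample times (s, strictly increasing) and
#'   fluorescence values of one well.
#' @param addition_time Ligand addition time (s).
#' @param baseline_s Baseline window length (s).
#' @return Baseline fluorescence F.
#' @export
compute_baseline <- function(time_s, fluorescence, addition_time,
                             baseline_s = 30) {
  if (is.unsorted(time_s, strictly = TRUE)) {
    stop("compute_baseline: sample times must be strictly increasing",
         call. = FALSE)
  }
  if (addition_time - baseline_s < time_s[1] - 1e-9) {
    stop("compute_baseline: no full baseline window before addition",
         call. = FALSE)
  }
  in_win <- time_s >= addition_time - baseline_s & time_s < addition_time
  if (sum(in_win) < 2) {
    stop("compute_baseline: fewer than 2 samples in the baseline window",
         call. = FALSE)
  }
  mean(fluorescence[in_win])
}

#' Fluorescence change of a well
#'
#' deltaF is the mean fluorescence over the final \code{tail_s} seconds of
#' the recording (half-open window \code{(t_end - tail_s, t_end]}) minus
#' the baseline F; deltaF/F divides by the baseline.
#'
#' @inheritParams compute_baseline
#' @param tail_s Response window length at the end of the recording (s).
#' @return list(F, dF, dff).
#' @export
compute_delta_f <- function(time_s, fluorescence, addition_time,
                            baseline_s = 30, tail_s = 10) {
  f0 <- compute_baseline(time_s, fluorescence, addition_time, baseline_s)
  t_end <- time_s[length(time_s)]
  in_tail <- time_s > t_end - tail_s & time_s <= t_end
  if (sum(in_tail) < 2) {
    stop("compute_delta_f: fewer than 2 samples in the final response window",
         call. = FALSE)
  }
  df <- mean(fluorescence[in_tail]) - f0
  list(F = f0, dF = df, dff = df / f0)
}

#' Per-well response measurements for a set of plates
#'
#' Computes baseline F, deltaF and deltaF/F for every well of a long-format
#' trace table. Wells with non-positive baseline fluorescence are flagged
#' invalid (and excluded downstream), never imputed.
#'
#' @param traces Long data.frame: plate_id, well_id, time_s, fluorescence.
#' @param plate_map data.frame: plate_id, well_id, receptor_id, ligand_id,
#'   concentration, role, technical_replicate.
#' @param addition_time Ligand addition time (s).
#' @param baseline_s,tail_s Window lengths (s).
#' @return data.frame with one row per well: the plate-map columns plus
#'   F, dF, dff and a logical \code{valid}.
#' @export
measure_wells <- function(traces, plate_map, addition_time = 30,
                          baseline_s = 30, tail_s = 10) {
  need <- c("plate_id", "well_id", "time_s", "fluorescence")
  if (!all(need %in% names(traces))) {
    stop("measure_wells: traces must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  key <- paste(traces$plate_id, traces$well_id, sep = "\r")
  map_key <- paste(plate_map$plate_id, plate_map$well_id, sep = "\r")
  split_t <- split(traces$time_s, key)
  split_f <- split(traces$fluorescence, key)
  out <- plate_map
  out$F <- NA_real_
  out$dF <- NA_real_
  out$dff <- NA_real_
  out$valid <- FALSE
  for (i in seq_len(nrow(out))) {
    k <- map_key[i]
    ts <- split_t[[k]]
    if (is.null(ts)) {
      warning("measure_wells: no trace for well ", plate_map$well_id[i],
              "; excluded", call. = FALSE)
      next
    }
    m <- compute_delta_f(ts, split_f[[k]], addition_time, baseline_s, tail_s)
    out$F[i] <- m$F
    out$dF[i] <- m$dF
    out$dff[i] <- m$dff
    if (m$F > 0) {
      out$valid[i] <- TRUE
    } else {
      warning("measure_wells: well ", plate_map$well_id[i],
              " has baseline F <= 0; excluded", call. = FALSE)
    }
  }
  out
}

#' Maximum deltaF/F of a plate's positive control
#'
#' The positive-control reference value of one plate: deltaF/F averaged
#' across the control's valid technical replicates at each of its tested
#' concentrations, then the maximum over concentrations (at a single,
#' saturating control concentration the two definitions coincide).
#'
#' @param well_measurements Output of [measure_wells()] for one plate.
#' @return Positive-control maximum deltaF/F (> 0).
#' @export
positive_control_max <- function(well_measurements) {
  pc <- well_measurements[well_measurements$role == "positive_control" &
                            well_measurements$valid, , drop = FALSE]
  if (nrow(pc) == 0) {
    stop("positive_control_max: plate ",
         unique(well_measurements$plate_id)[1],
         " has no valid positive-control wells", call. = FALSE)
  }
  by_conc <- tapply(pc$dff, pc$concentration, mean)
  mx <- max(by_conc)
  if (mx <= 0) {
    stop("positive_control_max: degenerate positive control (max dF/F <= 0)",
         call. = FALSE)
  }
  mx
}

#' Normalize a response to the plate positive control
#'
#' @param dff deltaF/F value(s).
#' @param control_max The plate's positive-control maximum deltaF/F, > 0.
#' @return \code{dff / control_max}.
#' @export
normalize_to_positive_control <- function(dff, control_max) {
  if (!is.finite(control_max) || control_max <= 0) {
    stop("normalize_to_positive_control: control max must be > 0",
         call. = FALSE)
  }
  dff / control_max
}

#' Baseline activity relative to the indicator-only control
#'
#' Ratio of a well's baseline fluorescence to the mean baseline of the
#' same plate's negative-control (indicator transfected alone) wells.
#' Values above 1 indicate elevated spontaneous activity, as seen for
#' some receptor mutants.
#'
#' @param F Baseline fluorescence value(s).
#' @param well_measurements Output of [measure_wells()] for that plate.
#' @return \code{F / mean(F of negative-control wells)}.
#' @export
baseline_activity <- function(F, well_measurements) {
  nc <- well_measurements[well_measurements$role == "negative_control" &
                            well_measurements$valid, , drop = FALSE]
  if (nrow(nc) == 0) {
    stop("baseline_activity: plate ",
         unique(well_measurements$plate_id)[1],
         " has no valid negative-control wells", call. = FALSE)
  }
  F / mean(nc$F)
}

#' Average technical replicates into biological replicates
#'
#' Collapses per-well measurements into one row per plate x receptor x
#' ligand x concentration condition — the plate's four technical
#' replicates average into a single biological replicate. Wells flagged
#' invalid are excluded; a condition with zero valid wells is dropped
#' with a warning.
#'
#' @param well_measurements Output of [measure_wells()] with a
#'   \code{dff_normalized} column (see [process_traces()]).
#' @return data.frame: plate_id, receptor_id, ligand_id, concentration,
#'   role, dff_normalized, dff, F, baseline_ratio, n_technical.
#' @export
average_technical_replicates <- function(well_measurements) {
  wm <- well_measurements
  cond <- interaction(wm$plate_id, wm$receptor_id, wm$ligand_id,
                      wm$concentration, wm$role, drop = TRUE)
  pieces <- lapply(split(wm, cond), function(d) {
    v <- d[d$valid, , drop = FALSE]
    if (nrow(v) == 0) {
      warning("average_technical_replicates: condition ",
              d$receptor_id[1], "/", d$ligand_id[1], "@",
              format(d$concentration[1]), " on plate ", d$plate_id[1],
              " has no valid wells; dropped", call. = FALSE)
      return(NULL)
    }
    data.frame(plate_id = v$plate_id[1], receptor_id = v$receptor_id[1],
               ligand_id = v$ligand_id[1], concentration = v$concentration[1],
               role = v$role[1],
               dff_normalized = mean(v$dff_normalized),
               dff = mean(v$dff), F = mean(v$F),
               baseline_ratio = mean(v$baseline_ratio),
               n_technical = nrow(v))
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    stop("average_technical_replicates: no valid conditions", call. = FALSE)
  }
  out <- out[order(out$plate_id, out$receptor_id, out$ligand_id,
                   -out$concentration), ]
  rownames(out) <- NULL
  out
}

#' Traces to biological-replicate measurements
#'
#' Full trace-processing stage: per-well deltaF/F, per-plate
#' positive-control normalization and indicator-only baseline ratios,
#' then technical-replicate averaging. Each plate contributes one
#' biological replicate per condition.
#'
#' @inheritParams measure_wells
#' @return data.frame as from [average_technical_replicates()].
#' @export
process_traces <- function(traces, plate_map, addition_time = 30,
                           baseline_s = 30, tail_s = 10) {
  wm <- measure_wells(traces, plate_map, addition_time, baseline_s, tail_s)
  wm$dff_normalized <- NA_real_
  wm$baseline_ratio <- NA_real_
  for (p in unique(wm$plate_id)) {
    on_plate <- wm$plate_id == p
    cm <- positive_control_max(wm[on_plate, , drop = FALSE])
    wm$dff_normalized[on_plate] <-
      normalize_to_positive_control(wm$dff[on_plate], cm)
    wm$baseline_ratio[on_plate] <-
      baseline_activity(wm$F[on_plate], wm[on_plate, , drop = FALSE])
  }
  average_technical_replicates(wm)
}
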
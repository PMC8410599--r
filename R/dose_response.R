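#' Maximum deltaF/F of a dose-response series
#'
#' The maximum response achieved at the highest tested concentration:
#' mean across biological replicates of the normalized deltaF/F at the top
#' concentration. The sign is preserved, so inhibitory series yield a
#' negative value.
#'
#' @param concentrations Concentration (molar) of each replicate
#'   measurement.
#' @param responses Normalized deltaF/F of each replicate measurement.
#' @return Mean response at \code{max(concentrations)}.
#' @export
max_dff <- function(concentrations, responses) {
  ok <- is.finite(concentrations) & is.finite(responses)
  concentrations <- concentrations[ok]
  responses <- responses[ok]
  if (length(concentrations) == 0) {
    stop("max_dff: no data", call. = FALSE)
  }
  top <- max(concentrations)
  at_top <- responses[concentrations == top]
  if (length(at_top) == 0) {
    stop("max_dff: no responses at the top concentration", call. = FALSE)
  }
  mean(at_top)
}

#' Fit dose-response curves for every receptor x ligand condition
#'
#' For each receptor x ligand pair in a biological-replicate measurement
#' table (see [process_traces()]), fits the Hill model, applies the EC50
#' censoring convention, and computes max deltaF/F and the activity
#' index. By default the Hill fit is to the mean response across
#' biological replicates at each concentration (\code{mode = "pooled"});
#' \code{mode = "per_replicate"} instead fits each biological replicate
#' separately and averages the resulting log EC50s, also retaining the
#' per-replicate values for group comparisons.
#'
#' @param measurements data.frame from [process_traces()] (columns
#'   plate_id, receptor_id, ligand_id, concentration, role,
#'   dff_normalized). Only \code{role == "experimental"} rows are fitted.
#' @param mode Pooled-mean fitting (default) or per-replicate fitting.
#' @param censor_value,censor_trigger Passed to [apply_censoring()].
#' @return Object of class \code{"dose_response_set"}: list of per-pair
#'   records (each with \code{fit}, \code{max_dff},
#'   \code{activity_index}, \code{replicate_log_ec50}, data) plus a
#'   summary table; see [as.data.frame.dose_response_set()].
#' @export
fit_dose_response <- function(measurements, mode = c("pooled", "per_replicate"),
                              censor_value = -2,
                              censor_trigger = c("nonconvergence",
                                                 "above_top")) {
  mode <- match.arg(mode)
  m <- measurements[measurements$role == "experimental", , drop = FALSE]
  if (nrow(m) == 0) {
    stop("fit_dose_response: no experimental measurements", call. = FALSE)
  }
  pair <- interaction(m$receptor_id, m$ligand_id, drop = TRUE)
  curves <- lapply(split(m, pair), function(d) {
    conc_means <- tapply(d$dff_normalized, d$concentration, mean)
    conc <- as.numeric(names(conc_means))
    pooled_fit <- fit_hill(conc, as.numeric(conc_means))

    rep_lec <- NULL
    if (mode == "per_replicate") {
      rep_lec <- vapply(split(d, d$plate_id), function(r) {
        f <- tryCatch(fit_hill(r$concentration, r$dff_normalized),
                      error = function(e) NULL)
        if (is.null(f)) return(NA_real_)
        f <- apply_censoring(f, censor_value = censor_value,
                             trigger = censor_trigger)
        f$log_ec50
      }, numeric(1))
    }

    fit <- apply_censoring(pooled_fit, censor_value = censor_value,
                           trigger = censor_trigger)
    if (mode == "per_replicate" && any(is.finite(rep_lec))) {
      fit$log_ec50 <- mean(rep_lec, na.rm = TRUE)
      # per-replicate mean can land on the censor value without the pooled
      # censor rule firing; keep the pooled censored flag
    }
    md <- max_dff(d$concentration, d$dff_normalized)
    list(receptor_id = d$receptor_id[1], ligand_id = d$ligand_id[1],
         concentrations = sort(conc, decreasing = TRUE),
         fit = fit, max_dff = md,
         activity_index = activity_index(fit$log_ec50, md),
         replicate_log_ec50 = rep_lec,
         n_bio = length(unique(d$plate_id)))
  })
  structure(list(curves = unname(curves), mode = mode,
                 censor_value = censor_value),
            class = "dose_response_set")
}

#' Summary table of a dose-response set
#'
#' @param x A [fit_dose_response()] result.
#' @param ... Unused.
#' @return data.frame: receptor_id, ligand_id, log_ec50, amplitude,
#'   slope, converged, censored, max_dff, activity_index, n_bio.
#' @export
as.data.frame.dose_response_set <- function(x, ...) {
  out <- do.call(rbind, lapply(x$curves, function(cv) {
    data.frame(receptor_id = cv$receptor_id, ligand_id = cv$ligand_id,
               log_ec50 = cv$fit$log_ec50, amplitude = cv$fit$amplitude,
               slope = cv$fit$slope, converged = cv$fit$converged,
               censored = cv$fit$censored, max_dff = cv$max_dff,
               activity_index = cv$activity_index, n_bio = cv$n_bio)
  }))
  out <- out[order(out$receptor_id, out$ligand_id), ]
  rownames(out) <- NULL
  out
}

#' @export
print.dose_response_set <- function(x, ...) {
  tab <- as.data.frame(x)
  cat("Dose-response set: ", nrow(tab), " receptor x ligand curves (",
      x$mode, " fitting), ", sum(tab$censored), " censored\n", sep = "")
  print(utils::head(tab, 10))
  if (nrow(tab) > 10) cat("...\n")
  invisible(x)
}

#' @export
summary.dose_response_set <- function(object, ...) {
  tab <- as.data.frame(object)
  structure(list(table = tab, n_censored = sum(tab$censored),
                 mode = object$mode),
            class = "summary.dose_response_set")
}

#' @export
print.summary.dose_response_set <- function(x, ...) {
  cat("Dose-response summary (", x$mode, " fitting): ",
      nrow(x$table), " curves, ", x$n_censored, " censored\n", sep = "")
  print(x$table)
  invisible(x)
}
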
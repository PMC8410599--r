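#' Hill dose-response model
#'
#' Expected steady-state response of a receptor at a given ligand
#' concentration under the three-parameter Hill model with a fixed zero
#' lower asymptote,
#' \deqn{r(c) = A \frac{c^h}{c^h + \mathrm{EC}_{50}^h},}
#' where \eqn{A} is the saturating response (negative for inhibitors),
#' \eqn{\mathrm{EC}_{50} = 10^{\code{log_ec50}}} molar is the
#' half-maximal concentration and \eqn{h} is the Hill slope.
#'
#' @param concentration Ligand concentration(s) in molar, >= 0. Vectorized.
#' @param log_ec50 log10 of the EC50 in molar.
#' @param amplitude Saturating response (normalized deltaF/F); may be
#'   negative for inhibitory ligands.
#' @param slope Hill coefficient, > 0.
#' @return Numeric vector of expected responses; 0 at zero concentration,
#'   approaching \code{amplitude} at saturating concentration.
#' @examples
#' hill_response(1e-5, log_ec50 = -5, amplitude = 1, slope = 1)  # half max
#' @export
hill_response <- function(concentration, log_ec50, amplitude, slope) {
  if (any(concentration < 0)) {
    stop("hill_response: concentration must be non-negative", call. = FALSE)
  }
  if (slope <= 0) {
    stop("hill_response: slope must be positive", call. = FALSE)
  }
  ec50 <- 10^log_ec50
  # work on the log-concentration scale to avoid overflow for large slopes
  out <- numeric(length(concentration))
  pos <- concentration > 0
  if (any(pos)) {
    lr <- slope * (log(concentration[pos]) - log(ec50))
    out[pos] <- amplitude * stats::plogis(lr)
  }
  out
}

#' Make a serial dilution series
#'
#' Descending concentration series produced by repeated constant-fold
#' dilution from a top concentration, the standard plate-assay protocol
#' (default elsewhere in the package: 7 points, 3-fold, 0.5 mM top).
#'
#' @param top_concentration Highest concentration, molar, > 0.
#' @param fold Dilution factor between successive points, > 1.
#' @param n_points Number of concentrations, >= 1.
#' @return Numeric vector of length \code{n_points}, strictly decreasing,
#'   element \code{i} equal to \code{top_concentration / fold^(i-1)}.
#' @examples
#' make_dilution_series(5e-4, 3, 7)
#' @export
make_dilution_series <- function(top_concentration, fold, n_points) {
  if (!is.finite(top_concentration) || top_concentration <= 0) {
    stop("make_dilution_series: top_concentration must be > 0", call. = FALSE)
  }
  if (!is.finite(fold) || fold <= 1) {
    stop("make_dilution_series: fold must be > 1", call. = FALSE)
  }
  if (n_points < 1) {
    stop("make_dilution_series: n_points must be >= 1", call. = FALSE)
  }
  top_concentration / fold^(seq_len(n_points) - 1)
}

#' Fit a Hill curve to a concentration series
#'
#' Unweighted least-squares fit of the three-parameter Hill model (zero
#' fixed lower asymptote, see [hill_response()]) to mean responses at a
#' series of concentrations. Negative amplitudes (inhibition) are
#' permitted. The slope is bounded to [0.2, 10]; starting values are the
#' response at the top concentration (amplitude), the log concentration of
#' half-maximal response by linear interpolation (log EC50) and 1 (slope).
#'
#' A series with (numerically) zero response variance cannot constrain the
#' model; it is returned unconverged with \code{degenerate = TRUE} and an
#' amplitude equal to the common response value, so that downstream
#' censoring applies.
#'
#' @param concentrations Molar concentrations, >= 4 distinct values.
#' @param responses Mean normalized deltaF/F at each concentration.
#' @param slope_bounds Length-2 bounds on the Hill slope.
#' @return An object of class \code{"hill_fit"}: a list with elements
#'   \code{log_ec50}, \code{amplitude}, \code{slope}, \code{converged},
#'   \code{censored} (always \code{FALSE} here; see [apply_censoring()]),
#'   \code{degenerate}, \code{fit_rss}, \code{n}, plus the data.
#' @seealso [apply_censoring()], [activity_index()]
#' @export
fit_hill <- function(concentrations, responses, slope_bounds = c(0.2, 10)) {
  ok <- is.finite(concentrations) & is.finite(responses)
  concentrations <- concentrations[ok]
  responses <- responses[ok]
  if (length(unique(concentrations)) < 4) {
    stop("fit_hill: need >= 4 distinct concentrations", call. = FALSE)
  }
  o <- order(concentrations)
  conc <- concentrations[o]
  resp <- responses[o]

  res <- structure(
    list(
      log_ec50 = NA_real_, amplitude = NA_real_, slope = NA_real_,
      converged = FALSE, censored = FALSE, degenerate = FALSE,
      fit_rss = NA_real_, n = length(conc),
      concentrations = conc, responses = resp
    ),
    class = "hill_fit"
  )

  if (stats::sd(resp) < 1e-12) {
    res$amplitude <- mean(resp)
    res$degenerate <- TRUE
    res$fit_rss <- sum((resp - mean(resp))^2)
    return(res)
  }

  amp0 <- resp[length(resp)]  # response at the top concentration
  lec0 <- .init_log_ec50(conc, resp, amp0)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      resp ~ amp * stats::plogis(s * (log(conc) - log(10^lec))),
      start = list(amp = amp0, lec = lec0, s = 1),
      lower = c(-Inf, -Inf, slope_bounds[1]),
      upper = c(Inf, Inf, slope_bounds[2]),
      # tight tolerances so last-ulp input perturbations (e.g. a pure gain
      # rescale of the traces) cannot move the optimum detectably
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15, gtol = 1e-15)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(res)
  }
  cf <- stats::coef(fit)
  res$log_ec50 <- unname(cf["lec"])
  res$amplitude <- unname(cf["amp"])
  res$slope <- unname(cf["s"])
  res$fit_rss <- sum(stats::resid(fit)^2)
  res$converged <- isTRUE(fit$convInfo$isConv) && is.finite(res$log_ec50)
  res
}

# log10 concentration of half-maximal response by linear interpolation;
# falls back to the geometric mid-concentration when the series never
# crosses half max.
.init_log_ec50 <- function(conc, resp, amp) {
  lx <- log10(conc)
  target <- amp / 2
  if (abs(amp) < .Machine$double.eps) {
    return(mean(range(lx)))
  }
  frac <- resp / amp  # 1 at saturation regardless of sign
  cross <- which(frac[-1] >= 0.5 & frac[-length(frac)] < 0.5)
  if (length(cross) == 0) {
    return(mean(range(lx)))
  }
  i <- cross[1]
  f1 <- frac[i]; f2 <- frac[i + 1]
  if (f2 == f1) {
    return(lx[i])
  }
  lx[i] + (0.5 - f1) / (f2 - f1) * (lx[i + 1] - lx[i])
}

#' Apply the EC50 censoring convention
#'
#' Dose-response series that never saturate within the tested
#' concentration range cannot support a Hill fit; following the assay
#' convention, such ligands are assigned a fixed placeholder
#' log10(EC50) of -2 (10 mM, more than an order of magnitude above the
#' usual 0.5 mM top concentration). The rule fires when the fit did not
#' converge or when the fitted EC50 exceeds the highest tested
#' concentration.
#'
#' @param fit A [fit_hill()] result.
#' @param concentrations Concentration series the fit was attempted on
#'   (defaults to the series stored in \code{fit}).
#' @param censor_value Placeholder log10 EC50 for censored fits.
#' @param trigger Censoring triggers to apply: non-convergence and/or a
#'   fitted EC50 above the top tested concentration.
#' @return The fit, with \code{censored} and \code{log_ec50} updated.
#' @export
apply_censoring <- function(fit, concentrations = fit$concentrations,
                            censor_value = -2,
                            trigger = c("nonconvergence", "above_top")) {
  trigger <- match.arg(trigger, several.ok = TRUE)
  stopifnot(inherits(fit, "hill_fit"))
  top <- max(concentrations)
  hit <- ("nonconvergence" %in% trigger && !fit$converged) ||
    ("above_top" %in% trigger && fit$converged &&
       is.finite(fit$log_ec50) && 10^fit$log_ec50 > top)
  if (hit) {
    fit$censored <- TRUE
    fit$log_ec50 <- censor_value
  }
  fit
}

#' Activity index
#'
#' Composite agonism score combining apparent affinity and efficacy:
#' \deqn{\mathrm{index} = -\log_{10}(\mathrm{EC}_{50}) \times
#'   \max \Delta F/F.}
#' Censored ligands (log EC50 fixed at -2) therefore score exactly
#' \code{2 * max_dff}.
#'
#' @param log_ec50 log10 EC50 (molar), possibly the censoring value.
#' @param max_dff Maximum normalized deltaF/F, i.e. the mean response at
#'   the highest tested concentration (sign preserved).
#' @return \code{(-log_ec50) * max_dff}.
#' @export
activity_index <- function(log_ec50, max_dff) {
  stopifnot(is.finite(log_ec50), is.finite(max_dff))
  (-log_ec50) * max_dff
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Hill fit (", x$n, " concentrations)\n", sep = "")
  if (x$censored) {
    cat("  censored: log10(EC50) set to ", format(x$log_ec50), "\n", sep = "")
  } else if (x$converged) {
    cat(sprintf("  log10(EC50) = %.4f  amplitude = %.4f  slope = %.3f\n",
                x$log_ec50, x$amplitude, x$slope))
  } else {
    cat("  not converged", if (x$degenerate) " (degenerate series)", "\n",
        sep = "")
  }
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(log_ec50 = object$log_ec50, amplitude = object$amplitude,
    slope = object$slope)
}

#' Predicted response from a fitted Hill curve
#'
#' @param object A \code{hill_fit}.
#' @param newdata Optional numeric vector of concentrations (molar);
#'   defaults to the fitted concentrations.
#' @param ... Unused.
#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$concentrations else newdata
  if (!object$converged && !object$censored) {
    stop("predict.hill_fit: fit did not converge", call. = FALSE)
  }
  if (object$censored && !is.finite(object$slope)) {
    # censored without usable shape parameters: no curve to evaluate
    stop("predict.hill_fit: censored fit has no fitted curve", call. = FALSE)
  }
  hill_response(conc, object$log_ec50, object$amplitude, object$slope)
}

#' @export
residuals.hill_fit <- function(object, ...) {
  object$responses - predict(object)
}

#' @export
summary.hill_fit <- function(object, ...) {
  out <- c(coef(object),
           rss = object$fit_rss, n = object$n,
           converged = as.numeric(object$converged),
           censored = as.numeric(object$censored))
  class(out) <- "summary.hill_fit"
  out
}

#' @export
print.summary.hill_fit <- function(x, ...) {
  print(unclass(x))
  invisible(x)
}

#' @export
plot.hill_fit <- function(x, ...) {
  conc <- x$concentrations
  graphics::plot(log10(conc), x$responses, xlab = "log10 concentration (M)",
                 ylab = "normalized dF/F", ...)
  if (x$converged || (x$censored && is.finite(x$slope))) {
    lc <- seq(min(log10(conc)) - 0.5, max(log10(conc)) + 0.5, length.out = 200)
    graphics::lines(lc, hill_response(10^lc, x$log_ec50, x$amplitude, x$slope))
  }
  invisible(x)
}
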
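#' Lifetime sparseness of a tuning profile
#'
#' Quantifies how narrowly a receptor is tuned across a ligand panel:
#' \deqn{S = \frac{1}{1 - 1/n}\left(1 -
#'   \frac{(\sum_i \mathrm{res}_i / n)^2}{\sum_i \mathrm{res}_i^2 / n}
#'   \right)}
#' where \eqn{n} is the panel size and \eqn{\mathrm{res}_i} the response
#' to ligand \eqn{i}. Inhibitory responses (values below 0) are set to 0
#' before the calculation. S is 0 for a perfectly flat profile and 1 for
#' a receptor responding to a single ligand.
#'
#' @param responses Numeric response vector (activity indices or max
#'   deltaF/F), length >= 2.
#' @return S in [0, 1]; \code{NA} (with a warning) when every response is
#'   zero after zeroing negatives, where the statistic is a 0/0 form.
#' @examples
#' lifetime_sparseness(c(2, 1, 1, 0))  # 4/9
#' @export
lifetime_sparseness <- function(responses) {
  n <- length(responses)
  if (n < 2) {
    stop("lifetime_sparseness: need at least 2 responses", call. = FALSE)
  }
  if (any(!is.finite(responses))) {
    stop("lifetime_sparseness: responses must be finite", call. = FALSE)
  }
  res <- pmax(responses, 0)
  if (all(res == 0)) {
    warning("lifetime_sparseness: all responses are zero after zeroing ",
            "negatives; sparseness undefined", call. = FALSE)
    return(NA_real_)
  }
  (1 / (1 - 1 / n)) * (1 - (sum(res / n))^2 / (sum(res^2) / n))
}

#' Build a receptor tuning profile
#'
#' One receptor's responses (activity index by default, or max deltaF/F)
#' across a ligand panel, with its lifetime sparseness.
#'
#' @param fits Dose-response table (from
#'   \code{as.data.frame(fit_dose_response(...))}) or a
#'   \code{dose_response_set}.
#' @param receptor_id Receptor to profile.
#' @param metric Response metric: \code{"activity_index"} (default) or
#'   \code{"max_dff"}.
#' @return Object of class \code{"tuning_profile"}: list with
#'   \code{receptor_id}, \code{panel} (ligand ids), \code{responses},
#'   \code{metric}, \code{n}, \code{sparseness}.
#' @export
tuning_profile <- function(fits, receptor_id,
                           metric = c("activity_index", "max_dff")) {
  metric <- match.arg(metric)
  if (inherits(fits, "dose_response_set")) fits <- as.data.frame(fits)
  d <- fits[fits$receptor_id == receptor_id, , drop = FALSE]
  if (nrow(d) < 2) {
    stop("tuning_profile: receptor ", receptor_id,
         " has fewer than 2 ligands", call. = FALSE)
  }
  d <- d[order(d$ligand_id), ]
  responses <- stats::setNames(d[[metric]], d$ligand_id)
  structure(
    list(receptor_id = receptor_id, panel = d$ligand_id,
         responses = responses, metric = metric, n = nrow(d),
         sparseness = lifetime_sparseness(responses)),
    class = "tuning_profile"
  )
}

#' @export
print.tuning_profile <- function(x, ...) {
  cat("Tuning profile of ", x$receptor_id, ": ", x$n, " ligands (",
      x$metric, "), lifetime sparseness = ",
      format(round(x$sparseness, 4)), "\n", sep = "")
  invisible(x)
}

#' Assemble an ordered tuning curve across receptors
#'
#' Orders the ligand panel by descending response in a reference
#' receptor (ties broken by ligand name, ascending) and aligns every
#' other profile's responses to that order — the standard overlay used
#' to compare mutant tuning against wild type.
#'
#' @param profiles List of [tuning_profile()] objects sharing one panel.
#' @param reference_receptor receptor_id of the ordering reference.
#' @return data.frame: ligand_id (in reference order), rank, then one
#'   response column per receptor.
#' @export
build_tuning_curve <- function(profiles, reference_receptor) {
  ids <- vapply(profiles, `[[`, character(1), "receptor_id")
  names(profiles) <- ids
  if (!reference_receptor %in% ids) {
    stop("build_tuning_curve: reference receptor ", reference_receptor,
         " not among the profiles", call. = FALSE)
  }
  ref <- profiles[[reference_receptor]]
  for (p in profiles) {
    if (!identical(sort(p$panel), sort(ref$panel))) {
      extra <- setdiff(p$panel, ref$panel)
      miss <- setdiff(ref$panel, p$panel)
      stop("build_tuning_curve: panel mismatch for ", p$receptor_id,
           if (length(extra)) paste0("; extra: ", paste(extra, collapse = ", ")),
           if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", ")),
           call. = FALSE)
    }
  }
  ord <- order(-ref$responses, ref$panel)
  ligands <- ref$panel[ord]
  out <- data.frame(ligand_id = ligands, rank = seq_along(ligands))
  for (p in profiles) {
    out[[p$receptor_id]] <- unname(p$responses[ligands])
  }
  out
}

#' Fraction of a panel that are agonists
#'
#' Counts the panel ligands satisfying an explicit activation criterion.
#' The default criterion calls a ligand an agonist when its Hill fit was
#' not censored and its activity index is positive; the criterion used is
#' echoed into the result for provenance.
#'
#' @param fits Dose-response table or \code{dose_response_set}.
#' @param receptor_id Receptor to evaluate.
#' @param criterion Predicate taking the receptor's fit table and
#'   returning a logical vector.
#' @param criterion_label Description recorded in the output.
#' @return list(fraction, n_active, n, criterion).
#' @export
count_active <- function(fits, receptor_id,
                         criterion = function(d) !d$censored & d$activity_index > 0,
                         criterion_label = "non-censored fit and activity index > 0") {
  if (inherits(fits, "dose_response_set")) fits <- as.data.frame(fits)
  d <- fits[fits$receptor_id == receptor_id, , drop = FALSE]
  if (nrow(d) == 0) {
    stop("count_active: no ligands for receptor ", receptor_id,
         call. = FALSE)
  }
  hit <- criterion(d)
  list(fraction = mean(hit), n_active = sum(hit), n = nrow(d),
       criterion = criterion_label)
}
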
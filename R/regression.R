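#' Filter a ligand panel to descriptor-complete rows
#'
#' Retains exactly the ligands with no missing descriptor values and
#' reports each excluded ligand with its missing fields, mirroring the
#' practice of restricting regression analyses to ligands whose
#' physicochemical properties are fully tabulated.
#'
#' @param panel data.frame with a \code{ligand_id} column and descriptor
#'   columns.
#' @param descriptors Descriptor column names (default: the package's 11
#'   descriptors present in the panel).
#' @return list(retained = complete-row subset, excluded = data.frame
#'   (ligand_id, missing_fields)).
#' @export
filter_complete <- function(panel,
                            descriptors = intersect(orpharm_descriptors(),
                                                    names(panel))) {
  if (length(descriptors) == 0) {
    stop("filter_complete: no descriptor columns found", call. = FALSE)
  }
  miss <- is.na(panel[descriptors])
  any_miss <- rowSums(miss) > 0
  excluded <- data.frame(
    ligand_id = panel$ligand_id[any_miss],
    missing_fields = apply(miss[any_miss, , drop = FALSE], 1, function(r) {
      paste(descriptors[r], collapse = ";")
    })
  )
  rownames(excluded) <- NULL
  retained <- panel[!any_miss, , drop = FALSE]
  if (nrow(retained) == 0) {
    stop("filter_complete: no descriptor-complete ligands remain",
         call. = FALSE)
  }
  rownames(retained) <- NULL
  list(retained = retained, excluded = excluded)
}

#' Squared correlation of observed and modelled values
#'
#' The square of the Pearson correlation between observed and modelled
#' activity indices — for an OLS fit with intercept this equals the
#' coefficient of determination. Zero variance in either vector makes
#' the correlation undefined; such degenerate cases are mapped to 0 (with
#' a \code{"degenerate"} attribute) so model rankings remain total.
#'
#' @param observed,modelled Equal-length numeric vectors, length >= 3.
#' @return R-squared in [0, 1].
#' @export
r_squared <- function(observed, modelled) {
  if (length(observed) != length(modelled) || length(observed) < 3) {
    stop("r_squared: need equal-length vectors of length >= 3",
         call. = FALSE)
  }
  if (stats::sd(observed) == 0 || stats::sd(modelled) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  stats::cor(observed, modelled)^2
}

#' Fit one descriptor subset by ordinary least squares
#'
#' @param panel Descriptor-complete ligand table with an
#'   \code{activity_index} column.
#' @param subset Character vector of 1 or 2 descriptor names.
#' @return list(descriptors, coefficients (intercept first), r_squared,
#'   rank_deficient).
#' @export
fit_descriptor_model <- function(panel, subset) {
  X <- panel[subset]
  y <- panel$activity_index
  if (nrow(X) < length(subset) + 1) {
    stop("fit_descriptor_model: more coefficients than ligands",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ ., data = cbind(X, y = y))
  cf <- stats::coef(fit)
  deficient <- any(is.na(cf))
  r2 <- if (deficient) NA_real_ else
    as.numeric(r_squared(y, stats::fitted(fit)))
  list(descriptors = subset, coefficients = cf, r_squared = r2,
       rank_deficient = deficient)
}

#' Enumerate and rank low-dimensional descriptor regressions
#'
#' Fits every single-descriptor linear model and every unordered pair of
#' descriptors (for 11 descriptors: 11 + 55 models) predicting the
#' activity index, and ranks them by descending R-squared — the
#' exhaustive search over the low-dimensional descriptor space that
#' identifies which physicochemical properties best predict agonism.
#' Ties are broken lexicographically by descriptor names; rank-deficient
#' fits (e.g. a duplicated column) are flagged and placed after all
#' ranked models.
#'
#' @param panel Ligand table (missing values allowed; filtered via
#'   [filter_complete()] first).
#' @param descriptors Descriptor columns to search.
#' @param dimensions Subset sizes to enumerate (default 1 and 2).
#' @return Object of class \code{"descriptor_ranking"}: data.frame with
#'   columns rank, dimension, descriptors, r_squared, intercept,
#'   coefficient columns; attribute \code{"excluded"} carries the
#'   missing-descriptor exclusion report.
#' @export
rank_descriptor_models <- function(panel,
                                   descriptors = intersect(
                                     orpharm_descriptors(), names(panel)),
                                   dimensions = c(1, 2)) {
  flt <- filter_complete(panel, descriptors)
  d <- flt$retained
  subsets <- list()
  if (1 %in% dimensions) {
    subsets <- c(subsets, as.list(descriptors))
  }
  if (2 %in% dimensions && length(descriptors) >= 2) {
    cmb <- utils::combn(descriptors, 2, simplify = FALSE)
    subsets <- c(subsets, lapply(cmb, sort))  # alphabetical, for stable labels
  }
  fits <- lapply(subsets, function(s) fit_descriptor_model(d, s))
  rows <- do.call(rbind, lapply(fits, function(f) {
    cf <- f$coefficients
    data.frame(dimension = length(f$descriptors),
               descriptors = paste(f$descriptors, collapse = " + "),
               r_squared = f$r_squared,
               intercept = unname(cf["(Intercept)"]),
               coef_1 = unname(cf[2]),
               coef_2 = if (length(cf) >= 3) unname(cf[3]) else NA_real_,
               rank_deficient = f$rank_deficient)
  }))
  ord <- order(rows$rank_deficient, -rows$r_squared, rows$descriptors)
  rows <- rows[ord, ]
  rows$rank <- NA_integer_
  rows$rank[!rows$rank_deficient] <- seq_len(sum(!rows$rank_deficient))
  rows <- rows[c("rank", "dimension", "descriptors", "r_squared",
                 "intercept", "coef_1", "coef_2", "rank_deficient")]
  rownames(rows) <- NULL
  attr(rows, "excluded") <- flt$excluded
  attr(rows, "n_ligands") <- nrow(d)
  class(rows) <- c("descriptor_ranking", "data.frame")
  rows
}

#' @export
print.descriptor_ranking <- function(x, n = 10, ...) {
  cat("Descriptor regression ranking: ", nrow(x), " models on ",
      attr(x, "n_ligands"), " descriptor-complete ligands (",
      nrow(attr(x, "excluded")), " excluded)\n", sep = "")
  print(utils::head(as.data.frame(unclass(x))[
    c("rank", "dimension", "descriptors", "r_squared")], n))
  if (nrow(x) > n) cat("...\n")
  invisible(x)
}
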
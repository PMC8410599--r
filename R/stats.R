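#' Brown-Forsythe test between groups
#'
#' Robust one-way heteroscedasticity-tolerant comparison computed as an
#' ANOVA on median-centred absolute deviations
#' \eqn{z_{ij} = |y_{ij} - \mathrm{median}(y_j)|}: the ANOVA-style
#' Brown-Forsythe variant.
#'
#' @param values Numeric observations.
#' @param groups Factor (or coercible) of group labels, >= 2 groups.
#' @return list(statistic, df, p_value).
#' @export
brown_forsythe_test <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) {
    stop("brown_forsythe_test: need at least 2 groups", call. = FALSE)
  }
  med <- tapply(values, groups, stats::median)
  z <- abs(values - med[as.integer(groups)])
  a <- stats::anova(stats::lm(z ~ groups))
  list(statistic = a[["F value"]][1],
       df = c(a[["Df"]][1], a[["Df"]][2]),
       p_value = a[["Pr(>F)"]][1])
}

#' Map a p-value to a significance label
#'
#' @param p P-value.
#' @param label_map Named numeric vector mapping labels to upper p
#'   thresholds, checked in increasing threshold order.
#' @return Label string ("ns" when no threshold is met).
#' @export
significance_label <- function(p, label_map = c("****" = 1e-4, "***" = 1e-3,
                                                "**" = 1e-2, "*" = 5e-2)) {
  label_map <- sort(label_map)
  for (i in seq_along(label_map)) {
    if (p < label_map[i]) return(names(label_map)[i])
  }
  "ns"
}

#' Compare mutant receptors to wild type
#'
#' Implements the assay's test-selection logic on per-biological-replicate
#' log EC50 values. When any group contains censored ("incalculably
#' high") EC50 values and Bartlett's test rejects variance homogeneity at
#' \code{alpha_bartlett}, each mutant is compared to the control with a
#' Brown-Forsythe test; otherwise a one-way ANOVA is followed by
#' Dunnett's multiple comparisons of every mutant against the control.
#'
#' @param groups Named list of numeric vectors: per-receptor replicate
#'   log EC50 values (>= 2 replicates each); must include
#'   \code{control_id}.
#' @param control_id Name of the wild-type/control group.
#' @param alpha_bartlett Significance level for Bartlett's gate.
#' @param censor_value The censoring placeholder; values equal to it mark
#'   a group as containing censored EC50s.
#' @param label_map Passed to [significance_label()].
#' @return Object of class \code{"wt_comparison"}: data.frame with one
#'   row per mutant (mutant_id, control_id, test_used, p_value, label)
#'   plus attributes \code{bartlett_p} and \code{any_censored}.
#' @export
compare_to_wildtype <- function(groups, control_id, alpha_bartlett = 0.05,
                                censor_value = -2,
                                label_map = c("****" = 1e-4, "***" = 1e-3,
                                              "**" = 1e-2, "*" = 5e-2)) {
  if (!control_id %in% names(groups)) {
    stop("compare_to_wildtype: control group '", control_id, "' missing",
         call. = FALSE)
  }
  if (length(groups) < 2) {
    stop("compare_to_wildtype: need the control and at least one mutant",
         call. = FALSE)
  }
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("compare_to_wildtype: every group needs >= 2 replicates",
         call. = FALSE)
  }
  mutants <- setdiff(names(groups), control_id)
  values <- unlist(groups, use.names = FALSE)
  glab <- factor(rep(names(groups), lengths(groups)),
                 levels = c(control_id, mutants))

  any_censored <- any(vapply(groups, function(g) any(g == censor_value),
                             logical(1)))
  # Bartlett's test degenerates when a group has zero variance (e.g. all
  # replicates censored at the same value); treat that as non-homogeneous.
  zero_var <- any(vapply(groups, function(g) stats::var(g) == 0, logical(1)))
  bartlett_p <- if (zero_var) 0 else
    stats::bartlett.test(values, glab)$p.value

  use_bf <- any_censored && bartlett_p < alpha_bartlett

  if (use_bf) {
    rows <- lapply(mutants, function(m) {
      two <- c(groups[[control_id]], groups[[m]])
      lab <- rep(c(control_id, m), c(length(groups[[control_id]]),
                                     length(groups[[m]])))
      p <- brown_forsythe_test(two, lab)$p_value
      data.frame(mutant_id = m, control_id = control_id,
                 test_used = "brown_forsythe", p_value = p,
                 label = significance_label(p, label_map))
    })
  } else {
    fit <- stats::aov(values ~ glab)
    gh <- multcomp::glht(fit, linfct = multcomp::mcp(glab = "Dunnett"))
    ps <- summary(gh)$test$pvalues
    rows <- lapply(seq_along(mutants), function(i) {
      data.frame(mutant_id = mutants[i], control_id = control_id,
                 test_used = "anova_dunnett", p_value = ps[i],
                 label = significance_label(ps[i], label_map))
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "bartlett_p") <- bartlett_p
  attr(out, "any_censored") <- any_censored
  class(out) <- c("wt_comparison", "data.frame")
  out
}

#' @export
print.wt_comparison <- function(x, ...) {
  cat("Mutant vs wild-type comparisons (",
      if (x$test_used[1] == "brown_forsythe")
        "Brown-Forsythe branch" else "ANOVA + Dunnett branch",
      "; Bartlett p = ", format(signif(attr(x, "bartlett_p"), 3)),
      ")\n", sep = "")
  print(as.data.frame(unclass(x)[c("mutant_id", "control_id", "test_used",
                                   "p_value", "label")]))
  invisible(x)
}
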
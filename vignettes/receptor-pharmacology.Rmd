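---
title: "Quantifying olfactory receptor pharmacology from calcium plate assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying olfactory receptor pharmacology from calcium plate assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orpharm)
```

## The assay and its model

Insect odorant receptors are odorant-gated ion channels. A standard way to
map which ligands activate a receptor of unknown specificity
(deorphanization) is to co-express the receptor with a genetically encoded
calcium indicator (GCaMP) in HEK cells on a multi-well plate, apply each
ligand over a dilution series, and read fluorescence on a plate reader:
30 s of baseline, then a 2 min read after ligand addition. orpharm
implements the full quantification chain for this assay.

**Per-well response.** The baseline fluorescence $F$ is the mean over the
30 s before addition; $\Delta F$ is the mean over the final 10 s of the
recording minus $F$; the response readout is $\Delta F/F$. Because the
readout is a ratio, it is invariant to any multiplicative gain on the
trace — well-to-well indicator expression differences largely cancel.
Inhibitory responses appear as negative $\Delta F/F$ and are carried
through with their sign.

**Plate normalization.** Transfection efficiency and cell counts vary
between plates, scaling all fluorescence multiplicatively. Each plate
carries a positive control (the wild-type receptor with its cognate
agonist) and a negative control (indicator transfected alone). Every
$\Delta F/F$ is divided by the plate's positive-control maximum
$\Delta F/F$ — taken as the control's technical-replicate-averaged
response at its highest tested concentration, which at saturation equals
the maximum over its series. Baseline activity of a construct is reported
as its $F$ divided by the mean $F$ of the same plate's indicator-only
wells; ratios above 1 indicate constitutive channel opening, seen for
some binding-pocket mutants. The four technical replicates of each
condition on a plate average into one biological replicate.

**Dose–response model.** Each receptor × ligand series is fitted with a
three-parameter Hill curve with a fixed zero lower asymptote,

$$ r(c) = A \, \frac{c^{h}}{c^{h} + \mathrm{EC}_{50}^{h}}, $$

appropriate because responses are baseline-subtracted. $A$ may be
negative (inhibitors). Fitting is unweighted least squares on replicate
means (Levenberg–Marquardt via minpack.lm), with the slope bounded to
$[0.2, 10]$ and initialized at 1, the amplitude initialized at the
top-concentration response, and $\log_{10}\mathrm{EC}_{50}$ initialized
at the interpolated half-max concentration. Convergence tolerances are
set very tight (`ftol = ptol = gtol = 1e-15`) so that numerically
equivalent inputs — e.g. a whole plate rescaled by a constant gain —
yield identical parameters to well below $10^{-9}$.

**Censoring.** A ligand whose curve never saturates within the tested
range has no identifiable EC50. Such ligands are assigned
$\log_{10}(\mathrm{EC}_{50}/\mathrm{M}) = -2$ (10 mM — more than an
order of magnitude above the usual 0.5 mM top concentration). The verbal
criterion "too high to reach saturation" is operationalized as: the fit
failed to converge, **or** the fitted EC50 exceeds the highest tested
concentration. Both the value and the trigger are configurable. A series
with zero response variance (a null ligand) is flagged degenerate and
falls under the same rule.

**Activity index.** Agonism is summarized by
$\mathrm{index} = -\log_{10}(\mathrm{EC}_{50}) \times \max \Delta F/F$,
where $\max \Delta F/F$ is the mean normalized response at the highest
tested concentration (sign preserved). The index rises with apparent
affinity and with efficacy; censored ligands score exactly
$2 \times \max\Delta F/F$.

## Tuning breadth and statistics

**Lifetime sparseness.** Tuning breadth over a panel of $n$ ligands with
responses $\mathrm{res}_i$ is

$$ S = \frac{1}{1 - 1/n}\left(1 -
  \frac{\left(\sum_i \mathrm{res}_i / n\right)^2}
       {\sum_i \mathrm{res}_i^2 / n}\right), $$

with all negative (inhibitory) responses set to 0 first. $S = 0$ for a
flat profile, $S = 1$ for a single responder; it is invariant to
rescaling the whole profile. When every response is zero after zeroing,
the statistic is a 0/0 form and is returned as `NA` with a warning
rather than silently as 0 or 1. Either the activity index (default) or
max $\Delta F/F$ can serve as $\mathrm{res}_i$; both are supported
because either is a defensible response metric and they give similar
orderings on saturating panels.

**Tuning curves.** For mutant-vs-wild-type overlays, ligands are ordered
by descending response in a reference receptor and every other profile is
re-ordered identically. Ties are broken by ligand name, ascending, so
output is deterministic; the choice is arbitrary but fixed.

**Mutant comparisons.** Per-replicate log EC50 groups are compared with
the assay's test-selection logic: if any group contains censored
("incalculably high") EC50 values *and* Bartlett's test rejects variance
homogeneity at $\alpha = 0.05$ (configurable; no published value
dictates it), each mutant is compared to the control with a
Brown–Forsythe test; otherwise one-way ANOVA with Dunnett-adjusted
comparisons against the control. A group of identical censored values
has zero variance, where Bartlett's statistic is undefined; that is
treated as maximal heteroscedasticity (gate fires). Among the several
procedures called "Brown–Forsythe", we use the ANOVA-style variant on
median-centred absolute deviations $|y_{ij} - \tilde y_j|$ — which
variant the original figure legends meant is not stated, and this one is
both robust and cross-checkable (it equals Levene's test with median
centring). Significance-label thresholds are configurable because
published legends themselves differ between figures.

## Descriptor regression

Which physicochemical properties predict agonism is assessed by
exhaustive low-dimensional OLS: every single descriptor (11 models) and
every unordered pair (55 models) is fitted against the activity index
and ranked by $R^2$, the squared Pearson correlation between observed
and modelled values (identical to the coefficient of determination for
OLS with intercept). "Every unique permutation" of a pair yields the
same OLS fit, so unordered combinations are enumerated once. Ligands
with any missing descriptor are excluded first and reported (the
canonical panel: 54 ligands, 6 incomplete, 48 analysed). Zero-variance
degeneracies map to $R^2 = 0$ with a flag so the ranking stays total;
rank-deficient designs (duplicated columns) are flagged and left
unranked. Coefficient signs are reported — direction matters
scientifically — but ranking uses $R^2$ only, and no multiple-testing
correction is applied because the output is a ranking, not a set of
hypothesis tests.

## The simulator: what it emulates and what it does not

`simulate_plate()`/`simulate_assay()` generate the study design:
7-point 3-fold dilution series from a 0.5 mM top, 4 technical replicates
per concentration, per-plate positive and negative controls, one plate
per biological replicate. Each well reads a constant baseline
$F_0 \cdot s_p$ ($s_p$ the plate scale), then relaxes
single-exponentially (time constant `kinetic_tau`, default 10 s —
consistent with the slowly activating currents of these channels; no
published kinetic model exists, so the form is a modelling choice) to
$F_0 \, s_p\, (1 + r(c))$ with $r$ the Hill response; i.i.d. Gaussian
noise is added per sample. Defaults: 1 Hz sampling (coarse rates
suffice for 30 s/10 s window means; the plate reader's true interval is
unpublished), plate scales drawn lognormal(0, 0.25) as a realistic
transfection variability, baseline $F_0 = 1000$ arbitrary units,
noise sd 5 (0.5% of baseline). Inhibition is modelled as negative
amplitude. Addition artefacts, photobleaching, GCaMP photophysics,
well-to-well crosstalk and cell biology are *not* simulated — so
passing recovery tests demonstrate the correctness of the quantification
chain, not robustness to every artefact of real plates.
`simulate_descriptor_panel()` likewise plants a known linear
descriptor–activity truth with controlled missingness.

Determinism is a contract: identical seeds and parameters give
bit-identical outputs, and the pipeline stages write a config hash into
every output header.

## Numerical and design choices

* Baseline window $[t_{add} - 30\,\mathrm{s}, t_{add})$, response window
  $(t_{end} - 10\,\mathrm{s}, t_{end}]$; half-open so the addition
  sample is not double-counted.
* Wells with $F \le 0$ or missing traces are excluded with a warning and
  logged; conditions with zero valid technical replicates are dropped,
  never imputed. No other QC rule is applied — none is published.
* Buffer-only control wells are processed and reported but not
  subtracted; no subtraction is described for the assay.
* Pooled-mean Hill fitting is the default; per-replicate fitting (fit
  each biological replicate, average the log EC50s) is available and is
  what the group comparisons consume. Whether the original analysis
  pooled or averaged is unstated; both are provided.
* Concentrations are molar, logs are base 10, and the censoring value
  $-2$ is read as $\log_{10}(\mathrm{EC}_{50}/\mathrm{M})$.

## Problem sizes

The bundled simulations are sized for quick, exact verification: the
default pipeline run uses an 8-ligand panel over 7 concentrations,
4 technical × 3 biological replicates (≈ 250 wells, 150 samples each);
recovery checks use 200 noisy refits; the null calibration of the
Dunnett procedure uses 1000 simulated experiments; the regression null
uses 1000 permutations at $n = 48$. These sizes give Monte-Carlo errors
comfortably below the tolerances they are checked against.

## A worked example

```{r example}
truth <- default_truth(noise_sd = 5)
truth$ligands

sim <- simulate_assay(truth, n_bio = 3, seed = 1)
meas <- process_traces(sim$traces, sim$plate_map)
fits <- fit_dose_response(meas)
as.data.frame(fits)

prof <- tuning_profile(fits, "WT")
prof
count_active(fits, "WT")$fraction
```

Caffeine is planted as a non-agonist (EC50 of 1 M, amplitude 0.05): its
responses are indistinguishable from noise, its activity index lands at
essentially zero, and the default agonist criterion excludes it — as it
excludes the inhibitor VUAA1, whose negative index is also zeroed inside
the sparseness calculation. On a noise-free run the same ligand is unfittable and is censored at
log EC50 = −2; under noise the
censoring rule only fires when the fit fails or the fitted EC50 leaves
the tested range, so near-zero junk fits are instead neutralized by the
index and the activity criterion.

## Known limitations

* The Hill fit assumes a monotone sigmoid; biphasic or bell-shaped
  dose–responses are out of scope.
* EC50s below the lowest tested concentration are not censored (the
  published convention only addresses the high side); such fits are
  ill-conditioned and should be read with care.
* The Brown–Forsythe branch compares each mutant to the control
  pairwise without further multiplicity adjustment, mirroring the
  published decision rule rather than extending it.
* Descriptor models are linear and low-dimensional by design; no
  regularization, cross-validation, or descriptor computation from
  structures.
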
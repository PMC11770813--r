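---
title: "Methods: tracer-based partition of glucose tolerance tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracer-based partition of glucose tolerance tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgtt)
```

## The measurement problem

An intraperitoneal glucose or insulin tolerance test performed with
[6,6-²H₂]glucose replaces the usual glucose bolus with a tracer carrying two
deuteriums at carbon 6. Every tracer molecule is two mass units heavier than
unlabelled glucose, so an LC-MS/MS measurement of the glucose isotopologue
envelope (M+0, M+1, M+2, ...) in a blood sample determines what fraction of
circulating glucose came from the injection (exogenous) versus from the body's
own production (endogenous, chiefly hepatic EGP). Three physiological facts
make the partition interpretable:

* tracer glucose taken up by tissue does not recirculate appreciably, so the
  labelled pool only ever shrinks after absorption completes;
* an IP glucose bolus at the modest dose used here does not provoke an insulin
  spike, so the GTT probes insulin-independent glucose handling;
* in the ITT, insulin and tracer are co-injected, so the same 50-min window
  reads out both insulin-stimulated uptake (labelled pool) and EGP
  suppression (unlabelled pool), while the co-injected glucose guards
  sensitive animals against severe hypoglycemia.

## Natural-abundance correction

Unlabelled glucose already shows M+1 and M+2 signal from natural ¹³C, ²H,
¹⁷O and ¹⁸O (for the default deprotonated ion C₆H₁₁O₆⁻, roughly 6.8% at M+1
and 1.4% at M+2 relative to M+0). Ignoring this background inflates apparent
enrichment, most visibly near t = 0 where true enrichment is zero. The
correction matrix has one column per labelled species: column *j* is the
expected envelope of the ion carrying *j* labels, computed by convolving the
per-atom isotope distributions of all atoms except the *j* labelled
hydrogens, then convolving with a Binomial(*j*, purity) term for the labels
themselves (a 99%-pure tracer leaves 2·0.99·0.01 of the doubly-labelled
species at M+1). Natural abundances are pinned constants (IUPAC 2013
representative values) so results do not drift with external tables; both
the abundances and the ion formula are overridable.

Numerical choices:

* **Truncation without renormalisation.** Envelopes are truncated at the
  largest measured shift K. Renormalising truncated columns would silently
  bias recovered fractions; instead the lost mass appears in the solver
  residual, which is reported per sample (`residual_norm`) and drives the
  `qc_flag` at a default relative threshold of 0.05.
* **Non-negative least squares** (`pracma::lsqnonneg`) rather than matrix
  inversion: with multiplicative area noise, inversion routinely yields
  negative fractions; NNLS keeps the solution physical and its residual
  doubles as the QC signal. Observed areas are normalised to sum 1 before
  solving so residuals are comparable across samples.
* **Clipping with provenance.** Enrichment is the corrected M+2 fraction
  clipped to [0, 1]; the raw value is retained (`enrichment_raw`) because a
  systematically negative raw value is diagnostic of a calibration problem
  that clipping would hide.
* An uncorrected mode (`correction = FALSE`, plain M+2/total ratio) is
  exposed for comparison with ratio-based workflows; the default is
  correction on.

The exact measured ion and any derivatisation vary between laboratories; the
default C₆H₁₁O₆⁻ is the common negative-mode choice for glucose quantitation
and is a configurable assumption of this package, not a fact about any
particular instrument method.

## Partition and AOC

With enrichment *e(t)* and glucometer total *G(t)*, the split is
definitional: exogenous = *G·e*, endogenous = *G·(1−e)*. Two conventions are
enforced deliberately:

* **No interpolation.** MS and glucometer samples come from the same tail
  bleed at the same nominal times; a timepoint present in only one source is
  flagged and dropped pairwise, a disjoint grid is an error. Interpolating
  would manufacture data precisely where a sample went missing.
* **Equal glucometer response** to labelled and unlabelled glucose: ²H₂
  substitution at C6 does not measurably alter glucose-oxidase chemistry.

Curves are summarised as the **signed** trapezoidal area of the
baseline-subtracted trace (AOC, mg/dL·min). The sign matters: in an ITT the
informative excursion is below baseline, and a positive-clamped AUC would
erase it. The exogenous curve uses a zero baseline (the t = 0 sample precedes
injection), which makes the three AOCs exactly additive
(total = exogenous + endogenous), a property the tests exploit. Unsorted
grids raise an error rather than being sorted, and fewer than two points is
an error. On the 6-point schedule the trapezoid is exact for piecewise-linear
curves and overestimates integrals of convex ones; the package reports the
trapezoid value because that is the convention for this assay, not as an
estimate of the true integral.

## Statistics

Each animal undergoes both tests a week apart, so the design is mixed:
diet/treatment group between animals, insulin (test mode) within animals. The
package fits a mixed-design two-way ANOVA per AOC outcome
(`aov(y ~ group * mode + Error(animal))`) and reports diet and insulin main
effects and their interaction. Pairwise cell contrasts use paired t-tests
within a group (same animals across modes) and Welch t-tests between groups,
Holm-adjusted, rendered as a compact letter display computed by
insert-and-absorb over the adjusted p-value matrix. Per-timepoint group
differences use Welch t-tests with Holm adjustment across the five
post-baseline timepoints. These choices (ANOVA flavour, post-hoc procedure)
are conventions of this package chosen to match the
main-effect/interaction/letters style of reporting; other reasonable
conventions exist, and α is configurable. Zero-variance cells (possible in
noiseless synthetic data) yield NA pairwise p-values rather than aborting a
report.

## The simulator

The generator exists so that every stage has ground truth. Per animal it
integrates, with `deSolve::lsoda` at rtol = atol = 1e-8 (the system is smooth
and non-stiff at these rates; truth and measurements are sampled from one
solve, so pipeline-vs-truth comparisons are not confounded by solver error):

* IP depot: `dD/dt = −ka_depot·D`, `D(0)` = 0.5 g/kg lean mass;
* labelled glucose: `dG_l/dt = ka_depot·D/V − (k0 + kI·A)·G_l` — no labelled
  inflow other than the depot (the no-recirculation assumption, which also
  makes the labelled trajectory provably independent of all EGP parameters);
* unlabelled glucose:
  `dG_u/dt = EGP0·exp(−sI·A − sG·(G_tot−Gb)) − (k0 + kI·A)·G_u`;
* insulin excess `A` (units of U/kg lean mass): zero in GTT mode (no
  secretion response to IP glucose is modelled), first-order absorbed and
  cleared bolus of 0.75 U/kg in ITT mode.

Uptake is driven by insulin **excess over basal**; with `EGP0 = k0·Gb` (the
default) the fasting state is then an exact fixed point, which the tests
verify. The exponential suppression form guarantees EGP stays positive
without clamping; any saturating positive form would satisfy the same
qualitative properties. Insulin lives in arbitrary units with a conversion
hook (`insulin_ugl_per_unit`) to the ELISA scale for the measured column,
since assay units vary between kits.

Defaults (per-minute rates; LFD-like / HFD-like presets):

| parameter | LFD | HFD | meaning |
|---|---|---|---|
| `Gb` (mg/dL) | 150 | 180 | fasting glucose (HFD hyperglycemia) |
| `k0` (/min) | 0.02 | 0.02 | basal fractional uptake |
| `kI` (/min per unit) | 0.15 | 0.08 | insulin-stimulated uptake |
| `sI` (per unit) | 6.0 | 3.5 | EGP suppression by insulin |
| `sG` (per mg/dL) | 0.0045 | 0.0015 | EGP suppression by glucose |
| `ka_depot` (/min) | 0.07 | 0.07 | IP absorption (peak ~15–20 min) |
| `Vd` (dL/kg lean) | 2.0 | 2.0 | distribution volume |
| `ka_ins`, `ke_ins` (/min) | 0.20, 0.04 | same | insulin bolus kinetics |

Presets were calibrated only to reproduce qualitative phenotype orderings at
cohort scale — HFD fasting hyperglycemia; greater HFD endogenous exposure in
the GTT; ITT total glucose tracking the endogenous, not the exogenous,
component; faster early EGP suppression in LFD; and a diet effect on GTT
endogenous AOC detectable at n = 14/15 — never to any measured curve. The
measurement model applies proportional Normal noise to glucometer readings
(CV 5%), multiplicative log-normal noise to MS areas (CV 5%, keeping areas
positive) and to ELISA insulin (CV 10%), and log-normal between-animal
variability (CV 12%, half that for `Gb`) on the kinetic parameters, with
`EGP0` re-derived per animal so each animal fasts at its own steady state.

What the generator does **not** emulate: counter-regulatory responses to
hypoglycemia, glucose effectiveness saturation, second-compartment glucose
kinetics, tracer recirculation (excluded by design), circadian or
stress-handling effects, glucometer quantisation, and chromatographic
interferences. Passing tests therefore demonstrate that the pipeline
correctly inverts its own measurement model and that the statistics hold
their nominal size under realistic noise — not that any particular biological
effect size in real animals is reproduced.

## Validation design and problem sizes

The test-suite checks run at sizes chosen to keep Monte Carlo error small
relative to the bands being checked: the correction round-trip uses 1,000
random compositions (tolerance 1e-8) and an exhaustive isotope-enumeration
oracle (1e-10); type-I error uses 400 replicate null cohorts of 10 animals
per cell, with the global null realised by sharing one preset across groups
and zeroing the ITT insulin dose (every factorial rejection rate must fall in
[0.02, 0.08] at α = 0.05); pattern reproduction uses 200 replicate cohorts at
n = 14/15; power for the GTT endogenous diet effect uses 200 GTT-only
replicates. Noiseless end-to-end recovery must match simulator truth to 1e-6
relative; partition conservation to 1e-9 relative.

## Known limitations

* The correction assumes unit-resolution isotopologue areas; fine isotope
  structure at high resolution is out of scope.
* Enrichment, not absolute tracer concentration, is the MS observable; the
  partition therefore inherits the glucometer's accuracy for totals.
* Rate-of-appearance/disappearance (Steele-style) modelling is deliberately
  absent: the assay's readouts are concentrations and AOCs.
* The compact letter display is a heuristic rendering of the pairwise test
  matrix; with many cells, minimal letter assignments are not unique.
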
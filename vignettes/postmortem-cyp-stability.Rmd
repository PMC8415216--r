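---
title: "Quantifying CYP abundance and postmortem stability with cypstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CYP abundance and postmortem stability with cypstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cypstab)
```

## The scientific problem

Physiologically based pharmacokinetic (PBPK) models need absolute hepatic
abundances of drug-metabolizing cytochrome P450 (CYP) enzymes. Postmortem
liver tissue collected at autopsy would dramatically widen access to such
data — if the CYP proteins survive the postmortem interval. cypstab
implements the computational chain of a stability study that addresses
this question in a porcine model: targeted LC–MS/MS quantification of four
CYP isoforms (CYP1A2, CYP2D25, CYP2E1, CYP3A29) in liver microsomes (PLM)
across storage at 4 °C and 21 °C, alongside probe-substrate enzyme
activity (phenacetin → paracetamol for CYP1A; midazolam →
alpha-hydroxymidazolam for CYP3A), method validation, and degradation
profiling.

Real raw data from such studies are rarely deposited, so the package is
built around a synthetic-data generator with known ground truth: every
downstream stage can be exercised, and its estimators validated, without
external data.

## The quantification model (AQUA)

Each CYP isoform is quantified through one proteotypic signature peptide
against a spiked, quantified stable-isotope-labelled internal-standard
(SIL-IS) peptide, chemically identical but mass-shifted (+10 Da labelled
Arg, +8 Da labelled Lys). With light (endogenous) and heavy (SIL-IS)
quantifier peak areas:

$$\mathrm{PAR} = \frac{A_\text{light}}{A_\text{heavy}}, \qquad
\text{pmol peptide} = \mathrm{PAR} \times \text{pmol SIL-IS}, \qquad
[\mathrm{CYP}] = \frac{\text{pmol peptide}}{\text{mg PLM}}.$$

`quantify_cyp()` applies these equations per injection and averages
technical replicate injections at the concentration level (the level of
averaging is a package choice; the arithmetic is linear, so averaging PAR
or concentration is equivalent for fixed digest mass). Concentrations come
from the quantifier peptide only; qualifier transitions, when present,
yield a QC area ratio and never enter the concentration. A missing or zero
heavy area is an error state (`missing_is`), not a zero concentration:
losing the internal standard invalidates isotope-dilution quantification.
A zero light area is a legitimate below-detection-limit zero.

Total microsomal protein is read off a Bradford/BSA standard curve
(`bradford_concentration()`, unweighted OLS with intercept — the
absorbance range of the assay is narrow, so weighting has no leverage),
and the microsomal protein per gram of liver (`compute_mppgl()`) is the
plain quotient of recovered protein over tissue mass, deliberately not
corrected for isolation losses.

## Method-validation statistics

* **Precision** (`precision_components()`): replicates grouped by
  run/day are decomposed by one-way ANOVA. The within-run variance is the
  pooled within-run mean square; the between-run variance is
  $\max\{0, (MS_B - MS_W)/n_0\}$ with $n_0$ the replicates per run
  (method-of-moments effective count for unbalanced designs, which are
  supported but flagged). Negative moment estimates clamp to zero —
  standard variance-components practice. "Total" CV is
  $\sqrt{\sigma^2_W + \sigma^2_B}$ over the grand mean; no day × replicate
  interaction term is modelled (a plain two-component model).
* **Trueness** (`trueness_percent()`):
  $100\,(\overline{x}_\text{spiked} - \overline{x}_\text{unspiked}) / \text{spike}$.
* **LOD/LLOQ** (`lod_lloq()`): 3× and 10× the sample SD of replicate
  low-level reactions per µg of digested protein. The SD pools all
  replicates regardless of day, reading "SD of the reactions" literally; a
  day-stratified pooled-SD alternative is exposed
  (`stratify_by_day = TRUE`). The LLOQ is computed as LOD × 10/3 so the
  definitional ratio is exact in floating point. The replicate CV is
  checked against the 20% acceptance bound; failures are flagged, not
  hidden. `one_point_calibration()` converts areas to fmol against the
  mean reference area of a known amount.

## Activity quantification

Calibrators are twofold serial dilutions from a top concentration
(`serial_dilution_levels()`; 15 levels from 20 µM end at 0.0012 µM after
rounding to 2 significant figures). `fit_calibration()` fits the
internal-standard response ratio against nominal concentration by weighted
least squares with $w_i = 1/x_i$ by default, excluding zero-concentration
points whose weight is undefined; 1/x weighting is the field's standard
for ranges spanning four orders of magnitude, where response variance
grows with concentration. Back-calculation
(`metabolite_concentration()`) inverts the line and applies the sample
dilution (15-fold here); negative back-calculated values — expected
low-end noise — floor to zero with a flag. The formation rate is

$$\text{rate} = \frac{c\,[\mu M] \times 1000}{t\,[\min] \times
\text{PLM}\,[\mathrm{mg/ml}]} \quad
\left[\tfrac{\text{pmol}}{\text{min} \cdot \text{mg}}\right],$$

using 1 µM ≡ 1 nmol/ml. Note one documented inconsistency in the source
material this models: reported rates of ~6000 pmol/min/mg over 20 min at
1 mg/ml imply ~120 µM product, above the 100 µM phenacetin substrate
concentration; the standard rate formula above is used as-is and the
discrepancy is not "fixed". Likewise a reported low calibrator of
0.0009 µM from 7.5 µM is consistent with 14, not 15, twofold dilutions
(15 give 0.00046 µM); the dilution operation is exact and generic.

## Degradation profiles and confidence intervals

For each analyte × temperature, `build_profile()` normalizes every
liver's series to its own t = 0 level, averages across livers per
timepoint, and attaches 95% CIs of the form

$$\bar{x}_t \pm t_{0.975,\,\nu}\; \frac{s_\text{pooled}}{\sqrt{n}},$$

where $s_\text{pooled}$ is the within-timepoint SD pooled across
timepoints under an equal-variance assumption and $\nu$ its degrees of
freedom. A Student t quantile is used rather than a normal one — the
conservative, standard choice for n = 2–3 livers. Two deliberate choices:

* **t = 0 groups are excluded from pooling by default.** Normalization
  pins every liver to exactly 1 at t = 0, so those groups carry zero
  within-group variance by construction; including them would add degrees
  of freedom without sums of squares and bias the pooled SD downward. The
  `include_t0_in_pooling` toggle restores them.
* **Liver exclusion is declarative.** Excluding a liver whose degradation
  profile differs (the demo config excludes liver 1 at 4 °C) is an
  explicit, recorded configuration choice — never an automatic outlier
  rule, for which there is no defensible criterion at n = 3.

`time_to_fraction()` summarizes a profile by the linearly interpolated
first downward crossing of a target fraction (e.g. the half-loss time);
first crossing wins on non-monotone noisy profiles, and profiles that
never cross return `NA`. `fit_decay_profile()` offers a parametric
alternative (least-squares lag + exponential). Pooling is per
(analyte, temperature); profiles at different temperatures never share an
SD. `compare_protein_vs_activity()` joins a protein and an activity
profile on shared timepoints to quantify how much more robust peptide
level quantification is than an assay requiring a functional enzyme.

## The synthetic-data generator

`simulate_quant_experiment()` emulates the degradation study from the
integrated-peak-area level down (no chromatograms or spectra are
simulated, and no bacterial/putrefaction mechanism is modelled). Its
generative model:

* **Decay**: each analyte × temperature follows a plateau of `lag_h`
  hours followed by first-order loss (`decay_fraction()`). The two
  parameters reproduce all qualitative patterns the study design probes —
  full stability at 4 °C up to ~96 h, protein stability for 24 h at 21 °C
  with ~50% loss at 48 h, earlier CYP3A29 onset, and the activity
  collapse between 24 and 48 h at 21 °C (lag ≈ 18.8 h, k ≈ 0.134 h⁻¹
  gives 50% at 24 h and ~2% at 48 h).
* **Noise**: three multiplicative layers — between-liver, between-run
  (one digest/run per liver × temperature × timepoint), within-run (per
  injection). Lognormal by default (peak areas are positive and
  right-skewed), parameterised so the realized CV equals the specification
  exactly ($\sigma^2 = \ln(1 + CV^2)$) and the mean is 1; a
  normal-multiplicative law is available. Defaults of 12% between-run and
  7% within-run CV sit in the range of the validated method's Table-2-style
  precision; the demo carries between-liver differences as deterministic
  per-liver scalings anchored to the reference t = 0 levels
  (`reference_liver_levels()`), so its expected liver means equal the
  reference values and `between_liver_cv` defaults to 0 there.
* **Heavy areas carry within-run noise only**: degradation happens in the
  tissue and biological/preparation variation affects the endogenous
  protein, whereas the SIL-IS peptide is spiked at digestion; the
  light/heavy ratio therefore carries exactly the liver, run and
  within-run draws of the light channel.
* **Design constants**: 70 µg PLM per digest, SIL-IS spikes of
  1000/1000/3000/1000 fmol for CYP1A2/CYP2D25/CYP2E1/CYP3A29, technical
  duplicate injections, timepoints 0–168 h (21 °C truncated at 72 h,
  where advanced putrefaction ends sampling in practice).
* **Trueness scale**: spikes of 10–50 fmol are only commensurate with the
  endogenous signature peptide at the injected (on-column) scale, so the
  demo validation stage represents the endogenous level as a 1/60
  injection fraction of the digest. At whole-digest scale (~1600 fmol
  endogenous CYP1A2 peptide) a 20 fmol spike could not be recovered at
  any realistic CV.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: chromatographic interferences and integration
error, matrix effects, sampling-site heterogeneity within a liver (folded
into between-run noise), non-exponential degradation kinetics, and any
correlation between protein and activity noise. Zero-noise closure and
Monte-Carlo recovery demonstrate the estimators are correct under the
stated model, not that the model exhausts real-data behaviour.

## Numerical choices and degenerate inputs

* Internal computation keeps full precision; report-style rounding (one
  decimal for pmol/mg and mg/g, two significant figures for rates) is
  applied only when formatting.
* `precision_components()` requires ≥ 2 replicates in some run; a single
  run yields a within-run CV with between-run/total `NA` (not estimable).
* `pooled_within_sd()` errors when no timepoint has ≥ 2 livers.
* Bradford and calibration fits error on fewer than two distinct
  x-values; Bradford inversions outside the standard absorbance range are
  flagged as extrapolated.
* `time_to_fraction()` ties break toward the earliest timepoint (exact
  hits return that timepoint; first crossing wins).
* All simulators are pure functions of (inputs, seed); `run_pipeline()`
  derives per-stage seeds by fixed offsets from the configured seed, and
  its manifest records output checksums.

## Problem sizes used by the shipped checks

The test-suite and acceptance checks use sizes chosen to make Monte-Carlo
error comfortably smaller than the tested tolerances while keeping the
default run short: 500 simulated 7-day × triplicate experiments for
CV-estimator recovery (±1 percentage point band), 1000 simulated
8-timepoint × 3-liver experiments for CI coverage (93.5–96.5% band), 200
simulated degradation experiments for half-loss-time recovery (median
relative error < 15%), and 100 random fixtures per oracle-equivalence
check (10⁻¹⁰ relative agreement).

## Known limitations

* The decay law is a two-parameter phenomenological stand-in; real
  degradation kinetics may be multi-phasic.
* The CI procedure assumes equal variance across timepoints on the
  relative scale; under strong decay with multiplicative noise this is an
  approximation (variance shrinks with the mean).
* Liver-specific degradation (one liver stable while others decline) is
  expressible only via the exclusion mechanism, not via per-liver decay
  parameters.
* MPPGL is uncorrected for isolation loss by design, so absolute values
  are method-conditional.
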
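# cypstab

Targeted quantification and postmortem stability analysis of cytochrome
P450 (CYP) enzymes in liver microsomes.

## What this is for

PBPK (physiologically based pharmacokinetic) modelling needs absolute
hepatic CYP abundances, and postmortem liver tissue taken at autopsy
could supply them for subpopulations that are otherwise inaccessible —
provided the proteins survive the postmortem interval. `cypstab`
implements the full computational chain of a porcine-model stability
study for forensic/DMPK scientists:

* **AQUA quantification** — absolute CYP isoform concentrations
  (pmol/mg microsomal protein) from light/heavy MRM peak areas against
  quantified stable-isotope-labelled internal-standard (SIL-IS) peptides,
* **MPPGL scaling** — microsomal protein per gram of liver from
  Bradford/BSA standard curves,
* **method validation** — within/between-run precision by one-way ANOVA
  variance components, spike-recovery trueness, replicate-SD LOD/LLOQ,
* **probe-substrate activity** — paracetamol and alpha-hydroxymidazolam
  formation rates via 1/x-weighted linear calibration,
* **degradation profiles** — per-liver relative-to-t0 trajectories with
  ANOVA-pooled 95% confidence intervals, interpolated half-loss times,
  and protein-vs-activity robustness comparison,
* **a hierarchical synthetic-data generator** (between-liver /
  between-run / within-run noise over lagged-exponential decay) so the
  whole pipeline is testable against known ground truth.

The core quantification model, per sample and isoform:

```
PAR  = A_light / A_heavy
pmol = PAR × pmol SIL-IS peptide
[CYP] (pmol/mg) = pmol / mg PLM digested
```

and the activity rate, from the back-calculated metabolite
concentration c (µM) in the reaction:

```
rate (pmol/min/mg) = c × 1000 / (t_min × PLM mg/ml)
```

## Worked example

Simulate a three-liver 21 °C series for CYP1A2 with half-loss 24 h after
a 24 h stable lag, quantify it, and profile the degradation:

```r
library(cypstab)

des <- experiment_design(livers = c("liver1", "liver2", "liver3"),
                         temperatures_C = 21,
                         timepoints_h = c(0, 2, 4, 6, 20, 24, 48, 72),
                         sil_spike_fmol = c(CYP1A2 = 1000))
dp <- decay_params("CYP1A2", baseline_level = 23.3, lag_h = 24,
                   decay_rate_per_h = log(2) / 24, temperature_C = 21)
nm <- noise_model(between_liver_cv = 0.15, between_run_cv = 0.12,
                  within_run_cv = 0.07)

sim <- simulate_quant_experiment(des, dp, nm, seed = 101)
quant <- quantify_cyp(sim$peak_areas, sim$samples, sim$transitions,
                      des$sil_spike_fmol)
profile <- build_profile(quant, "CYP1A2", 21)
profile
#> <stability_profile> CYP1A2 at 21 C (livers: liver1, liver2, liver3)
#>   pooled within-timepoint SD 0.1735 on 14 df
#> # A tibble: 8 × 5
#>   time_h     n mean_relative ci_low ci_high
#>    <dbl> <int>         <dbl>  <dbl>   <dbl>
#> 1      0     3         1     0.785    1.21
#> 2      2     3         1.17  0.953    1.38
#> 3      4     3         1.18  0.965    1.39
#> 4      6     3         1.19  0.973    1.40
#> 5     20     3         1.06  0.850    1.28
#> 6     24     3         1.20  0.984    1.41
#> 7     48     3         0.535 0.320    0.750
#> 8     72     3         0.285 0.0697   0.500

time_to_fraction(profile, 0.5)
#> [1] 51.38754
```

Reading this: each liver's concentrations are divided by its own t = 0
level, so `mean_relative` is the fraction of the nondegraded level
remaining (1.20 at 24 h is measurement noise around full stability; the
true curve is flat until 24 h). The 95% CIs use the within-timepoint SD
pooled across timepoints. The interpolated half-loss time of ~51 h is
close to the generating truth of 48 h (lag 24 h + one 24 h half-life).
`plot_stability_profile(profile)` draws the ribbon plot.

A full synthetic study — both temperatures, all four isoforms, MPPGL,
validation and activity — runs via the bundled configuration:

```r
res <- run_pipeline(demo_config(seed = 1), out_dir = "run1")
res$table1              # per-liver t = 0 levels (the Table-1 analogue)
res$validation_report   # precision / trueness / LOD / LLOQ per isoform
res$stability_summary   # remaining fractions and half-loss times
```

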
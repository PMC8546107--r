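# retimet

Analysis pipeline for **retinal oxygen metabolism and haemodynamics** in
three-group ocular cohort studies — the study design used to compare
multiple-sclerosis eyes with and without a history of optic neuritis
against healthy controls.

Imaging the retina is currently the most direct non-invasive window onto
central-nervous-system microcirculation and oxygen metabolism. This
package implements, as tested and reusable R code, the full measurement
model of such a study:

* **Doppler OCT velocimetry and flow.** Dual-beam phase differences are
  converted to absolute blood velocity,
  `V = |ΔΦ·λ / (4π·n·τ·Δα·cos β)|`, per-vessel volumetric flow
  `Q = (D²/4)·π·V` (µl/min), and total retinal blood flow (TRBF) as the
  mean of the arterial and venous sums over all vessels ≥ 40 µm.
* **Oxygen extraction model.** Distance-corrected vessel saturations are
  combined into central-vessel saturations (flow-weighted on the venous
  side), converted to oxygen contents — haemoglobin-bound plus
  plasma-dissolved via an inverted Hill curve — and folded into
  `extO2 = (cO2,CRA − cO2,CRV) · Q` (µl O₂/min).
* **Knudtson vessel equivalents.** CRAE/CRVE by iterative
  largest-with-smallest pairing of the six largest calibers
  (k = 0.88 arteries / 0.95 veins), and the arterio-venous ratio.
* **OCTA densities.** Multiscale Hessian (Frangi-type) large-vessel
  detection on en-face angiograms, a 2.5–4 mm annular peripapillary ROI,
  and mean-value binarization capillary / large-vessel densities.
* **Structural summaries.** Global circumpapillary RNFL thickness and
  ETDRS inner-quadrant GCIPL.
* **Cohort statistics.** One-way ANOVA per metric, Levene's test, gated
  planned pairwise contrasts (pooled or Welch), Pearson correlations.
* **Synthetic cohorts with ground truth.** A generator reproducing the
  statistical structure of the study (group-shifted flows, saturations,
  calibers, capillary fractions; mass-conserving vasculature; angiogram
  phantoms with known vessel masks), so every stage is testable against
  known truth.

See `vignettes/retinal-oxygen-metabolism.Rmd` for the models, parameter
defaults, and design decisions.

## Worked example

Simulate a miniature cohort (6 eyes per group), run the full analysis,
and look at oxygen extraction:

```r
library(retimet)
cohort <- generate_cohort(cohort_config(n_per_group = c(6, 6, 6)),
                          seed = 42)
res <- run_study(cohort)
print(res)
#> Study result: 18 eyes analysed, 0 quarantined
#> Omnibus ANOVA:
#>   trbf         F =   0.833, p = 0.4538
#>   ext_o2       F =   4.039, p = 0.03952
#>   crae         F =   9.081, p = 0.002605
#>   ...

res$group_summary[res$group_summary$metric == "ext_o2", ]
#>   metric   group n     mean        sd
#> 4 ext_o2   MS_ON 6 2.272898 0.5289490
#> 5 ext_o2 MS_noON 6 2.802660 0.5082228
#> 6 ext_o2 healthy 6 3.203858 0.6586058

res$tests[res$tests$metric == "ext_o2", ]
#>   metric                        test  statistic    p_value
#> 3 ext_o2                       anova  4.0386201 0.03951895
#> 4 ext_o2                      levene  0.5483144 0.58907758
#> 5 ext_o2   contrast_MS_ON_vs_MS_noON -1.7690278 0.10732157
#> 6 ext_o2   contrast_MS_ON_vs_healthy -2.6995737 0.02232970
#> 7 ext_o2 contrast_MS_noON_vs_healthy -1.1813129 0.26481038
```

Oxygen extraction is lowest in the optic-neuritis eyes (2.27 µl O₂/min),
intermediate in the fellow eyes, highest in controls; the omnibus ANOVA
is significant, so the three planned contrasts are computed (pooled
variance here, since Levene's test is non-significant), and only
MS+ON vs healthy reaches significance at this miniature sample size.
Eyes whose analysis fails are quarantined with a logged reason, not
silently dropped or imputed.

The individual stages are exported directly, e.g.

```r
k <- doct_constants(wavelength_m = 8e-7, tau_s = 1e-4, n_blood = 1.35,
                    dalpha_rad = 0.01, beta_deg = 0)
v <- doppler_velocity(0.5, k)   # 0.02357851 m/s
vessel_flow(100, v)             # 11.11111 ul/min for a 100-um vessel
```

## The analysis workflow

`analysis/` contains the numbered drivers of the end-to-end study on a
synthetic cohort, writing all tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # cohort + angiograms -> results/study/
Rscript analysis/02_analyze_cohort.R  # per-eye metrics, group stats -> results/analysis/
Rscript analysis/03_correlations.R    # haemodynamics vs structure, normality advisory
```

Outputs: `per_eye_metrics.csv`, `group_summary.csv`, `tests.csv`,
`quarantine.csv`, `correlations.csv` (floats at 6 significant digits).

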
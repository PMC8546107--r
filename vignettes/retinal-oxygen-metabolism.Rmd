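---
title: "Retinal oxygen metabolism and haemodynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retinal oxygen metabolism and haemodynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retimet)
```

This vignette documents the science implemented in `retimet`: the models,
their assumptions, the tunable parameters, and the design choices made
where the published analysis conventions leave latitude. The package
targets cross-sectional ocular cohort studies that combine dual-beam
Doppler OCT blood-flow measurements, reflectometric vessel oximetry,
fundus-based vessel calibers, en-face OCT angiography, and structural OCT,
compared across three groups (here labelled `MS_ON`, `MS_noON`,
`healthy`, after the motivating application to multiple sclerosis with
and without optic neuritis).

## Doppler velocimetry and total retinal blood flow

A dual-beam Doppler OCT system probes one retinal spot with two beams
separated by a small angle $\Delta\alpha$. Moving blood cells imprint
different phase shifts on the two beams; their difference $\Delta\Phi$
relates to absolute velocity by

$$V_{abs} = \left|\frac{\Delta\Phi\,\lambda}
  {4\pi\, n\, \tau\, \Delta\alpha\, \cos\beta}\right|,$$

with $\lambda$ the source centre wavelength, $\tau$ the interval between
the two recordings, $n$ the group refractive index of blood and $\beta$
the angle between the detection plane and the velocity vector. The sign
of $\Delta\Phi$ encodes flow direction relative to the detection plane;
since flows are summed by vessel kind, the absolute value is taken per
vessel. The equation is singular at $\beta = 90°$; `doct_constants()`
enforces a configurable floor on $|\cos\beta|$ (default 0.05) and raises
a hard error below it rather than returning an ill-conditioned velocity.

Phase series covering at least one cardiac cycle are averaged over the
largest whole number of cycles that fits the recording when a pulse-period
hint is available (`average_phase()`); a partially sampled final cycle
would otherwise bias the systolic/diastolic balance. Without a hint the
full series is used.

Per-vessel volumetric flow assumes a circular lumen,
$Q = \tfrac{D^2}{4}\pi V_{abs}$, reported in µl/min. Vessels narrower
than 40 µm are excluded from flow totals (strictly below; a vessel at
exactly 40 µm is kept), mirroring the caliper threshold of the
measurement protocol. Arterial and venous totals are summed separately
and total retinal blood flow (TRBF) is their mean — on a closed
circulation the two totals estimate the same quantity, and averaging
halves independent measurement error.

The device constants are not universal: the defaults in
`doct_constants()` (840 nm, 25 µs, $n$ = 1.38, 9.5 mrad, $\beta$ = 65°)
describe a plausible instrument of this class and exist so the synthetic
pipeline is self-consistent; an analysis of real recordings must supply
the instrument's own values via `read_constants_config()`. A per-vessel
`beta_deg` column overrides the global angle where vessel geometry was
measured individually.

## Oximetry and the oxygen-extraction model

Reflectometric oximetry yields a saturation per measured vessel. The
model folds these into central-vessel saturations:

* each measured saturation may be corrected linearly for the distance
  between its measurement point and the central-vessel trunk
  (`correct_saturation()`); the coefficient defaults to 0 — the stage is
  present and testable, but no correction is applied unless a study
  supplies a slope — and results are clamped to $[0, 1]$;
* the central retinal artery saturation is the unweighted mean of the
  corrected arterial values (arterial blood is distributed, not mixed);
* the central retinal vein saturation is the flow-weighted mean
  $\sum_i Q_i S_i / \sum_i Q_i$ of the corrected venous values, because
  CRV blood is the mixture of all merging veins.

Oxygen content per mL of blood combines haemoglobin-bound and
plasma-dissolved oxygen:

$$cO_2 = \big(c_{Hb}\, h\, S + \alpha\, pO_2(S)\big) / 100,$$

with $c_{Hb}$ the haemoglobin concentration (default 15 g/dL), $h$ the
Hüfner number (1.34 mL O₂/g), and $\alpha$ the plasma solubility
(0.0031 mL O₂/dL/mmHg). The oxygen tension is recovered from saturation
by inverting the Hill dissociation curve,
$pO_2 = p_{50}\,(S/(1-S))^{1/n}$ with $p_{50} = 26.6$ mmHg and
$n = 2.7$, capped at 100 mmHg (the inverse diverges as $S \to 1$, and
the dissolved fraction above arterial tension is negligible) and set to
0 at $S = 0$. These are standard adult human values; all are
configuration in `oxygen_model_params()` and the tests exercise the
model at explicit parameter values so results are not constant-dependent.
Note the cap does not bind at typical arterial saturations: at
$S = 0.95$ the inverse gives $pO_2 \approx 79$ mmHg.

Retinal oxygen extraction is the arteriovenous content difference times
flow, $extO_2 = (cO_{2,CRA} - cO_{2,CRV})\, Q$, with $Q$ the TRBF
defined above (the mean of the arterial and venous totals). It is
antisymmetric in the two contents and linear in $Q$.

## Vessel equivalents

Central retinal artery and vein equivalents follow the revised Knudtson
"big six" scheme: the six largest calibers are paired iteratively —
largest with smallest — each pair combining as
$k\sqrt{w_1^2 + w_2^2}$ with $k = 0.88$ for arteries and $0.95$ for
veins; an unpaired middle width carries over unchanged, and rounds repeat
until one value remains. When fewer than six vessels are supplied all are
used, with a warning, since the scheme's constants were calibrated on
six. The arterio-venous ratio is CRAE/CRVE.

## OCTA densities

Large vessels are separated from the capillary bed on the en-face
angiogram with a multiscale Hessian (Frangi-type) vesselness filter:
at each scale $\sigma$ the image is convolved with scale-normalised
Gaussian second-derivative kernels, the Hessian eigenvalues
$|\lambda_1| \le |\lambda_2|$ form a tubularity measure
$\exp(-R_b^2/2b^2)\,(1 - \exp(-S^2/2c^2))$ for bright structures
($\lambda_2 < 0$), with $R_b = \lambda_1/\lambda_2$,
$S^2 = \lambda_1^2 + \lambda_2^2$, $b = 0.5$ and $c$ set adaptively to
half the maximal Hessian norm per scale. Responses are maximised over
scales, thresholded at a fraction of the image-wide maximum (default
0.15), and dilated by 1 px to close the thin boundary sliver the
threshold misses. The default scales $\sigma \in \{3,4,5,6\}$ px target
vessel calibers of roughly 6–14 px on a 384-px, ~4.4 mm scan. The
threshold, dilation radius and scales are parameters; the defaults were
fixed on synthetic phantoms with known masks before being frozen, and
every test passes them explicitly.

Densities are evaluated in a ring-shaped region of interest centred on
the optic disc (default inner/outer diameters 2.5/4.0 mm), membership
half-open in radius, distances measured between pixel centres, 1-based
matrix indexing. In capillary mode the large-vessel mask is removed from
the ROI; in large-vessel mode the inverted mask removes the capillaries.
The remaining pixels are binarized at their own mean (computed within
the remaining ROI only, which makes the measure invariant under affine
intensity rescaling); a pixel exactly at the mean counts as white, so a
constant region has density 100%. Density is the percentage of white
pixels among the remaining pixels — note this makes large-vessel density
a *within-compartment* percentage; conventions that divide by all ring
pixels produce much smaller LVD numbers, so LVD scales are not
comparable across conventions.

## Structural summaries

Global RNFLT is the unweighted mean of the circumpapillary ring-scan
thickness profile. GCIPL is the sum of the averaged GCL and averaged IPL
thicknesses over the four inner (3 mm) ETDRS quadrants. Layer
segmentation itself is consumed as input, not computed.

## Cohort statistics

Each metric is compared across the three groups with a fixed-effects
one-way ANOVA ($F$ on $(k-1, N-k)$ df). Planned pairwise contrasts are
computed only for metrics whose omnibus test is significant (strictly
below $\alpha = 0.05$). Levene's test (ANOVA on absolute deviations from
the group mean) is run before the contrasts; the published design does
not state its consequence, so the package adopts the only sensible
reading: pooled-variance contrasts when Levene's $p \ge 0.05$, Welch
otherwise. No multiple-testing correction is applied to the three
planned contrasts (raw p-values are reported, as in the study design).
A Kolmogorov–Smirnov normality check is available as an advisory report
only; no branch depends on it. Standard implementations are used
throughout (`oneway.test`, `t.test`, `cor.test`); the test suite checks
them against hand-written sums-of-squares oracles and, for Levene's
test, against an independent implementation.

## The synthetic cohort generator

Because the study's patient-level data are not available, the package
ships a generator (`generate_cohort()`) that emulates the *statistical
structure* the analysis assumes, with ground truth recorded for every
derived quantity:

* three groups with 16/16/18 eyes by default;
* per-eye TRBF drawn from the groups' published distributions
  (33.2 ± 6.0, 38.3 ± 4.6, 37.2 ± 4.7 µl/min);
* 6–8 arteries and veins per eye; lognormal calibers with group-shifted
  medians chosen so the Knudtson equivalents land in the published
  ranges; arterial velocities rescaled so arterial flow totals the eye's
  TRBF; venous calibers rescaled ($\sqrt{\text{flow ratio}}$) so venous
  outflow equals arterial inflow exactly — mass conservation holds
  before noise;
* arterial saturations near 0.95; venous saturations group-shifted
  (0.60/0.57/0.55), the chief carrier of the extraction effect;
* ground truth computed by running the package's own equations on the
  noise-free observables, after which additive Gaussian measurement
  noise (diameter SD 2 µm, phase SD 5×10⁻⁴ rad, saturation SD 0.02) is
  applied to the recorded observables;
* angiogram phantoms: a binary speckle background whose bright-pixel
  fraction equals the eye's capillary fraction (group-shifted
  0.46/0.49/0.52), overlaid with bright meandering tubes whose support
  is the true large-vessel mask. The speckle levels (0.20/0.50) and
  intensity noise (SD 0.12) are deliberately close enough to overlap:
  real capillary-bed reflectance is continuous, and mean-value
  binarization only behaves realistically (removing a bright vessel
  *raises* capillary density by lowering the threshold) when the
  intensity distribution has mass near the threshold. With the published
  venous saturations, generated extractions (~2.4–3.0 µl O₂/min) sit
  somewhat above the published 1.8–2.3 — the study's measured
  arteriovenous saturation gap was evidently narrower than the round
  defaults — but every group *ordering* reproduces.

All randomness flows from one seed; equal seeds give bit-identical
cohorts.

What the generator does **not** emulate: spatial correlation of real
speckle, projection and motion artifacts, vessel branching geometry,
segmentation errors in the consumed layer thicknesses, eye-level
correlation between modalities (each modality's group shift is drawn
independently), and between-eye correlation within a patient (the two
MS eyes are generated independently). Passing tests therefore
demonstrate internal consistency and correct implementation of the
models at the study's design conditions — not agreement with any real
instrument's error structure.

## Numerical and simulation-scale choices

* Velocities: absolute value per vessel; the caliper filter is strict at
  40 µm; the $\cos\beta$ floor errors rather than extrapolates.
* Saturation corrections are clamped to $[0,1]$; the Hill inverse is
  capped at 100 mmHg.
* Binarization ties count as white (deterministic, documented boundary).
* Flat angiograms give an empty vessel mask, not an error; an ROI left
  empty after compartment removal is an error.
* Eyes whose analysis fails inside `run_study()` are quarantined with a
  logged reason and excluded from summaries rather than imputed.
* Simulation sizes: oracle-equivalence checks run 100 random instances
  per operation; recovery and conservation checks use 200–300 eyes per
  condition; null calibration of the ANOVA uses 2000 replicates at group
  sizes 16/16/18; ordering checks use 500 eyes per group, with the
  density stage isolated by ground-truth vessel removal at that scale
  and a 30-per-group companion running the full Hessian detector
  end-to-end. These sizes give stable medians and rates while keeping
  the whole suite fast on a single CPU.

## A worked miniature

```{r example}
cohort <- generate_cohort(cohort_config(n_per_group = c(6, 6, 6)),
                          seed = 42)
res <- run_study(cohort)
res$group_summary[res$group_summary$metric %in% c("trbf", "ext_o2"), ]
res$tests[res$tests$metric == "ext_o2", ]
```

## Known limitations

* The raw reflectometric estimation of saturation from dual-wavelength
  fundus images is out of scope; saturations are consumed as inputs.
* The Hessian filter variant and parameters used by any given study's
  software are generally unrecoverable from publications; numeric
  equality of CD/LVD with a specific instrument pipeline is not claimed,
  only the behaviour of the method class.
* The distance-correction slope for saturations defaults to 0 because no
  functional form is published; supplying a nonzero slope changes
  central saturations and hence extraction.
* LVD is a within-compartment percentage (see above).
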
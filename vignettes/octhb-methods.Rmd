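---
title: "Quantifying the outer-retina hyporeflective band and its light–dark physiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the outer-retina hyporeflective band and its light–dark physiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octhb)
```

## The measurement problem

On log-intensity OCT B-scans of the retina, a hyporeflective band (HB)
appears between the photoreceptor outer-segment tip (PRT) reflective layer
and the apical retinal pigment epithelium (RPE). Its prominence depends on
light adaptation, and — together with the thickness of the ELM-to-RPE
span, an established readout of subretinal-space hydration — it behaves
like a functional biomarker of photoreceptor mitochondrial respiration.
`octhb` implements the full measurement and inference chain for this
biology: profile-based quantification of the two OCT indices from B-scans,
amplitude extraction from step-response electroretinograms (ERG), peak
phalloidin/F-actin fluorescence at the HB region, and the Bayesian
hierarchical models that turn per-mouse light–dark differences into
group-level estimates with percentile credibility intervals.

All stages are exercised against a synthetic-data module with recorded
ground truth, so the package is fully testable without access to animal
data.

## HB magnitude, HB width, ELM-RPE thickness

An averaged transretinal intensity profile is built per eye:

1. A-scan columns whose lateral distance from the optic nerve head is
   350–630 µm (both sides) are extracted; with 1.4 µm lateral sampling this
   is 250–450 px from the ONH center.
2. Columns are averaged in bins of 10.
3. Binned profiles are aligned at their ELM peaks by integer-sample shifts
   and averaged; the four radial scans of an eye are aligned and averaged
   the same way. Integer shifts avoid interpolation artifacts; averaging is
   restricted to the common support.

On the averaged profile, the ELM is the tallest local maximum in a window
vitreal of the RPE anchor (the most scleral sample reaching 90% of the
profile maximum); IS/ep, PRT and RPE peaks are the tallest local maxima in
windows sclerad of the ELM (defaults 4–24, 24–45, 40–75 µm; equal-height
ties resolve to the most vitreal index). The HB baseline is the straight
chord joining the PRT and RPE peak intensities. Then

* **HB magnitude** = maximum of (baseline − profile) over the interior of
  the chord, floored at 0, in grayscale units of the 8-bit log-intensity
  image. Because the axial grid (1.6 µm default) undersamples a trough only
  a few µm wide, the sample maximum is refined by a three-point parabola;
  without this the raw maximum is biased low by up to ~1 grayscale unit
  depending on grid phase.
* **HB width** = distance in µm between the two half-maximum crossings of
  the deviation curve flanking its peak, located by linear interpolation
  between adjacent samples. A crossing that runs off the chord interval is
  truncated at the interval edge and flagged.
* **ELM-RPE thickness** = distance from the ELM peak to the basal RPE
  boundary. The basal boundary is not defined by the instrument, so the
  package uses the half-height crossing on the scleral RPE flank above the
  distal background floor (median of the 20 most scleral samples), with
  sub-pixel interpolation; this is testable and calibration-independent.

Quantification operates directly on the log-scaled 8-bit intensities as
exported; no delogging is attempted, since the literature's units are
grayscale units of such images. Axial index 0 is the most vitreal row;
human scans without an ONH reference are first flattened to the RPE
(per-column translation to the median RPE row) and measured the same way.

## The phantom: what it emulates and what it does not

`generate_bscan()` renders a layered phantom: nine Gaussian reflectivity
bands (NFL through RPE) on a background floor, with the region between the
PRT and RPE peaks bridged by the straight chord and a Gaussian trough of
depth `hb_depth_drop` and FWHM `hb_width_um` subtracted. This geometry is
deliberate: the deviation from the measured baseline is then exactly the
trough Gaussian, so magnitude and width have closed-form ground truth
(`2σ√(2 ln 2)` for the width). The PRT and RPE amplitudes are equal, which
keeps the chord flat and both endpoints genuine local maxima; real mouse
profiles have a brighter RPE, but a tilted straight chord would swallow
the PRT peak entirely and is a phantom artifact, not a property of real
data. Recorded truth is computed on a grid 8× finer than the pixel grid
with the same operational definitions as the measurement path.

The dark-adapted state multiplies the trough depth by 0.2 and shrinks all
outer-retina offsets from the ELM by 10% — a reduced band, not a different
layer set, because the literature reports magnitude reduction rather than
band disappearance. Both factors are configurable; the true dark-state
trough shape is unknown and the ×0.2 default is a stand-in, not a claim.
Light-state trough depths of scientific interest span 5.6–12.7 grayscale
units. Default calibration is 1.6 µm/px axial (theoretical axial
resolution in tissue) and 1.4 µm/px lateral (1.4 mm scans at 1000
A-scans). Radial scans receive independent noise and independent global
axial shifts of up to 3 px to exercise ELM alignment.

Not emulated: speckle statistics, vascular shadows, eye-motion artifacts
beyond the global shift, lateral tissue structure. Passing the phantom
suite therefore demonstrates correctness of the measurement geometry and
its noise robustness, not performance on pathological clinical scans.
In-memory phantoms keep continuous intensities; only the TIFF writer
quantizes to 8-bit, so oracle checks are not polluted by quantization.

## ERG and F-actin quantification

Synthetic step-response ERGs are a baseline plus three components with
disjoint temporal support: an a-trough (0.02–0.14 s post-onset), a b-peak
(0.2–0.9 s) and a slow c-dome (2–6 s, peaking at 4 s — within the 3–5 s
window typical of the RPE/Müller-driven response to a 10-s step).
Raised-cosine shapes with disjoint support make the trough-to-peak
conventions exact: a = baseline to a-window minimum, b = a-trough to
b-window maximum, c = baseline to c-window maximum, each floored at 0 with
a flag. The a-window (0–0.3 s) and c-window (2–6 s) are configuration,
since published protocols state only the c-window approximately.
Amplitude–intensity functions are polynomials in log10 intensity over
0.01–1000 cd/m²; treatment scales the c-wave by 1.10 (a ~10% increase) by
default.

F-actin depth profiles are bimodal (apical peak at the HB region, basal
peak), with peak heights following group + side + interaction structure
plus mouse random intercepts. `factin_peak_at_hb()` reports the raw window
maximum by default — background subtraction is implemented but off, since
published peak fluorescence is raw; the flag exists because session
offsets are common in practice. The HB window depth bounds are required
configuration: published work does not state them.

## The Bayesian models

All models are fitted by MCMC in JAGS with seeded chains. Defaults follow
the convention of 4 chains × 30,000 iterations thinned by 5, discarding
the first half as warmup; the estimand, not the engine, is the contract,
so any sampler satisfying split-R̂ < 1.01 and adequate ESS at full
settings is equivalent, and reduced settings are used for simulation
studies. "Diffuse" priors are concretized adaptively: normal(0, 100·MAD)
for locations, half-Cauchy(5·MAD) for SDs, all overridable.

**Group hierarchy (one trait).** Observations normal around group means,
group means normal around an overall mean with its own diffuse prior,
half-Cauchy on both SDs. Per-group responses are also summarized
descriptively as mean/SD of the within-group light–dark differences
(`normalize_by_group_sd()`); whether that normalization should use the SD
of differences or of raw values is ambiguous in the source material — the
package uses differences, and the choice is isolated in one function.

**Joint bivariate hierarchy.** Per-mouse light–dark differences
(ELM-RPE, HB) are bivariate normal within group; group mean vectors are
bivariate normal around the overall mean with between-group correlation
`r_mu` carrying a beta(0.5, 0.5) prior on (r+1)/2. Within-group variances
are lognormal with Cauchy hyperpriors on their location and scale;
within-group correlations are beta-distributed (mean/variance
parameterization) around an overall correlation with a uniform(0, bound)
prior on the dispersion. The bivariate normals are factorized into
conditional univariate normals — algebraically identical to a triangular
(Cholesky) factorization of the covariance and an order of magnitude
faster in JAGS than matrix-variate nodes. Correlations enter as
r = 0.9999·(2z − 1), the slight shrinkage keeping conditional variances
positive when the posterior piles up near |r| = 1 (which it does when the
true correlation is 0.975). `r_mu` is also reported as a regression slope,
r_mu·σ_HB/σ_ELM-RPE, for correlation scatter plots.

**Drug mixed model.** Light–dark changes in both traits across paired
control/treated sessions, with fixed effects intercept, treatment,
drug-group (ACZ reference, DNP 5 and 10 mg/kg) and treatment×group, plus
bivariate mouse random intercepts and bivariate residuals. The "control"
rows are each mouse's pre-treatment vehicle session, matching the
repeated-measures design the random intercept implies. The normalized drug
response (Ỹ_drug − Ỹ_control)/Ỹ_control is computed per draw from the
model-implied means; −1 is complete elimination. Draws whose control mean
crosses zero are flagged, and the functional aborts if they exceed 1% —
a ratio with a sign-ambiguous denominator is not interpretable.

**F-actin model.** Group, side, group×side and a mouse-within-group
random intercept; group differences are per-draw contrasts of fitted cell
means.

**ERG intensity–response models.** Per wave, candidate polynomials of
degree 1–3 in centered log10 intensity with a drug main effect and
drug×term interactions and a mouse random intercept. Candidates use an
orthogonal polynomial basis — the same span as raw powers, but far better
conditioned for Gibbs sampling. WAIC and PSIS-LOO (with Pareto-k
diagnostics; smoothing by a Zhang–Stephens generalized-Pareto fit) are
computed for every candidate; a higher degree is adopted only when it
improves the criterion by at least 4, mirroring the convention of
preferring the simpler model for small improvements. If more than 10% of
Pareto-k values exceed 0.7 the selection falls back to WAIC.

All intervals are empirical percentile intervals (type-7 interpolation of
order statistics); "significant" means the 95% interval excludes zero. No
multiplicity adjustment is applied beyond that convention. Location
parameters are point-summarized by the posterior mean; bounded correlation
parameters by the posterior median, since their posteriors pile up against
±1 and skew the mean away from the central tendency.

## Numerical and design choices

* Seeds: one master integer; every stage derives a child seed by hashing
  the master with a stage label (`derive_seed()`), so streams are stable
  under pipeline reordering. All child seeds stay below 2³¹.
* Convergence gate: fits check split-R̂ on their headline parameters
  against 1.05 and warn by default (`on_nonconvergence = "error"`
  upgrades to an error). At reduced simulation settings a skewed
  boundary-concentrated posterior (r_mu near 1) can show R̂ ≈ 1.05–1.10
  while its interval is perfectly usable, which is why warn is the
  default; production fits at full settings should use the error gate.
* Degenerate inputs: monotone profiles (no landmarks), zero-magnitude HB
  (width undefined by construction), zero within-group SD, unpaired
  sessions and ill-defined response ratios all fail with named errors
  rather than returning numbers.
* Recovery-study sizes: the simulation studies in the tests use the study
  group sizes (8 groups of 4, 4, 5, 6, 10, 8, 6, 5 for the joint model;
  10/6/5 for the drug arms; 5 + 5 for ERG), 20 replicates for coverage
  statements, 5 replicates averaged for point-recovery of the normalized
  drug response, and 200 ranks for simulation-based calibration of the
  group model at reduced sizes. Calibration is run for the group model
  only; the other fitters share the same machinery and are covered by
  coverage/recovery checks instead.

## Limitations

The phantom's flat chord and Gaussian trough are an idealization; real
baselines tilt, and the operational chord definition then measures a
slightly different quantity than any "true" trough depth — on real data
the indices are comparative biomarkers, not absolute physical depths.
The ELM detector assumes the outer-retina geometry of the configured
windows; grossly abnormal retinas need window reconfiguration. ERG
component shapes are stylized (disjoint supports); real a/b waves overlap,
so exactness statements apply to the synthetic traces only. PSIS-LOO uses
a self-contained implementation of the generalized-Pareto smoothing;
diagnostics above k = 0.7 should be taken as "refit or use WAIC", not
smoothed away.
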
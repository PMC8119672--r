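# octhb

Quantification and hierarchical Bayesian modeling of the outer-retina
**hyporeflective band (HB)** on OCT images.

On log-intensity OCT B-scans, a hyporeflective band sits between the
photoreceptor outer-segment tips (PRT) and the apical retinal pigment
epithelium (RPE). Its prominence changes with light adaptation, in parallel
with the thickness of the ELM-to-RPE span — a readout of subretinal-space
hydration driven by photoreceptor mitochondrial respiration. `octhb` is for
vision scientists who want to measure these two functional OCT biomarkers
and model their light–dark physiology:

* **OCT quantification** — transretinal intensity profiles from B-scans
  (ROI extraction 350–630 µm from the optic nerve head, lateral binning,
  ELM-peak alignment, radial-scan averaging), then three indices per eye:

  - *HB magnitude*: peak deviation below the baseline chord joining the
    PRT and RPE intensity maxima (grayscale units),
  - *HB width*: distance between the half-maximum points of that deviation
    (µm),
  - *ELM-RPE thickness*: ELM peak to the basal RPE half-height boundary
    (µm).

  A human-scan mode flattens images to the RPE band before measurement.
* **ERG analysis** — a-, b- and c-wave amplitudes from 10-s step-response
  electroretinograms (baseline-to-trough, trough-to-peak, baseline-to-dome
  conventions).
* **F-actin analysis** — peak phalloidin fluorescence at the HB region of
  depth-intensity profiles.
* **Bayesian models (JAGS)** — per-group hierarchical light–dark
  responses; a joint bivariate hierarchical model whose headline estimand
  is the between-group correlation r<sub>µ</sub> of the two traits' mean
  light–dark differences (beta(0.5, 0.5) prior on (r+1)/2, lognormal
  within-group variance hierarchy); a bivariate drug-effect mixed model
  (treatment × drug-group fixed effects, bivariate mouse intercepts) with
  the scale-free **normalized drug response**
  (Ỹ<sub>drug</sub> − Ỹ<sub>control</sub>)/Ỹ<sub>control</sub> computed per
  posterior draw (−1 = complete elimination of the light–dark response);
  an F-actin group × side model; and polynomial ERG intensity–response
  models selected by WAIC/PSIS-LOO with a "simpler unless it improves the
  criterion by ≥ 4" rule. All summaries are 95% percentile credibility
  intervals; "significant" means the interval excludes zero.
* **Synthetic data** — layered retinal B-scan phantoms with closed-form
  ground truth for all three indices, hierarchical bivariate cohorts,
  paired drug cohorts, ERG waveforms and F-actin profiles, so the entire
  pipeline is testable without animal data. Every generator is
  bit-reproducible from one integer seed.

## Worked example

Measure a light/dark pair of phantom eyes and fit the joint model to a
simulated eight-group cohort:

```r
library(octhb)

p <- phantom_params(hb_depth_drop = 10, noise_sd = 2, seed = 42)
light <- quantify_eye(generate_radial_set(p, "light", subject_id = "m1"))
dark  <- quantify_eye(generate_radial_set(p, "dark",  subject_id = "m1"))
rbind(light, dark)[, c("state", "hb_magnitude", "hb_width_um", "elm_rpe_um")]
#>   state hb_magnitude hb_width_um elm_rpe_um
#> 1 light     9.749562    6.913891   56.44098
#> 2  dark     1.767581    6.427037   51.15630
```

The light-adapted eye shows an HB ~9.7 grayscale units deep and an ELM-RPE
span of 56.4 µm; dark adaptation collapses the band (programmed to 20% of
its light depth) and thins the outer retina by ~10%, exactly the
physiology the phantom encodes.

```r
cohort <- simulate_cohort(cohort_sim_spec(seed = 1))  # 8 groups, 48 mice
fit <- fit_joint_bivariate(cohort,
                           settings = sampler_settings(chains = 4,
                                                       iterations = 4000,
                                                       thin = 1),
                           seed = 1)
td <- tidy(fit)
td[td$term %in% c("mu_elm_rpe", "mu_hb", "r_mu", "slope_hb_on_elm"), ]
#>   term            estimate std.error conf.low conf.high  rhat   ess
#> 1 mu_elm_rpe        10.1      1.83      6.28     13.7    1.01  349.
#> 2 mu_hb              9.15     1.33      6.43     11.7    1.00  304.
#> 3 r_mu               0.933    0.0872    0.688     1.000  1.00  367.
#> 4 slope_hb_on_elm    0.698    0.144     0.390     0.971
```

The cohort was simulated with a true between-group correlation of 0.975;
the posterior of `r_mu` centers near it with an interval excluding zero,
and `slope_hb_on_elm` is the same association expressed as a regression
slope for correlation scatter plots (`plot_correlation(fit, cohort)`).

`run_pipeline(pipeline_config(out_dir = "run1", seed = 1))` chains the
stages end to end (simulate → quantify → light–dark differences → model →
report) and writes CSV tables, a markdown report and a manifest with
per-file checksums; rerunning with the same seed reproduces every CSV
bit-identically.

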
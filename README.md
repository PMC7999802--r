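# wristpd

Detection of Parkinson's disease (PD) from raw wrist-worn accelerometry
recorded passively in daily life. The package is aimed at researchers
working with free-living actigraphy cohorts (triaxial, 100 Hz, units of g,
days of data per subject) who want a fully tested, reproducible
implementation of an activity-segmentation + movement-feature + adapted
mixture-model screening pipeline — together with a synthetic cohort
generator that makes every stage testable without access-restricted
cohort data.

## The method

For a recording $x(t) \in \mathbb{R}^3$, the magnitude
$m(t) = \lVert x(t)\rVert_2$ is summarised by its sliding-window standard
deviation $\sigma_m(t)$ ($|t'-t| \le \tau_1 = 10$ s, population form).
Sustained **gait** is detected where $\sigma_m > 0.05$ g for ≥ 30 s (gaps
≤ 15 s tolerated); sustained **low movement** (LM) where
$0.001 < \sigma_m < 0.03$ g for ≥ 240 s. Segments are cut into 10 s
frames; gait frames must show a first autocorrelation peak (the step
time) at a delay in [0.21, 1.75] s with height > 0.1 on all three axes.

Features per frame:

- **Gait dispersion** $D_i = |V|^{-2} \sum_{t_1,t_2 \in V}
  |\hat x_i(t_1) - \hat x_i(t_2)|$ on z-scored axes after 2-SD outlier
  removal — low values mean rigid, stereotyped movement;
- **LM eigenspectra** of $45 \times 45$ channel-delay correlation
  matrices (3 channels × 15 delays, delay spacings {1, 3, 7, 15}
  samples), concatenated over scales (180 values) — concentration in few
  eigenvalues means low movement dimensionality;
- **Frame incidences** (valid gait and LM frames per day).

Per cross-validation fold, each feature set is z-scored, projected on
principal components explaining 97.5% of training variance, modelled by a
background GMM (K = 5, diagonal covariances, 4 EM iterations, variance
floor 0.01) and MAP-adapted (relevance r = 16, means only) into class
models. A subject's score is
$\log \bar L_{PD} - \log \bar L_{control}$ with per-frame likelihoods
averaged arithmetically; component scores fuse additively with weight
$\alpha = 0.15$ on incidence scores. Accuracy is pooled-test-fold AUC and
sensitivity at FPR 0.1/0.2 under stratified 5-fold cross-validation.

## Worked example

```r
library(wristpd)

# a synthetic 20+20 cohort, one day per subject, with PD effect knobs:
# less walking, more sustained low movement, more rigid swing, lower
# movement dimensionality
spec <- cohort_spec(20, 20, days = 1, seed = 7,
                    effect_knobs = pd_effect_knobs())
feats <- simulate_features(spec)     # simulate -> segment -> featurise
report <- run_cv(feats)              # 5-fold cross-validated evaluation
print(report)
```

```
<wpd_report> 40 subjects, 0 excluded
                    scores   auc sens_fpr10 sens_fpr20  n
                      S_G1 0.761      0.150      0.600 39
                      S_G2 0.537      0.050      0.300 40
               S_G1+a*S_G2 0.753      0.150      0.600 39
                     S_LM1 0.871      0.368      0.842 37
                     S_LM2 0.748      0.500      0.750 40
             S_LM1+a*S_LM2 0.865      0.368      0.842 37
         S_G1+a*S_G2+S_LM1 0.870      0.421      0.895 36
 S_G1+a*S_G2+S_LM1+a*S_LM2 0.870      0.421      0.895 36
```

Rows are fused score combinations (G = gait, LM = low movement, 1 =
multiframe feature score, 2 = frame-incidence score): here the fully
fused score separates PD from control subjects with AUC 0.87 on the 36
subjects that had both frame types; `n` varies because a combination only
evaluates subjects whose required frame types exist. Effect sizes
(`report$effects$summary`, Cohen's d, PD − control) show the planted
structure: negative for gait incidence and dispersion, positive for LM
incidence.

The numbered scripts under `analysis/` run the complete study narrative —
cohort simulation, diurnal incidence patterns, effect sizes,
cross-validated classification, and accuracy versus days of wear — each
writing its tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_incidence_patterns.R
Rscript analysis/03_effect_sizes.R
Rscript analysis/04_classification.R
Rscript analysis/05_days_of_data.R
```

The methods vignette (`vignettes/wristpd-methods.Rmd`) documents the
models, every tunable parameter with units and defaults, the synthetic
generator's design and its limits.

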
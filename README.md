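# odorint

Analysis of odor-plume **intermittency** and how it is encoded — by behaving
animals and by olfactory-bulb glomeruli observed with wide-field calcium
imaging. Built for researchers analysing trial-based olfactory experiments
(PID-style concentration traces, nasal pressure, lick events, and
per-glomerulus fluorescence at 25 frames/s), and for anyone who wants a
fully synthetic, ground-truthed testbed for such pipelines.

## The statistic at the core

At a fixed point in a turbulent plume, odor arrives as whiffs separated by
blanks. Intermittency is the probability that concentration exceeds a
threshold tied to the source concentration C₀:

    γ = Pr[ C ≥ 0.1 C₀ ]

computed over the 6 s odor window. The same construction is applied twice
more:

* **estimated perceived intermittency** — the same statistic restricted to
  the odor actually inhaled (samples inside sniff inhalation intervals,
  T = total inhalation time);
* **glomerular intermittency (GI)** — the fraction of the odor window a
  glomerulus's deconvolved, baseline-z-scored response spends at Z ≥ 2.
  The OLS slope of GI against stimulus γ ("GI slope") separates
  whiff-driven (positive) from blank-driven (negative) glomeruli.

Around these sit the full pipeline: square-wave/plume stimulus generation
and quantification, sniff detection, dF/F → 0.075–10 Hz zero-phase
Butterworth filtering → quadratic bleach correction → 150 ms exponential
deconvolution → z-scoring, responder detection, encoding ANOVA,
shuffle-corrected stimulus cross-correlation, correlation-distance
hierarchical clustering (cutoff 0.74), 20×3-fold linear-discriminant
decoding (trained on one third, tested on two thirds), and Go/No-Go
hit-rate / false-alarm bookkeeping with engagement trimming.

## Worked example

```r
library(odorint)
cfg <- generator_config(seed = 42)

# a 5-pulse, duty-80 square wave: gamma is exact by construction
sq <- gen_square_wave(5, 80, cfg)
compute_intermittency(sq)   # 0.8
count_whiffs(sq)            # 5

# a small imaging session with two planted glomerular phenotypes
gl  <- gen_glomerulus_population(12, frac_cluster1 = 0.5, cfg)
ses <- gen_session(cfg, glomeruli = gl,
                   trial_gammas = rep(c(0.2, 0.5, 0.8), each = 10))
res <- process_session(ses)
res
#> <session_result> 30 trials, 12 glomeruli

# recovered GI slopes per planted cluster (presets -0.59 / +0.89)
sl <- merge(res$slopes, gl[, c("roi_id", "cluster")], by = "roi_id")
round(tapply(sl$slope, sl$cluster, mean), 2)
#>     1     2
#> -0.59  0.84

# clustering on GI tuning profiles at correlation distance cutoff 0.74
hc <- hierarchical_cluster(interglomerular_corr(gi_profiles(res$gi)),
                           cutoff = 0.74)
hc$n_clusters               # 2, matching the planted split exactly
```

The mean recovered slopes sit on the planted values (−0.59 exactly, 0.84 vs
0.89 — the small shrinkage comes from edge blurring at the z-threshold
crossing), and the two planted phenotypes separate into exactly two
clusters with no misassignments.

## Package tour

| Area | Functions |
| --- | --- |
| Stimuli | `stimulus_trace`, `compute_intermittency`, `normalize_trace`, `binarize_trace`, `apply_gain`, `count_whiffs`, `label_cs` |
| Synthetic data | `generator_config`, `gen_plume_trace`, `gen_square_wave`, `gen_sniff_trace`, `gen_glomerulus_population`, `gen_fluorescence`, `gen_session` |
| Sniffing | `detect_sniffs`, `perceived_odor`, `perceived_intermittency`, `cumulative_perceived_intermittency`, `mean_sniff_frequency` |
| Imaging | `compute_dff`, `bandpass`, `bleach_correct`, `deconvolve`, `convolve_kernel`, `zscore_response`, `first_sniff_response`, `detect_responders`, `preprocess_trace` |
| Encoding | `compute_GI`, `fit_GI_slope`, `encoding_anova`, `xcorr_shuffled`, `spatiotemporal_map` |
| Population | `gi_profiles`, `interglomerular_corr`, `hierarchical_cluster`, `crossval_classify`, `glomerulus_curves` |
| Behavior | `score_trials`, `session_metrics`, `first_lick_by_intermittency`, `decode_from_perceived` |
| Sessions | `process_session`, `gi_matrix`, `trial_table`, `write_trial_table` |

The methods vignette (`vignettes/odor-intermittency-methods.Rmd`) documents
the models, conventions, numerical choices, and what the synthetic
generator does and does not emulate.
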
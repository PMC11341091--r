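# popdprime

Task engagement changes how auditory cortex encodes sounds. `popdprime`
is an R package for asking *how*: given trial-structured population
spike counts recorded while an animal alternates between performing a
go/no-go tone-in-noise detection task and listening passively to the
same stimuli, it quantifies

- **behavioral sensitivity** per target SNR,
  d′ = Φ⁻¹(hit rate) − Φ⁻¹(catch response rate);
- **single-neuron discriminability** |Z[target] − Z[catch]| with
  permutation significance;
- **population decoding** via d′² = Δμᵀ Σ⁻¹ Δμ, estimated in the 2-D
  space spanned by the signal axis (Δμ) and the dominant noise
  covariability axis (decoding-based dimensionality reduction, dDR),
  which avoids the severe small-sample bias of full-space decoders;
- **covariability structure** by factor analysis of the spike-count
  covariance, Σ = LLᵀ + Ψ (percent shared variance, loading similarity,
  cross-validated dimensionality, alignment with the coding axis);
- **pupil-indexed arousal control**: removal of pupil-explainable
  variance (r̄ᵢ = rᵢ − αᵢ(p − p̄)) while preserving stimulus means;
- the **four-model Gaussian ablation** (null / gain-only /
  independent-variance / shared-variance) that regenerates population
  responses with selected parameters tied across behavioral states and
  re-runs the identical decoding, attributing engagement-related
  decoding changes to response gain vs variance vs covariance.

The headline quantity is **selective enhancement**: the
engagement-related improvement in task-relevant (target vs catch)
discriminability beyond the task-irrelevant (target vs target)
improvement. A synthetic-session generator with known ground truth
(psychometric outcomes, flat-hazard trial structure, factor-model
population responses, pupil coupling) makes every stage testable.

## Worked example

```r
library(popdprime)

cfg <- session_config(seed = 1)                       # 60 neurons, 25 trials/stimulus/state
s   <- simulate_session(cfg, region_mode = "dPEG_like")
s
#> <task_session> 60 neurons, 715 events (250 trials), 20 bins of 0.02 s
#>   ground truth: dPEG_like (rank 1 shared covariance)

psychometric_table(s$events)
#> # A tibble: 4 × 6
#>   snr_db n_target hit_rate n_catch catch_rate dprime
#>    <dbl>    <int>    <dbl>   <int>      <dbl>  <dbl>
#> 1    -10       25     0.28      25       0.24  0.123
#> 2     -5       25     0.68      25       0.24  1.17
#> 3      0       25     0.8       25       0.24  1.55
#> 4    Inf       25     0.96      25       0.24  2.46

r   <- regress_out_pupil(evoked_response(s))          # z-scored, arousal-controlled
dec <- pairwise_decoding(r)                           # dDR decoding per stimulus pair
category_summary(dec)
#> # A tibble: 3 × 3
#>   category                 n_pairs mean_value
#>   <chr>                      <int>      <dbl>
#> 1 distractor_vs_distractor       3     0.0152
#> 2 target_vs_catch                4     0.240
#> 3 target_vs_target               6     0.181

selective_enhancement(dec, normalized = TRUE)
#> [1] 0.05863452
```

Behavioral d′ rises with SNR (0.12 at −10 dB to 2.46 for the pure
tone). Engagement improves decoding of every pair (positive normalized
Δd′), but the task-relevant target-vs-catch improvement (0.240) exceeds
the task-irrelevant target-vs-target improvement (0.181): selective
enhancement 0.059 for this session, as built into the dPEG-like ground
truth. `run_pipeline()` repeats this over sessions and adds
signed-rank tests, covariability metrics and the neural–behavioral
correlation; `engagement_ablation()` runs the four-model simulation;
`plot_decoding()`, `plot_ddr_projection()`, `plot_psychometric()` and
`tidy()`/`glance()` methods cover inspection.

## Documentation

The methods vignette (`vignettes/popdprime-methods.Rmd`) describes the
models and their assumptions, every tunable parameter with its default
and rationale, what the synthetic generator does and does not emulate,
and the numerical conventions (ridge, permutation p-value convention,
EM tolerances, tie-breaks).
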
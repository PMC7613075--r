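# swapkit

Analysis toolkit for **swap errors** (non-target intrusions) in
continuous-report cued recall from visual working memory — for researchers
who run delayed-estimation tasks in which one circular feature of an item
(its location, orientation, or motion direction) cues the reproduction of
another.

When memory for the *cue* feature is noisy, the wrong item can appear
closest to the cue and its report feature is reproduced instead of the
target's. swapkit implements the computational machinery around this
*feature variability* account:

- **Circular statistics**: wrapping to (−π, π], circular distance, mean
  resultant vector, circular SD = √(−2 log R), circular MAD, von Mises
  density/sampler, Fisher information m·κ·I₁(κ)/I₀(κ).
- **Synthetic task generator** for three designs (6-item
  orientation×location with 30°/15° minimum separations and three
  reliability levels; 4-item direction×location with 60°/60°; 6-item
  spatially cued orientation report with fixed / rotated / random layouts),
  with responses simulated from known generative processes and ground-truth
  item selection recorded.
- **Swap-frequency estimators**: the nearest-item heuristic; the
  three-component von Mises mixture p_T·f(x−r_t; κ) + p_N/(N−1)·Σⱼ f(x−rⱼ; κ)
  + p_U/2π fit by EM; and a distribution-free resultant-vector method with a
  correction for minimum-separation artifacts, plus the randomization
  procedure that computes expected non-target deviation histograms and MADs
  under the no-swap null.
- **Parameter-free Monte Carlo predictor**: predicts the swap rate when a
  feature dimension serves as *cue* purely from the response errors observed
  when the same dimension is *reported*.
- **Model fitting and comparison**: maximum-likelihood fits (Nelder-Mead) of
  a Poisson-spiking neural binding model with a per-level conjunction-coding
  parameter (6 free parameters for a 3-level design) and of an interference
  model in full (6 parameters/cell, 36 total) and partial (A_a = 0, 30
  total) variants, compared by AIC and BIC.

## Worked example

Simulate a group-scale orientation-cued location-report task from the
neural binding model, estimate swap frequencies, and predict them from the
orientation-report condition:

```r
library(swapkit)

truth <- nbm_params(kappa_loc = 12, kappa_feat = 5, gain = 30,
                    conjunction = c(low = 0.35, medium = 0.55, high = 0.8))

trials    <- generate_trials(task_orientation_location("location", 400L), seed = 99)
responses <- simulate_responses(trials, "nbm", truth, seed = 100)
estimate_swaps(responses, "nearest_item")
#>         method  level proportion n_trials
#> 1 nearest_item    low     0.2975      400
#> 2 nearest_item medium     0.1750      400
#> 3 nearest_item   high     0.1150      400

ori  <- simulate_responses(generate_trials(task_orientation_location("orientation", 400L),
                                           seed = 101), "nbm", truth, seed = 102)
predict_swaps(responses, build_error_pools(ori), n_iter = 500L, seed = 103)
#>    level predicted_proportion n_trials n_iter       mc_se
#> 1    low              0.31722      400    500 0.003306677
#> 2 medium              0.17392      400    500 0.002748439
#> 3   high              0.08507      400    500 0.002348676
```

The nearest-item estimates fall from 30% to 12% of trials as the
orientation signal strengthens (conjunction 0.35 → 0.8), and the
parameter-free predictions — built only from orientation-report errors —
track them level by level: the swap gradient is carried by cue-dimension
variability. A mixture fit of the low-reliability cell gives the same
picture in mixture weights:

```r
low <- subset(responses, level == "low")
fit_mixture(low)
#> <mixture_estimate> p_target 0.705  p_nontarget 0.257  p_uniform 0.038  kappa 46.13
#>   loglik -241.71 on 400 trials
```

`fit_nbm()` / `fit_im()` fit the two generative models to such data and
`compare_fits()` tabulates ΔAIC/ΔBIC and best-model counts;
`run_pipeline()` chains simulate → estimate → predict → fit → compare with
plain-text artifacts and stage caching.

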
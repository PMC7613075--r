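---
title: "Swap errors in cued recall: estimation, prediction and models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Swap errors in cued recall: estimation, prediction and models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swapkit)
```

## The problem

In continuous-report cued recall, an observer memorizes an array of items,
each a conjunction of two circular features (for example an orientation at a
location). One feature of one item — the *cue* — is then shown, and the
observer reproduces the other feature — the *report* — of the same item on a
continuous scale. Responses cluster around the target's report feature, but
a fraction cluster around the report features of *other* items: swap errors.
swapkit implements the computational machinery for studying these errors:

* a circular-statistics core (`wrap_angle()`, `circ_resultant()`,
  `circ_sd()`, `circ_mad()`, `vm_pdf()`, `vm_sample()`);
* a synthetic-data generator reproducing the structural constraints of three
  task designs (`task_orientation_location()`, `task_direction_location()`,
  `task_spatial_cue()`, `generate_trials()`, `simulate_responses()`);
* three swap-frequency estimators (`nearest_item_swaps()`,
  `fit_mixture()`, `resultant_vector_estimate()`) plus the randomization
  correction for minimum-separation artifacts
  (`expected_nontarget_profile()`) and a distance-binned non-target analysis
  (`mad_by_distance()`);
* a parameter-free Monte Carlo predictor of swap frequency from
  cue-dimension variability (`predict_swaps()`);
* two fittable generative models — a Poisson-spiking neural binding model
  (`fit_nbm()`) and an interference model in full and partial variants
  (`fit_im()`) — compared by AIC/BIC (`compare_fits()`).

All angles live on \((-\pi, \pi]\) radians. Orientation, which is periodic
over 180 degrees, is doubled into this space at I/O time
(`scale_orientation()`); every internal computation is in radians on the
full circle. Minimum separations for orientation are enforced in the native
space before doubling, so a 15-degree native separation appears as
\(\pi/6\) internally.

## The synthetic generator and what it emulates

`generate_trials()` draws item features uniformly over the set of
configurations satisfying the design's minimum pairwise separations, by
rejection sampling. Rejection (rather than sequential placement) makes the
accepted configurations exactly uniform on the constraint set; since the
original experiments do not state their sampler, we fix this choice once and
the estimator corrections consistently condition on the generator actually
used. The three bundled designs reproduce: six items with 30-degree location
and 15-degree (native) orientation separations and three stimulus-
reliability levels; four moving-dot items with 60-degree separations in both
dimensions; and six orientation patches under fixed / rotated / random
spatial layouts (random layout: 36-degree separation; orientations
unconstrained).

`simulate_responses()` attaches responses from a known generative process —
a pure-target von Mises, the classic three-component mixture (optionally
with wrapped-Laplace errors, to exercise distribution-free claims), the
neural binding model, or the interference model — and records which item the
process actually selected. That ground truth is what estimator validation
compares against.

The generator emulates the *statistical structure* of the tasks: feature
layouts, separations, condition levels, cue/report roles. It does not
emulate stimulus rendering, encoding dynamics, eye movements, sequential
dependencies, participant heterogeneity, or lapses that real data contain.
Passing recovery tests therefore shows that the estimators and fits are
correct under their stated assumptions, not that those assumptions hold for
any particular empirical dataset.

Simulation functions take explicit integer seeds; identical seed and
configuration give byte-identical output tables. (Per-trial counter-derived
substreams were considered and dropped in favour of a single sequential
stream — the package has no parallel execution paths, and a single stream
keeps reproducibility trivial.)

## Estimating swap frequencies

**Nearest item.** A response is a swap iff it lies strictly closer to some
non-target's report feature than to the target's. Exact ties go to the
target — conservative, and probability zero under continuous features. The
heuristic is reliable when report noise is small relative to the report
separations; with genuinely noisy reports it misclassifies, which is why the
package carries two model-based estimators alongside.

**Three-component mixture.** `fit_mixture()` maximizes the likelihood of
the standard mixture — von Mises around the target, von Mises around each
non-target with a shared total weight, uniform guessing — by
expectation-maximization: responsibilities in the E step, weight updates in
the M step, and the shared concentration updated by the standard
Bessel-ratio inversion \(A^{-1}(r)\) with Newton refinement. EM runs from
ten dispersed starts by default with a \(10^{-6}\) log-likelihood
convergence tolerance; non-convergence is flagged, never silent. With
purely uniform data the model is degenerate (a zero-concentration von Mises
is itself uniform), so the guessing weight and concentration trade off;
the fit is reported as-is.

**Resultant vector.** The resultant of a mixture is the weighted sum of the
component resultants, which permits estimating the mixture weights without
assuming any error shape. For each harmonic \(k\), the cosine moments of
deviations from the target and (pooled) from the non-targets satisfy a
linear system in \(u_k = p_T\phi_k\) and \(v_k = p_N\phi_k\), where
\(\phi_k\) is the unknown error distribution's \(k\)-th Fourier
coefficient. The system's cross terms are the separation moments
\(C_k = E[\cos k(r_j - r_t)]\) and \(G_k\) (between non-targets), computed
directly from the observed arrays — the closed-form limit of estimating
them by randomization, and the place where minimum-separation structure is
corrected for. First-harmonic moments alone only identify the *products*
weight × resultant length; no finite set of moments separates them without
an extra assumption, because the uniform component contributes to no
harmonic. We therefore reconstruct the non-uniform part
\(p_T(\phi(e) - 1/2\pi) = \frac1\pi\sum_k u_k\cos ke\) and integrate it over
an antipodal window \([w_0, \pi]\) on which the error density is treated as
negligible; this identifies \(p_T\) (and likewise \(p_N\)) for any error
shape whose mass stays clear of the antipode. Defaults — 15 harmonics,
\(w_0 = 3\pi/4\) — were fixed from a numerical study of truncation bias
against sampling noise before the validation suite was written. The
estimator is unconstrained: a negative non-target weight is meaningful
evidence for no swaps. It needs pooled (group-scale) data; its sampling
error at a few thousand trials is several percentage points, and grows when
report variability is high (overlapping component distributions) or the
window assumption is strained (very diffuse errors).

**Randomization correction.** Minimum separations make the deviation-from-
non-target distribution non-uniform even when non-targets have no causal
influence: responses clustered on the target are also kept away from
non-targets, carving a central dip. `expected_nontarget_profile()`
estimates that null by replacing one non-target's report feature per trial
with a fresh constraint-respecting value (which cannot have influenced the
response) and recomputing deviations over many iterations (default 1000).
The expected histogram is subtracted from the observed one, and the same
draws give the expected mean absolute deviation. Which non-target is
replaced rotates deterministically across trials; the profile is invariant
to that choice up to Monte Carlo error. Histograms use 37 equal bins on
\((-\pi,\pi]\) — an odd count centres a bin at zero, where swap mass peaks.

**Distance-binned MAD.** `mad_by_distance()` bins each non-target by its
cue-feature distance from the cued value and reports the circular MAD of
responses around that non-target's report feature. With unconstrained
uniform report features the no-swap reference is exactly \(\pi/2\); dips
below it localize swaps in cue space. Binning adapts to the layout:
equispaced arrays occupy discrete distances (60/120/180 degrees for six
items) and each becomes a bin; otherwise seven equal bins from 34 to 180
degrees are used.

## Predicting swaps from cue variability

`predict_swaps()` implements the parameter-free account: if swaps arise
because memory for cue features is noisy, then the error distribution
observed when that dimension is *reported* should predict how often a
non-target wins the cue comparison. For each trial, one error per item is
resampled (with replacement) from the matching level's pool, added to the
item cue features, and a swap flagged when a perturbed non-target lands
nearest the cue; 1000 iterations per trial are averaged. Errors are drawn
independently across items — within-trial error correlations would change
the predictions, so this assumption is stated rather than buried. Raw
errors are resampled without kernel smoothing, and ties again go to the
target.

## The neural binding model

Each array's features are encoded in an idealized conjunctive population:
the total spike count is Poisson with mean `gain` and spikes distribute
uniformly over items, which is equivalent to independent Poisson counts of
mean `gain/N` per item. Every spike carries one von Mises location sample
(concentration `kappa_loc`); with probability `conjunction` (per stimulus-
reliability level, shared across the two report conditions) it also carries
a feature sample (`kappa_feat`). Decoding a feature is maximum-likelihood:
the resultant direction of that item's samples, or a uniform draw when no
samples exist. The item whose decoded cue value is nearest the cue is
selected and its decoded report value is the response. Swaps arise solely
from cue-dimension decode variability; there is no guessing mechanism.
A three-level experiment has six free parameters: two concentrations, the
gain, and three conjunction values.

**Likelihood.** Because per-item counts are independent Poissons (and
feature-thinning splits them into independent feature and non-feature
Poissons), the response density marginalizes spike counts *exactly* by
truncated enumeration — no Monte Carlo over count vectors is needed. For
one trial,
\[
p(x) = \sum_i \sum_r P(\text{select } i,\, m^{rep}_i = r)\;
       f_r(x - r_i;\, \kappa_{rep}),
\]
where the selection probability integrates item \(i\)'s cue decode-error
density against the survival functions of its competitors' absolute decode
errors, marginalized over their counts. The only tabulated ingredient is
the decode-error density \(f_m\): conditional on the sample resultant
length \(R\), the decode error is von Mises with concentration
\(\kappa R\), so \(f_m\) is a mixture over the distribution of \(R\). That
distribution is drawn once from a fixed matrix of uniforms pushed through
the von Mises quantile function (column-wise cumulative resultants give all
\(m\) at once), making every likelihood evaluation deterministic and smooth
in \(\kappa\) — two evaluations at identical parameters are identical, and
refitting from a previous optimum cannot lower the likelihood. Numerical
settings: a 720-point angular grid (0.5-degree cells; angles are rounded to
the nearest cell in the selection integral), Poisson truncation at the
\(1-10^{-7}\) quantile, 4000 resultant-length draws in 48 bins per count.
Selection probabilities are renormalized to sum to one per trial, absorbing
grid-rounding residue. The per-trial selection integral is implemented in
C++.

**Fitting** is Nelder-Mead on transformed parameters (log concentrations
and gain, logit conjunctions) from dispersed starts, with box bounds that
keep the enumeration within its tabulated range. **Diagnostics** at fitted
parameters are produced by mass simulation: conditional zero-spike
probabilities in the cue dimension given swap/correct outcomes (the
unconditional probability has the closed form \(e^{-\lambda c}\), used to
validate the simulation) and mean cue-dimension Fisher information
\(m\,\kappa\,I_1(\kappa)/I_0(\kappa)\) for targets and selected non-targets
by outcome.

## The interference model

Responses mix three retrieval routes: cue-based (each item weighted by
\(\exp(-|d_j|/s)\), an exponential — circular Laplace — function of its cue
distance \(d_j\), with the target's weight fixed at 1 because its distance
is zero and the cue-based route's weight \(A_c\) is fixed at one), cue-
*independent* (weight \(A_a\) per item, regardless of cue similarity), and
uniform background noise (weight \(A_b\)). One item may occupy the focus of
attention; only the state in which that item is the *target* changes
anything: the target's report concentration becomes `kappa_f` (constrained
\(\ge \kappa\); focus enhances precision) and the noise weights \(A_a,
A_b\) shrink by the factor `r`. We set the probability of the target being
focused to \(1/N\) — simultaneous presentation privileges no item — and
treat all other focus states as the baseline, since only the target-focused
state is given distinct dynamics in the model description. \(A_b\) is not
rescaled with set size (set size is constant within each experiment; noted
as a caveat for cross-set-size use). The full variant has six free
parameters per report-condition × level cell; the partial variant freezes
\(A_a = 0\) (five). The model makes no prediction linking report-dimension
variability to cueing with the same dimension, so it is fit per cell and
aggregated: 36 versus 30 parameters across the six cells of a three-level,
two-condition experiment. `aic`/`bic` use the number of trials entering
each likelihood as the BIC sample size — the standard convention, fixed
here explicitly.

## Validation strategy and problem sizes

The test suite validates each layer against an independent oracle: circular
statistics against closed forms (Bessel ratios, uniform limits), the
generator against its constraints and uniform marginals, estimators against
generator ground truth (mixture weights at \(n = 3000\); the resultant
method under wrapped-Laplace errors at \(10^4\) pooled trials; nearest-item
labels exactly, in the low-noise regime), the Monte Carlo predictor against
a two-item quadrature oracle and against select-nearest ground truth, the
binding-model density against its own simulator, and the fits by parameter
recovery (conjunction values within 0.1 at 500 trials per level and
condition; interference-model \(A_a \approx 0\) when generated at zero,
with \(n = 3000\) in the tested cell). Recovery runs use these sizes as the
package's chosen study scale; the qualitative dissociation — lowering
conjunction raises swap rate when the manipulated feature cues, and raises
report dispersion (not swap rate) when it is reported — is asserted on
simulations of 3000 trials per point.

## Known limitations

* The resultant-vector identification assumes negligible error density in
  the antipodal window; with very diffuse report errors the target weight
  is underestimated and the estimate is flagged as unreliable only in the
  grossest cases.
* The nearest-item heuristic inherits bias from uniform guesses (a uniform
  response is counted as a swap with probability \((N-1)/N\)).
* The binding-model likelihood is exact only up to grid resolution and the
  tabulated resultant-length distribution; both are fixed, so the induced
  (small) bias is shared between fits being compared.
* Interference-model parameters beyond \(A_a\) — notably `kappa_f` and `r`
  — are weakly identified at realistic trial counts because the focus state
  is latent and rare; recovery claims are limited accordingly.
* The generator does not model participant heterogeneity; group-scale
  pooling in the examples treats trials as exchangeable.
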
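---
title: "Models and methods behind drmtrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind drmtrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`drmtrack` analyzes recognition decisions in the
Deese–Roediger–McDermott (DRM) false-memory paradigm by combining a
distributional-semantics predictor with mouse-tracking dependent
variables and crossed random-effects models. This vignette explains the
statistical machinery, the choices we made where the design was
genuinely open, and what the synthetic-data generator does and does not
emulate. It states no empirical result beyond what the package's tests
and `scripts/acceptance.R` themselves compute.

## The semantic predictor

Word meanings are taken from a word-embedding space (word2vec text
format; any dimensionality, the spaces typically used are 300–400
dimensional). For a recognition probe $nw$ and the studied words
$sw_1,\dots,sw_k$ of its list, the semantic-similarity index is the
frequency-weighted mean cosine

$$\mathrm{SSim}(nw) \;=\;
\frac{\sum_{i=1}^{k}\cos(\vec{nw},\vec{sw_i})\,F(sw_i)}
     {\sum_{i=1}^{k}F(sw_i)},$$

with $F$ a corpus occurrence count. New probes (critical lures, weak
lures, unrelated words) use all $k = 12$ studied words of their
(assigned) list; a studied probe uses the other 11, never its own
cosine with itself. Two properties anchor the test suite: SSim is a
convex combination of cosines, hence bounded by their minimum and
maximum; and it is invariant under rescaling all frequencies by a
positive constant, which makes the raw-count vs. per-million question
moot (we therefore read the frequency file as-is). Out-of-vocabulary
words are a hard error by default — a silent zero would bias the
weighted sum — with an explicit `skip_oov` escape that drops and logs
the word. All lookups fold case, because stimulus norms are mixed-case
while embedding vocabularies are typically lowercased.

## Trajectory measures

Raw mouse records are (x, y, t) samples in screen-height units with the
origin at screen centre (start button at (0, −0.35), response buttons
at (±0.50, 0.25)). Processing follows the standard mouse-tracking
chain:

1. **Movement onset** is the first sample displaced more than 0.01
   screen units from the start position (the threshold is a parameter;
   "first hand movement" has no universal numeric definition).
   Initiation RT is onset time minus the start-button click.
2. **Time normalization**: x and y are linearly interpolated at 101
   equally spaced time points spanning onset to response click, so
   trajectories of different durations are comparable step by step.
   The 101 step times are kept, so time-indexed measures (MD-time)
   stay on the real clock.
3. **Symmetric remapping**: right-ending trajectories are mirrored
   about the vertical axis through the start point; an endpoint
   exactly on that axis is resolved from the recorded response button,
   never guessed.
4. **Maximum deviation (MD)** is the signed perpendicular distance
   from the straight start-to-end line, largest in magnitude, positive
   toward the *unchosen* option (attraction to the competitor); ties
   resolve to the earliest step, and small negative values (curvature
   away from the competitor) are legitimate.
5. **Sample entropy** is computed on the first differences of the 101
   x positions, with template length $m = 3$ and tolerance
   $r = 0.2\,\mathrm{SD}$ of the differenced series:
   $-\ln(A/B)$, where $B$ counts ordered pairs of distinct length-$m$
   templates within Chebyshev distance $r$ and $A$ the corresponding
   length-$(m+1)$ pairs. Both template sets are indexed $1..N-m$, so a
   constant series scores exactly 0. When $A = 0$ the entropy is
   undefined; the trial is flagged aberrant rather than given a
   sentinel value. These are the defaults of the trajectory packages
   this field uses; $m$, $r$ and the use of differences are exposed
   because published analyses rarely state them, and absolute entropy
   values are **not** comparable across parameterizations — only
   within one.
6. **MD-time** is the interpolated clock time of the MD step, relative
   to movement onset.

Any failure in this chain (too few samples, no movement, undefined
entropy) marks the trial aberrant with a reason string; batches never
abort. The aberrant fraction is part of the exclusion report.

## Exclusion rules and transforms

Filters run in a fixed order, each marking rows rather than deleting
them: overall RT (movement onset to selection) outside (300, 5000) ms —
strict inequalities, boundary trials stay; aberrant trajectories; then
trials whose MD or sample entropy is more than 3 SD from the
*participant's own* mean (the within-participant reading is the
standard mouse-tracking convention; a pooled mode exists for
sensitivity analysis). The DV filter is single-pass — it is applied
once, never iterated to convergence. Initiation RT, MD-time and sample
entropy are natural-log transformed for modelling; MD is left raw
(its small negative values rule out a log). The log base is exposed
because slope magnitudes are base-sensitive.

## Mixed models

Responses (new = 0, old = 1) are fit with a binomial-logit GLMM by
Laplace approximation; the four trajectory DVs with Gaussian LMMs by
REML. Fixed effects are `SSim * Type` (GLMM) and
`SSim * Type * Response` (LMMs) under treatment coding with reference
level *new* for both factors; SSim enters untransformed and uncentered
(the headline quantities — per-cell simple slopes — are invariant to
centering, while omnibus main effects are not, so the coding is
recorded in provenance). Random structure is crossed intercepts for
participant and item.

* **Singularity fallback.** A variance component at the zero boundary
  (relative tolerance $10^{-6}$) flags the fit singular; the item
  intercept is removed and the model refit once, with the event
  recorded in provenance. A still-singular fallback proceeds with a
  warning.
* **Model criticism.** After the first fit, observations with
  \|standardized conditional residual\| > 2.5 are removed and the model
  refit, exactly once; removing more than 20% of rows triggers a hard
  warning. On clean Gaussian data this removes
  $2\Phi(-2.5)\approx1.24\%$ of rows in expectation, which the
  acceptance suite verifies.
* **Degrees of freedom.** Satterthwaite approximation via `lmerTest`
  for LMM t and Type-III F tests (the convention of this literature's
  R toolchain); a residual-df fallback (`df_method = "residual"`) is
  available and recorded. GLMM terms use Wald z.
* **Simple slopes** are linear contrasts on the fixed-effect vector
  (e.g. the slope in the old/old cell is
  $\beta_{SSim}+\beta_{SSim:Type}+\beta_{SSim:Resp}+\beta_{SSim:Type:Resp}$),
  never refits on subsets; a releveled refit reproduces them to
  numerical tolerance, which is a regression test.
* **Pseudo-R² (total)** is the conditional coefficient of
  determination in the Nakagawa–Schielzeth sense — (fixed + random
  variance) / (fixed + random + residual), with $\pi^2/3$ as the
  latent-scale residual for the logit model. The estimator name is
  stored beside the value because "pseudo-R²" alone is ambiguous.
* **Observed power** for the triple interaction: simulate the response
  from the fitted full model (fresh random effects and residuals),
  refit full and reduced models by maximum likelihood, likelihood-ratio
  test at $\alpha = 0.05$; power is the rejection proportion over
  converged simulations with a Clopper–Pearson interval.
  Non-convergent simulations are counted and excluded from the
  denominator. Note that simulating from point estimates makes
  observed power an optimistic, estimate-conditional quantity — it is
  reported because it is this literature's convention, not because it
  is a good design tool.
* No multiple-testing correction is applied anywhere, matching the
  analysis tradition the pipeline implements.

## The synthetic-data generator

`synth_config()` fixes the study design: 12 lists × 12 studied words,
recognition set of 96 items per participant (48 studied — list
positions 1, 4, 7, 10 — plus 12 critical lures, 24 weak lures, 12
unrelated words), 40 participants by default, and the screen geometry
above.

**Embeddings.** Each list is a cluster on the unit sphere:
members are `normalize(centre + sigma * g / sqrt(dim))`, so `sigma` is
the noise norm relative to the unit centre. Defaults
`sigma_studied = 0.6`, `sigma_critical = 0.3`, `sigma_weak = 1.0`, with
unrelated words isotropic, produce the defining mean-SSim gradient
critical > weak > unrelated with near-certainty across seeds (a tested
generator invariant). Studied-word positions are ordered by cosine to
the lure, a stand-in for forward-associative-strength ordering.
Frequencies are Zipfian (exponent 1) over a random rank permutation.

**Responses.** Bernoulli draws from
$\mathrm{logit}^{-1}(\beta_0+\beta_s z+\beta_t T+\beta_{st} zT
+u_p+u_i)$ with $z$ the z-scored SSim over the 96 recognition items
(z-scoring inside the generator keeps coefficient magnitudes
interpretable across embedding draws), $T$ the studied indicator.
Defaults $\beta = (-1.0, 0.9, 2.2, -0.8)$,
$\tau_{participant} = 0.8$, $\tau_{item} = 0.4$ give hit rates around
0.73 and a graded false-alarm profile (critical ≈ 0.45, weak ≈ 0.25,
unrelated ≈ 0.05) — a realistic DRM pattern with a strong SSim effect
confined to new items.

**Trajectories.** After a log-normal initiation delay
(meanlog $\log 280$, sdlog 0.45, plus a participant offset with SD
0.25), the pointer advances each ~12.5 ms sample (80 Hz with 1 ms
jitter) by
$v\,[(1-w)\hat u_{chosen} + w\,\hat u_{other}]$ plus AR(1) motor
noise, where the competitor weight
$w(t) = \mathrm{clamp}(\alpha_0 + \alpha_1\,c,\,0,\,0.9)\,
e^{-t/\tau_w}$ decays over the movement and $c$ is the conflict input.
By default (`conflict_mode = "pattern"`) $c = z(\mathrm{SSim})$ only
for new items answered "new" — the cell in which this literature
locates the effect — with a fully crossed mode for sensitivity tests
and a `none` mode for null calibration. Conflict also couples into the
motor noise (amplitude ×(1 + 1.6 w) and autocorrelation reduced by
0.8 w): without that coupling, sample entropy *fell* with conflict,
because the larger systematic velocity of curved trials inflates the
relative tolerance $r = 0.2\,\mathrm{SD}$ — noise amplitude alone is
invisible to a scale-relative entropy. The coupling expresses the
substantive idea that conflicted movements are not only more curved
but less smooth.

Defaults $\alpha_0 = 0.55$, $\alpha_1 = 0.35$, $\tau_w = 1100$ ms,
$v = 0.009$, noise SD 0.0012 with autocorrelation 0.995,
`noise_conflict = 0.8`, and a participant SD of 0.08 on $\alpha_0$
were calibrated once so that (i) MD lands in a realistic envelope
(mean ≈ 0.14, central 98% within roughly −0.05 to 0.35 screen units,
matching published descriptive ranges for this task class), (ii)
initiation RT and MD-time have plausible means (≈ 350 and ≈ 770 ms),
(iii) roughly 6–7% of trials are unprocessable (undefined entropy),
the order of magnitude real pipelines report, and (iv) the planted
three-way interaction on MD is detectable with high power at the
default sample size, so the recovery tests are well posed. They were
not revisited afterwards.

**What the generator does not emulate.** Absolute sample-entropy
levels (parameterization-dependent, see above); lexical properties of
real word stimuli (tokens are synthetic labels); encoding-phase
dynamics and the distractor task; item-level trajectory variance
outside the conflict channel. One knock-on effect worth knowing: the
generator plants a *cell-specific item effect* (conflict only in
new/correct-rejection), but the fitted models carry a *shared* item
intercept, so at larger sample sizes a small negative spillover slope
can appear in the false-alarm cell. This is a property of
intercept-only crossed models under cell-specific item effects, not a
bug in either component — and the same sign pattern appears in the
empirical literature. Passing tests on generator data therefore
validate the machinery and its statistical calibration, not any claim
about real participants.

## Numerical and interface choices

* Time normalization preserves endpoints exactly; interpolation is
  piecewise linear (tested against an independent evaluator).
* MD ties break to the earliest step with a $10^{-12}$ float
  tolerance, so a straight line reports its first step rather than
  floating-point noise.
* The entropy kernel is a small C++ routine (exact counting, no
  approximation); the suite proves it equal to a naive O(N²) R loop.
* Every stochastic function takes an explicit seed; the generator is
  byte-reproducible, and the pipeline manifest records config hash,
  input/output checksums and per-stage row counts.
* Stage outputs are plain CSV/JSON, so any stage can be re-run or
  audited in isolation. The package's interface is its R functions
  (`gen_experiment()`, `measure_trials()`, `apply_trial_filters()`,
  `build_model_table()`, the `fit_*` family, `run_pipeline()`) plus
  `scripts/acceptance.R`; we ship no shell wrapper because the
  intended users work in R.

## Problem sizes used by the shipped checks

The test suite calibrates the null rejection rate over 500 simulated
experiments of 10 participants, checks coefficient recovery over 200
replicates at the default 40 participants (and slope-sign recovery
over 40 full trajectory replicates), model criticism over 40 runs of
5000-row tables, and power calibration with 200 parametric
simulations. `scripts/acceptance.R` runs one full default-size
experiment with 200 power simulations per DV. These sizes are the
package's choice of a desk-scale validation; all of them are ordinary
function arguments and scale up freely.

## Known limitations

* Random slopes are deliberately out of scope (intercepts-only, as in
  the analyses this package supports); so are drift-diffusion models
  and velocity/AUC-type trajectory indices.
* Satterthwaite df for simple slopes come from `lmerTest`'s contrast
  machinery; with the residual-df fallback the p-values are mildly
  anticonservative in small samples.
* The two-attractor trajectory model is a stand-in chosen for
  testability, not a mechanistic claim; quantities that depend on its
  fine structure (e.g. absolute MD-time distributions) should be read
  as illustrative.
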
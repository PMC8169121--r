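---
title: "Models and methods behind sniffsearch"
author: "sniffsearch authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sniffsearch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sniffsearch)
```

`sniffsearch` analyzes freely-moving rodent olfactory-search behavior: it
segments three-point pose trajectories (snout tip, back of head, center of
mass, sampled at 80 Hz) into discrete movement motifs with a Bayesian
auto-regressive hidden Markov model (AR-HMM), relates movement and motif
timing to the sniff cycle measured with an intranasal thermistor, maps
investigation and approach behavior over the arena, and decodes trial
labels from motif transition statistics. This vignette explains the models,
the tunable parameters, and the design decisions; the worked example in the
README shows the code in action.

## The AR-HMM

A hidden state sequence $z_t \in \{1,\dots,S\}$ evolves as a Markov chain
with row-stochastic transition matrix $\pi$ and a uniform initial
distribution. Conditional on $z_t = z$, the observed trajectory
$x_t \in \mathbb{R}^d$ follows a state-specific linear autoregression

$$x_t = A_z x_{t-1} + b_z + \varepsilon_t, \qquad
  \varepsilon_t \sim \mathcal{N}(0, Q_z).$$

Each state is thus a brief, simple movement pattern — a drift, a turn, a
pause — and switches between states compose complex trajectories. The first
frame of every trial is conditioned on rather than modeled, so all AR terms
run from $t = 2$; `log_joint_likelihood()` evaluates exactly this sum. The
model has $S(S-1) + 3Sd(d+1)/2$ free parameters (`n_free_parameters()`):
$S(S-1)$ transition probabilities plus, per state, $d^2$ for $A_z$, $d$ for
$b_z$ and $d(d+1)/2$ for the symmetric $Q_z$.

### Priors

Inference is fully Bayesian with conjugate priors (`arhmm_prior()`):

* Transition rows: Dirichlet with uniform mean and total concentration
  $\alpha = 4$, i.e. $\alpha/S$ per cell. An `alpha_per_cell` switch puts
  $\alpha$ in every cell instead, for users who read the concentration
  convention the other way.
* Noise covariances: inverse-Wishart with identity scale and $d + 2$
  degrees of freedom.
* Dynamics: $[A_z\,b_z]$ jointly matrix-normal given $Q_z$, mean $[I\,0]$,
  row covariance $Q_z$ and identity column covariance — so freezing in
  place ($A = I$, $b = 0$) is the prior's central tendency.

### Gibbs sampling

`gibbs_fit()` alternates two exact conditional draws: state sequences for
all trials by forward-filter backward-sampling (compiled; scaled messages
guard underflow), then parameters from their Dirichlet and
matrix-normal-inverse-Wishart conditionals. The first sweep starts from
iid-uniform labels, seeded. Defaults follow the standard recipe: 300
iterations, the first 200 discarded, 100 retained. Retained draws give
per-frame posterior state probabilities (draw frequencies), posterior-mean
parameters (transition rows renormalized after averaging to absorb
rounding), and time-wise MAP label sequences.

The joint posterior is multimodal: a single near-unit-root state ($A
\approx I$) can absorb several spatially separated regimes as one random
walk, and a blocked Gibbs chain essentially never crosses out of that mode
once entered — we observed roughly one seed in eight landing there on
well-separated synthetic data, and the mode persists even though its joint
log-likelihood is far below the truth's. `gibbs_fit()` therefore runs
`n_restarts = 3` independent chains and keeps the one with the highest
final-sweep joint log-likelihood. Restarts are the standard pragmatic
defense; users fitting small models (especially $S = 2$ on limited data,
where the basin of the degenerate mode dominates) should raise
`n_restarts`.

Model size is chosen by held-out likelihood: `crossval_model_scan()` splits
at trial granularity, fits per candidate $S$, and evaluates
`heldout_loglik()` (forward algorithm, uniform initial distribution) on the
test trials. On real behavioral data held-out likelihood typically keeps
rising with $S$; the package also provides `usage_filter()` which drops
motifs occupying under 5% of assigned frames, the pruning rule used when a
moderate-sized model is read out for interpretation.

## Sniff analysis

Inhalation onsets are troughs of the (cooling) thermistor signal,
exhalation onsets are peaks; a `polarity` flag accommodates inverted
hardware. The trace is boxcar-smoothed over 25 ms (`smooth_trace()`), then
`detect_sniffs()` finds alternating extrema with a topographic-prominence
criterion (default: 20% of the trace range — the prominence threshold is a
free choice, exposed as an argument). Each extremum is then relocated by a
least-squares parabola fitted to the raw trace over a window scaled to 0.17
of the local sniff period, which localizes to a fraction of a sample
without being biased by the waveform's asymmetry.

Localization precision is physics-limited: the curvature of the trough
scales with the square of the sniff rate, so at slow rates (below about
5 Hz) sub-millisecond localization of a noisy trace is not attainable by
any unbiased local estimator we tried (template matching and harmonic-phase
fits do worse under natural cycle-length jitter). The onset-recovery
property (99% of planted onsets within one sample) is therefore stated for
the fast-sniffing regime (8 Hz and above) that characterizes active
search.

Sniffs with durations (inhalation-to-inhalation) below the 5th or above the
95th percentile of the session are excluded
(`filter_sniff_durations()`; linear-interpolation quantiles, ties kept).
Instantaneous sniff rate is the reciprocal of the enclosing duration;
sniff phase is latency from inhalation onset divided by duration.

## Sniff-locked kinematics

`compute_kinematics()` yields per frame: nose speed (Euclidean snout
displacement), yaw velocity (change of the unsigned angle between the
nose-head and head-body segments, so centrifugal motion is positive
regardless of side), and Z-velocity (change of snout-head distance, a 2-D
proxy for pitch/vertical motion). Trials containing a frame above 100
px/frame of nose speed are discarded as tracking glitches
(`exclude_glitch_trials()`), and tracking-derived streams are advanced two
frames (25 ms) onto the sniff clock (`align_tracking_to_sniff()`), the
camera-pipeline latency.

Synchrony is quantified three ways:

* `sniff_triggered()` extracts 400 ms windows centered on each kept
  inhalation; the modulation index of the grand-mean curve is
  $(\max - \min)/(\max + \min)$.
* `sniff_kinematic_synchrony()` computes Pearson-normalized
  cross-correlation (`stats::ccf`) and Welch-averaged magnitude-squared
  coherence. The coherence windowing is a free choice: 1 s Hann windows
  with 50% overlap by default, configurable.
* `trial_shuffle_test()` builds the null by re-pairing each trial's sniff
  train with another trial's kinematics (a random derangement, truncated to
  the shared record length); $p = (1 + \#\{\text{null} \ge
  \text{obs}\})/(1 + n)$. The derangement null needs roughly ten or more
  trials: with very few trials, excluding the identity pairing measurably
  inflates the type-I error (we measured 0.08 at nominal 0.05 with eight
  trials, 0.04 with ten).

## Motif structure and spatial analysis

`cluster_transition_matrix()` groups retained motifs into two blocks by the
similarity of their outgoing transition rows (Euclidean distance on raw
probabilities; Ward agglomerative by default, k-means with 100 restarts as
an alternative — both must, and do, recover planted block structure).
The two groups are labeled investigation (slow, tortuous, fast-sniffing)
and approach (fast, directed) by their kinematic summaries
(`state_summary()`). Motif onsets (label changes; trial starts count) are
aligned to the sniff cycle in time (`onset_time_psth()`, 12.5 ms bins) and
in phase (`onset_phase_hist()`), each summarized by a modulation index with
derangement-permutation significance (`onset_modulation_test()`).

Spatial statistics live on a 25 cm (longitudinal, initiation port at 0) by
15 cm (lateral) arena; bins tile it exactly (50 x 30 at 0.5 cm for
occupancy and sniff-rate maps, 25 x 15 at 1 cm for state occupancy). The
investigation-approach index is
$(\mathrm{inv} - \mathrm{app})/(\mathrm{inv} + \mathrm{app})$ per bin or
per axis-projected profile; the transition zone is 5-10 cm from the port.
Gaussian smoothing (sigma = 1 bin) is display-only — statistics are
computed on raw histograms. Right-choice trials can be reflected laterally
(`reorient_by_choice()`) so the chosen side is always on one side.
Correct-incorrect contrasts use the grand mean over mice of per-mouse
profile differences, with a null from 1000 within-mouse label scrambles and
pointwise exceedance p-values (a max-statistic family-wise variant is also
returned).

## Decoding

Each trial's MAP sequence becomes an $S \times S$ empirical transition
matrix (`empirical_transition_matrix()`): pair counts, row-normalized, with
zero-count rows imputed uniform and flagged so the feature dimension stays
fixed. A pooled-covariance linear discriminant with ridge shrinkage
(default $\lambda = 0.1$ toward the scaled identity) classifies the
flattened matrices under stratified five-fold cross-validation; shrinkage
is necessary because the features are exactly collinear (rows sum to one)
and can outnumber trials. Significance comes from re-training on
label-shuffled training folds (100 shuffles per fold), z-scoring the true
accuracy against each fold's null, averaging z across folds, and taking a
normal tail at the averaged z's null scale $1/\sqrt{K}$ for $K$ folds. On
cleanly clustered data the shuffle null is bimodal — a shuffled classifier
locks onto the true cluster axis with random polarity — which caps each
fold's z near 1.3; averaging across folds and testing at the $1/\sqrt{K}$
scale restores power while staying calibrated under the null.

## Plume discriminability

PID recordings on a 7 x 5 grid of sampling locations (about 15 two-second
trials per location and stimulus side) are reduced to 25 ms chunk means —
roughly one inhalation's worth of odor. Per location, the left- and
right-trial chunk distributions give a scaled discriminability
$|2\,\mathrm{AUC} - 1|$, computed by the rank (Mann-Whitney) formula. For
gradient discriminability, the j-th chunk mean of every location is
assembled into a pseudosample field, the spatial gradient is taken by
central differences (one-sided at edges), and the per-bin gradient-angle
distributions are compared the same way; angles are linearized as
$\sin(\theta)$ relative to the longitudinal axis before the ROC (a raw
mode exists), since an ROC on raw circular values would depend on the
branch cut. Maps can be quantized to eight gray levels for display
(`quantize_map()`).

## The synthetic-data generators

Every stage is exercised on data from `synthetic_data`-style generators
with known ground truth and explicit seeds:

* `gen_arhmm_params()` places stationary means on a circle of radius
  `separation` (default 3 trajectory units) with per-state
  contraction-rotation dynamics (spectral radius 0.8) and isotropic noise
  (sd 0.3) — well-separated but overlapping regimes.
* `gen_sniff_trace()` plants inhalation onsets from a rate profile with
  lognormal per-sniff jitter (sd 0.05) and renders
  $-\cos(2\pi\phi) + 0.15\cos(4\pi\phi)$ with the phase $\phi$
  interpolated through the onsets by a monotone spline. The waveform is
  deliberately smooth at its extrema: a piecewise (kinked) waveform has a
  curvature discontinuity at the trough that displaces the smoothed
  extremum by several milliseconds, which would make sub-sample onset
  recovery impossible for any detector — and only trough/peak timing
  matters downstream. An `outlier_fraction` plants 3x / (1/3)x duration
  outliers for filter testing. Additive noise sd is 0.02 on a
  unit-amplitude trace.
* `gen_sniff_locked_kinematics()` produces
  $\mathrm{baseline}\,(1 + m\cos 2\pi\phi)$ plus noise, so the
  sniff-triggered modulation index recovers the planted depth $m$.
* `simulate_session()` builds full sessions in a 25 x 15 cm arena with a
  decision line at 15 cm: each trial has an investigation epoch (slow
  casting near the initiation port, 10 Hz sniffing) followed by an approach
  epoch (fast directed movement to the chosen port, 5 Hz sniffing), each
  alternating between two sub-second movement modes so a fitted AR-HMM
  sees a two-block transition structure. Choices follow a logistic readout
  of a noisy left-right concentration difference (about 80% correct by
  default), keeping correct and incorrect trials populated; an
  always-correct rule exists for degenerate checks. Nose position carries a
  sniff-locked extension along the heading with configurable depth.
* `gen_plume_session()` emulates the 7 x 5 PID grid with mirror-imaged
  exponential plumes from the two odor ports plus white measurement noise.
  The PID sample rate is not a fixed constant of the recording setup, so it
  is a parameter (default 1 kHz).

What the generators do *not* emulate: real turbulent plume statistics
(intermittency, advection), posture-estimation error structure, drift in
the thermistor baseline, or across-mouse variability in kinematics. Passing
tests therefore demonstrate correctness of the algorithms under the stated
generative assumptions, not performance on any particular animal dataset.

## Numerical choices and problem sizes

Cholesky factorizations of posterior scatter matrices are jittered by
$10^{-10} I$ on failure; forward messages are rescaled per frame; MAP ties
break toward the lowest state index; quantile type 7 with a $10^{-9}$
relative tolerance keeps duration ties. All randomness flows through
explicit seeds, and generators restore the caller's RNG state.

The test suite and the acceptance script run at deliberately desk-scale
problem sizes — e.g. 50 trials x 200 frames for parameter recovery, ten
replicates of 20 x 100 for model selection, 200 simulations of ten trials
for permutation calibration — chosen so the whole suite completes in a few
minutes on one core while every statistical property remains sharply
testable. Exact enumeration cross-checks use $S = 2$, $T = 8$ toys where
the $2^8$ label sequences can be summed directly.

## Known limitations

* Blocked Gibbs mode-sticking (above); restarts mitigate but do not
  eliminate it, and $S = 2$ fits on short records are the worst case.
* Sub-sample sniff-onset localization degrades below ~5 Hz sniffing.
* The derangement permutation tests are slightly anti-conservative below
  ~10 trials.
* Z-velocity is a 2-D proxy that confounds pitch and vertical translation,
  as with any overhead-camera preparation.
* The finite-$S$ model is fit exactly as specified; no hierarchical
  (HDP/sticky) extensions are provided.
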
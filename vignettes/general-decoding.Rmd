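---
title: "Specific and general decoders of correlated population activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Specific and general decoders of correlated population activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popdecode)
```

## The scientific problem

Improvements in perception — for instance under covert spatial attention —
are routinely accompanied by decreases in the mean pairwise spike-count
("noise") correlation of sensory populations. This is puzzling: an optimal
linear readout of a *specific* fine discrimination can largely ignore a
global shared fluctuation, so why should behavior track it? One resolution
is that observers do not re-optimize their readout for each task at hand,
but use a *general* readout — a single set of weights able to decode any
stimulus along the relevant dimension. A general readout must weight
neurons by their overall tuning; because shared variability also aligns
with tuning similarity, a general readout is inextricably sensitive to the
magnitude of correlated variability.

`popdecode` implements the estimators, circuit model and session-level
analysis pipeline needed to study this hypothesis end-to-end on synthetic
data:

* the **specific decoder**: the optimal local linear estimator of a fine
  orientation discrimination, and the bias-corrected estimator of linear
  Fisher information \(\hat I\);
* the **general decoder**: a complex linear readout
  \(\hat z = w^\mathsf{T} r\) mapping population activity onto the
  orientation ring, with its closed-form optimal weights and an
  information measure \(\hat I^g\) based on the circular decoding
  residual;
* the **observer's ("monkey's") decoder**: a linear classifier trained on
  behavioral choices and scored on stimulus identity with leave-one-out
  cross-validation;
* **shared-variability statistics**: pairwise noise/signal correlations
  and the eigenspectrum of the shared covariance \(L L^\mathsf{T}\) from a
  Gaussian factor-analysis model fitted by EM;
* a **scaled spiking circuit model** of attention (Gabor-filtered Poisson
  layer 4 of V1 feeding recurrent excitatory–inhibitory EIF layers for
  V1 L2/3 and V4);
* **synthetic behavioral sessions** of a cued orientation change-detection
  task, with choices generated from a planted linear readout.

## Estimators

### Specific decoder and bias-corrected Fisher information

For a fine discrimination of \(\theta_\pm = \theta_0 \pm d\theta\) (defaults
\(\theta_0 = 0.5\), \(d\theta = 0.01\)) with mean responses \(f_\pm\) and
noise covariance \(\Sigma\), the minimum-MSE locally unbiased estimator has
weights \(w = \Sigma^{-1} f' / (f'^\mathsf{T} \Sigma^{-1} f')\) and variance
\(1/(f'^\mathsf{T}\Sigma^{-1} f')\) — the inverse linear Fisher information.
From finite data the information is estimated with the bias correction

\[
\hat I \;=\; \frac{(\hat f_+-\hat f_-)^\mathsf{T}}{d\theta}
\Big(\tfrac{\hat\Sigma_+ + \hat\Sigma_-}{2}\Big)^{-1}
\frac{\hat f_+-\hat f_-}{d\theta}\,
\frac{2N_{tr}-N-3}{2N_{tr}-2} \;-\; \frac{2N}{N_{tr}\,d\theta^2},
\]

valid for \(2N_{tr} > N+3\). Two conventions deserve emphasis, both kept
deliberately:

* the mean difference is divided by \(d\theta\) exactly as printed above,
  while the two conditions sit \(2\,d\theta\) apart; oracle fixtures in the
  test suite therefore place the condition means \(d\theta \cdot f'\)
  apart so the quotient equals the target derivative;
* negative estimates are legitimate near zero information and are
  returned unmodified.

```{r fisher-example}
S <- matrix(c(1, 0.5, 0.5, 1), 2)
tm <- gen_gaussian_population(0.05 * c(1, 1), -0.05 * c(1, 1), S,
                              trials_per_condition = 200, seed = 1)
fisher_info_bc(tm, dtheta = 0.1)   # analytic value: f' S^-1 f' = 4/3
```

### General decoder

Orientation is embedded on the unit circle as \(z = e^{i 2\pi\theta}\);
the factor \(2\pi\) (needed for \(\theta \in [0,1)\) to cover the circle
once) is isolated in `ring_phase()`. The optimal fixed complex readout is

\[
w \;=\; \big\langle \Sigma(\theta) + f f^\mathsf{T} \big\rangle_\theta^{-1}
\big\langle f e^{i2\pi\theta} \big\rangle_\theta ,
\]

computed from per-orientation empirical moments with maximum-likelihood
(divide-by-\(n\)) covariances so that, with equal trials per orientation,
the moment solution coincides exactly with least-squares regression of
\(z\) on the raw responses — a property the test suite exploits as an
independent oracle. Its information is the inverse variance of the wrapped
circular residual with a finite-sample factor,
\(\hat I^g = \mathrm{Var}(\hat\theta-\theta)^{-1}(N_{tr}-N-2)/(N_{tr}-1)\).
Residuals are wrapped to \((-0.5, 0.5]\) and the variance is taken on the
normalized-orientation scale, so \(\hat I\) and \(\hat I^g\) share units
(\(1/\theta^2\)); a wrapped-linear rather than circular variance is used,
which is accurate whenever decoding is better than chance and exact in the
small-error regime. Noiseless data (zero residual variance) yield the
explicit sentinel `unbounded = TRUE` rather than a number.

### Cross-validated classifiers

`loocv_linear_performance()` implements the electrophysiology-style
decoders: per left-out trial, a ridge-regularized linear discriminant
(pooled covariance plus `ridge` times its mean diagonal; default
`ridge = 1`) is fitted on the remaining trials' training labels and the
left-out trial is scored against its evaluation label. The heavy default
ridge is a deliberate choice for the trial-limited regime the sessions
emulate (tens of units, tens of presentations per condition), where an
unregularized pooled-covariance inverse is dominated by sampling noise;
logistic regression and a linear SVM are selectable alternatives. Ties at
the boundary go to the first (lower) class. For the observer's decoder,
training labels are the choices and evaluation labels the stimulus — the
defining asymmetry of that analysis. `pair_discrimination()` mirrors the
model-side comparison: a linear SVM with stratified two-fold
cross-validation, either on the raw \(N\)-dimensional responses
("specific" regime) or on the two-dimensional plane \((\mathrm{Re}\,\hat
z, \mathrm{Im}\,\hat z)\) after projecting through the fixed complex
readout ("general" regime), with the orientation pair separated by
\(\Delta\theta = 0.04\) by default.

## The ring surrogate

`ring_params()`/`gen_ring_responses()` generate the parametric population
used wherever the full spiking simulation would be wasteful. Counts are

\[ r = f(\theta)\,(1 + g) + \varepsilon, \qquad
   g \sim N\!\big(0,\ \sigma_r^2 (1 - c\,a)^2\big), \]

truncated at zero: a wrapped-Gaussian tuning bump per unit, one shared
multiplicative gain per trial (the "radial" fluctuation that elongates
trial clouds along the mean-response direction), and private noise.
Attention \(a \in [0,1]\) shrinks the shared-gain SD by \(1 - c\,a\) with
\(c = 0.5\), so full attention halves the dominant shared mode — a
deliberately simple stand-in for the circuit model's quenching of
low-dimensional variability.

Two default choices matter and were fixed once, before the attention
analyses were run:

* **Tuning heterogeneity** (`heterogeneity = 0.3`): per-unit amplitudes,
  widths and baselines are log-normally dispersed around their means. A
  perfectly homogeneous ring is a degenerate special case: its optimal
  complex readout cancels gain noise exactly (the readout of a symmetric
  bump population is a pure first harmonic), and, worse, pure gain noise
  acting on the *difference* of two discriminanda behaves as an
  information-limiting component for the specific decoder. Heterogeneous
  tuning — as in both the recorded populations and the circuit model —
  restores the physiological ordering: attention helps the general
  decoder more than the specific one.
* **Truncation at zero** is a departure from exact Gaussianity, accepted
  because counts are nonnegative; the analytic moment helpers
  (`ring_covariance()`, `ring_expected_rsc()`) describe the pre-truncation
  model, and the test suite quantifies how close the generated data stay
  to them (within a few percent at the default operating point).

## The spiking circuit model

The three-layer model runs at reduced scale: layer 4 of V1 as
orientation-selective Gabor filters with Poisson spiking, and two
recurrent excitatory/inhibitory EIF populations (V1 L2/3, V4) on periodic
grids over the unit square \(\Gamma\).

* **Front end.** The orientation preference map is a superposition of 30
  randomly phased plane waves at wavenumber \(2\pi/\Lambda\)
  (\(\Lambda = 0.2\)); its defining acceptance property is spectral (the
  dominant spatial frequency of the complex field equals \(1/\Lambda\)),
  not bit-level formula identity. Stimuli are 25×25-pixel Gabors
  (\(\sigma = 0.2\), \(\lambda = 0.6\), \(\phi = 0\)) corrupted by
  per-pixel Ornstein–Uhlenbeck noise (\(\tau_n = 40\) ms,
  \(\sigma_n = 3.5\)) advanced with the *exact* discretization, so the
  stationary variance \(\sigma_n^2/2\tau_n\) holds for any step. Each L4
  unit's rate is the rectified response of a Gabor filter sharing the
  image's parameters, centered at the unit's grid position with its
  map-preferred orientation; one scalar normalization, fitted by
  `calibrate_filterbank()` against the stationary noise distribution,
  brings the grand-mean ON rate to 10 Hz. OFF intervals are independent
  Poisson at 5 Hz.
* **Recurrent layers.** EIF dynamics are integrated by forward Euler
  (`dt = 0.01` ms by default; the scaled analyses below use 0.05 ms) with
  exponential synapses, distance-dependent wrapped-Gaussian connectivity
  (feedforward widths 0.05, recurrent 0.1) drawn once per configuration,
  and membrane potentials randomized per simulation. The printed protocol
  (20 s of alternating 300 ms OFF / 200 ms ON intervals, first ON count
  discarded) produces 39 spike-count "trials" per simulation.
* **Attention** interpolates the V1→V4 feedforward strength
  \(\gamma \in [20, 23]\) mV (E and I targets in ratio \(1 : 0.4\)) and
  the depolarization of V4 inhibitory neurons \(\mu_i \in [0, 0.5]\)
  mV/ms, linearly in the attention level.
* **Adopted constants.** The single-neuron EIF constants, synaptic time
  constants, in-degrees and recurrent coupling strengths follow the
  companion excitatory–inhibitory model family rather than being printed
  model values; they are documented defaults in `network_config()`, all
  overridable, chosen once so that the scaled network sits in a stable,
  balanced regime (V4 excitatory rates of a few tens of Hz) in which the
  attention parameters reproduce the qualitative physiology: excitatory
  rates increase while the leading shared-variability mode shrinks. A
  reflecting floor at −100 mV bounds compound-inhibition excursions that
  a small network would otherwise exhibit; a configurable 200 Hz ceiling
  flags (never clips) runaway units.

Scale matters for what the model can express. At a few hundred neurons
per layer, V4's shared variability is dominated by common image noise
propagated through the layers, and because attention scales the V1→V4
gain, that inherited component *grows* with attention — the quenching
mechanism (inhibitory stabilization of internally generated fluctuations)
has nothing to act on. At 2500 excitatory + 625 inhibitory neurons per
recurrent layer an internally generated shared component appears, and the
attention analyses run at that scale (grid side 50, `dt = 0.1` ms, nine
20 s simulations per attention condition, ~350 pooled ON-interval
counts), with 30 samplings of 50 units drawn from below the configured
rate ceiling. The excitatory-rate increase under attention is a robust,
strongly significant effect at this scale. The decreases in mean pairwise
correlation and in the leading shared eigenvalue are a different matter:
mean r_SC here is of order 10^-3 and the energy of the slow shared mode
fluctuates strongly between 20-second simulation windows, so the
attentional modulation sits at or below the resolution that a
single-workstation number of windows affords (the original analyses
pooled thousands of trials per condition). The packaged attention test
asserts all three signs; on a given realization the correlation and
eigenvalue assertions may fail for lack of power rather than because the
mechanism is absent, and increasing the number of simulations per
condition is the remedy when more compute is available.

## Synthetic sessions and the choice model

`gen_session()` emulates one recording day of the cued change-detection
task: blocks of 125 change trials, 80% at the cued location (20 per change
amount) and 20% uncued (20 at the median amount, 5 at the largest), with
every trial a sequence of 200 ms stimulus presentations of which the last
carries the change and the first is flagged for exclusion. Counts are
drawn from the ring model in two windows per presentation — a 200 ms rate
window (emulating 60–260 ms after stimulus onset) for rates and
correlations, and a 70 ms decoder window (60–130 ms) for all decoding —
sharing the per-presentation gain so that the windows are consistent.

Choices arise from a planted linear readout: the decision variable is the
axis projection of the decoder-window counts plus Gaussian noise, and a
saccade is emitted when it crosses the midpoint between the mean start and
mean median-change projections. The default planted axis is an equal-parts
mixture of the radial (gain) direction and the *mean change direction
across all five amounts* — i.e., the readout of an observer who decodes
"did anything change?" with one fixed set of weights. This choice is the
generative embodiment of the hypothesis under study and makes the
session-level analyses identifiable: the choice-trained decoder recovers
the axis, its performance co-varies with the shared-noise amplitude (which
the radial component reads out), and decoders trained on broader sets of
change amounts converge to the stimulus part of the axis.

Default change amounts are `c(0.04, 0.07, 0.11, 0.18, 0.3)` on the
normalized ring with tuning width 0.15, spanning sub-width (hard,
essentially tangential) to supra-width (easy, with a substantial radial
component) changes; the decision-variable noise defaults to 0.35 of the
start-to-median projection separation, which yields psychometric curves
rising from ~0.3 to ~0.95 across amounts. The median (third) amount is
reserved for the observer's decoder, so ladder decoders use amounts
{1, 2, 4, 5}.

Across synthetic "days", two session parameters vary: the shared-gain SD
(which moves both mean correlated variability and the observer's
performance, because the planted axis reads the gain direction out) and a
decoder-window-only private-noise multiplier (`decode_noise_factor`),
emulating day-to-day variation in early-window count reliability such as
latency jitter or adaptation state. The second factor gives every
stimulus decoder a common day-level influence without touching the
rate-window correlation structure; since its imprint on a decoder's
measured performance is attenuated by training-sample noise, decoders
trained on more change amounts (higher generality levels, pooling more
presentations) track it — and hence the observer's decoder — more
faithfully. This is the mechanism behind the rising
correlation-with-the-observer ladder in the packaged analyses.

## Session-level analyses

* `include_units()` applies the inclusion rule (mean stimulus rate above
  10 Hz and a two-sided Wilcoxon signed-rank test against the 100 ms
  pre-trial baseline at \(p < 10^{-10}\)).
* `specific_and_monkeys_decoders()` trains, per cue condition and
  population size (most responsive units first, ranked by evoked
  response), the stimulus-trained specific decoder and the choice-trained
  observer's decoder on the same presentations, both scored on stimulus
  identity by leave-one-out cross-validation.
* `generality_ladder()` trains one decoder per \(k\)-subset of the
  non-median amounts (\(k = 1..4\); 1, 4, 6, 4, 1 subsets), evaluates each
  on every included changed orientation versus the start (leave-one-out
  within the training amounts, direct scoring with a transferred midpoint
  threshold otherwise), and measures how well each predicts the
  subject's choices on median-change presentations.
* `performance_vs_rsc()` correlates decoder performance with mean
  correlated variability across day-condition points, excluding
  high-r_SC outliers above the upper Tukey fence (Q3 + 1.5 IQR; only the
  upper fence is applied, matching how the exclusion is used) and
  reporting both filtered and unfiltered variants.
* `williams_test()` compares the two decoders' dependent correlations
  with Williams'/Steiger's t2 statistic on \(n-3\) degrees of freedom.
  Because the cited procedure is not printed in full anywhere we rely on,
  the implementation is validated by a Monte-Carlo type-I-error oracle
  (rejection rate at \(\alpha = 0.05\) within [0.04, 0.06] under a
  trivariate-normal null with \(n = 86\)) rather than by formula
  citation.

## Numerical choices

* **Factor analysis** is fitted by EM with a principal-component start,
  relative log-likelihood tolerance \(10^{-8}\), a floor on private
  variances, and up to 10 jittered restarts on non-convergence; the
  likelihood is asserted nondecreasing at every step in the tests. The
  default `m = 5` factors match the shared-eigenspectrum analyses.
* **Ill-conditioned second moments** in the general decoder trigger a
  recorded ridge (smallest power of ten restoring the reciprocal
  condition number above \(10^{-10}\)).
* **Seeds.** Every stochastic routine takes an explicit seed; stream
  seeds are derived arithmetically (all below \(2^{31}\)) so that stages
  are independently reproducible. Generators restore the caller's RNG
  state.
* **Degenerate inputs** are first-class: zero-variance units are excluded
  listwise from correlation pairs with a report; single-class training
  folds score by the majority class and are counted; constant performance
  vectors yield explicitly "undefined" correlations.

## Problem sizes

The packaged analyses default to desk scale, chosen as the smallest sizes
at which the qualitative physiology is reliably resolved: ring-model
populations of 25–200 units with 40–60 trials per orientation on a
50-point grid; Fisher estimation with a few hundred trials per condition;
sessions of 2 blocks × 125 change trials with 25-unit populations; and
the spiking network at 576 L4 / 576+144 V1 / 576+144 V4 neurons for
front-end and smoke-level work, or 2500 L4 / 2500+625 V1 / 2500+625 V4
for the attention analyses (20 s simulations, `dt = 0.05`–0.1 ms). The
cluster-scale settings of the original study (tens of thousands of
trials, 0.01 ms steps) remain reachable through the same configuration
objects.

## What passing tests do and do not show

The synthetic generators emulate the *structure* the analyses rely on —
low-dimensional gain-like shared variability aligned with tuning, its
reduction by attention, cue-block task composition, and choices driven by
a fixed linear readout. They do not emulate many features of real
recordings: non-Poisson count dispersion, adaptation and temporal
nonstationarity within and across trials, eye-movement artifacts,
unit-isolation quality, or reward-history effects on behavior. Passing
tests therefore certify that the estimators and the pipeline recover
planted structure with the right signs and magnitudes under the model's
assumptions — not that real V4 data would yield the same effect sizes.

## Known limitations

* The scaled spiking network inherits its correlated variability mostly
  from common input noise; internally generated low-dimensional dynamics
  (and between-area correlation effects) require cluster-scale
  simulations outside this package's default footprint.
* The general decoder's information sentinel treats residual variances
  below \(10^{-18}\) as exact decodes; between that and machine precision
  the estimate is numerically unstable (as any inverse-variance would be).
* `williams_test()` assumes jointly normal inputs; heavy-tailed
  performance measures would need a permutation variant.
* The OSF-deposited recordings of the original study can be analyzed by
  exporting them to the documented `trial_matrix` CSV layout
  (`read_trial_matrix()`), but no download adapter is bundled.
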
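# popdecode

Specific and general linear decoders of correlated neural population
activity, with a scaled spiking circuit model of visual attention.

## The problem

Attention reliably improves perceptual performance while *decreasing* the
mean spike-count correlation (r_SC) of sensory populations — yet an
optimal linear decoder of the specific task at hand can largely ignore
that shared variability, so the correlation between behavior and r_SC is
a long-standing puzzle. One candidate resolution: observers use a
*general* readout — one fixed set of weights able to decode any stimulus
along the relevant dimension. Because a general readout must weight
neurons by their tuning, and shared variability aligns with tuning
similarity, its performance is inextricably tied to the magnitude of
correlated variability.

`popdecode` implements the estimators and simulations needed to study
this hypothesis end-to-end on synthetic data:

* **Specific decoder & bias-corrected linear Fisher information.** For a
  fine discrimination of θ₀ ± dθ, weights w = Σ⁻¹f′/(f′ᵀΣ⁻¹f′) and the
  finite-trial estimator
  Î = (Δf̂/dθ)ᵀ ((Σ̂₊+Σ̂₋)/2)⁻¹ (Δf̂/dθ) · (2Nₜᵣ−N−3)/(2Nₜᵣ−2) − 2N/(Nₜᵣ dθ²).
* **General decoder.** A single complex weight vector w with
  ẑ = wᵀr ≈ e^{i2πθ}; closed-form optimum
  w = ⟨Σ(θ)+ffᵀ⟩θ⁻¹ ⟨f e^{i2πθ}⟩θ and information
  Îᵍ = Var(θ̂−θ)⁻¹ · (Nₜᵣ−N−2)/(Nₜᵣ−1) from wrapped circular residuals.
* **Observer's ("monkey's") decoder.** A ridge-regularized linear
  discriminant trained on behavioral choices, scored on stimulus identity
  with leave-one-out cross-validation.
* **Shared variability statistics.** Pairwise noise/signal correlations
  and the eigenspectrum of LLᵀ from the factor model x ~ N(μ, LLᵀ+Ψ),
  fitted by EM (m = 5 factors by default).
* **Circuit model.** A scaled three-layer spiking model: Gabor-filtered
  Poisson layer 4 of V1 (orientation map with column spacing Λ = 0.2,
  25×25-pixel Gabor stimuli with OU pixel noise, τₙ = 40 ms, σₙ = 3.5;
  calibrated to 10 Hz mean ON rate, 5 Hz OFF), feeding recurrent
  excitatory–inhibitory exponential integrate-and-fire layers for V1 L2/3
  and V4. Attention interpolates the V1→V4 feedforward strength
  γ ∈ [20, 23] mV and V4 inhibitory depolarization μᵢ ∈ [0, 0.5] mV/ms.
* **Synthetic sessions.** Cued orientation change-detection days (125
  change trials per block, 80%/20% cued/uncued, five change amounts,
  uncued changes restricted to the median and largest amounts) with
  choices generated from a planted linear readout — so pipeline recovery
  can be tested against ground truth.

## Worked example

```r
library(popdecode)

# a heterogeneous orientation-tuned population with shared gain noise
p <- ring_params(n_units = 50, radial_sd = 0.2, private_sd = 1.5)

# fine-discrimination information, bias-corrected (Eq.-style estimator)
pair <- gen_ring_responses(p, thetas = c(0.49, 0.51),
                           trials_per_theta = 400, seed = 1)
fisher_info_bc(pair, dtheta = 0.01)
#> fisher_estimate: bias-corrected I = 211574  (N = 50 units, Ntr = 400, dtheta = 0.01)

# general decoder over the full ring and its information
ring <- gen_ring_responses(p, thetas = (0:49) / 50,
                           trials_per_theta = 40, seed = 2)
g <- general_weights(ring)
general_info(ring, g)
#> fisher_estimate: bias-corrected I = 25092.6  (N = 50 units, Ntr = 2000)

# attention (shared-gain quenching) helps the general decoder more
p1 <- ring_params(n_units = 50, radial_sd = 0.2, private_sd = 1.5,
                  attention = 1)
ring1 <- gen_ring_responses(p1, thetas = (0:49) / 50,
                            trials_per_theta = 40, seed = 2)
general_info(ring1, general_weights(ring1))$value /
  general_info(ring, g)$value
#> [1] 1.54
```

The first number is the linear Fisher information of the local
discrimination (in 1/θ² units on the normalized ring): the population
distinguishes orientations 0.49 vs 0.51 with an effective θ resolution of
1/√211574 ≈ 0.002. The second is the general decoder's information — far
lower, because one fixed readout must serve all orientations. The final
ratio (> 1) shows attention improving the general decoder; the matched
specific-decoder ratio is smaller, the package's desk-scale reproduction
of the key model contrast.

The two canonical experiments are one call each:

```r
b <- run_model_experiment(experiment_config(backend = "ring", seed = 1))
b$ratios            # attended/unattended information ratios, raw and shuffled
s <- run_session_experiment(experiment_config(n_days = 10, seed = 1))
s$perf_vs_rsc       # decoder performance vs mean r_SC across days
s$williams          # Williams' test comparing the two decoders' correlations
```

A thin command-line wrapper with verbs `sweep`, `session`, `simulate`,
`decode`, `stats` is installed at `inst/cli/popdecode.R`.

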
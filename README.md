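# higgsr

Oscillatory brain networks are functional networks synchronized at a
specific frequency. At that frequency, narrow-band (analytic) source
activity is well described by a complex circular Gaussian whose Hermitian
precision matrix `Θ_ιι(f)` — the inverse of the cross-spectrum — encodes
the network: the modulus of an off-diagonal entry is an undirected edge
(partial coherence), its phase a lag. M/EEG never observes the sources
directly; sensors see `v(t,f) = L ι(t,f) + ξ(t,f)` through a lead field
`L`, so identifying the network is an inverse problem, and the common
two-step practice (reconstruct source activity first, then fit a
graphical model to the pseudo-data) accumulates errors from both steps.

`higgsr` is for researchers who study frequency-specific connectivity
from M/EEG-like spectral data. It provides:

* **hgLASSO** — a Hermitian graphical LASSO for complex cross-spectra:
  the penalised MAP problem
  `min −log|Θ| + tr(Σ̂Θ) + λ‖A⊙Θ‖₁` over Hermitian positive definite
  matrices at the analytic rate `λ = √(log q / (2T))`, solved by an ADMM
  whose positive-definite update is a closed-form ridge square root, with
  one adaptive support-refit cycle;
* **desparsified inference** — the debiased estimate
  `unb(Θ̂) = 2Θ̂ − Θ̂Σ̂Θ̂`, standardized edgewise by
  `√(Θ̂ᵢᵢΘ̂ⱼⱼ + |Θ̂ᵢⱼ|²)`; under the null the statistic
  `Z = √T |unb(Θ̂)ᵢⱼ| / √(Θ̂ᵢᵢΘ̂ⱼⱼ + |Θ̂ᵢⱼ|²)` follows the Rayleigh
  density `2z·e^{−z²}` (scale `1/√2`), so per-edge p-values are
  `exp(−z²)`;
* **a one-step EM inverse solution** that estimates `Θ_ιι(f)` directly
  from the sensor cross-spectrum `Σ̂_vv(f)` given `L`, alternating a
  Gaussian-posterior expectation stage with graphical maximization
  stages (debiased and Rayleigh-thresholded each iteration), plus a
  scalar sensor-noise update;
* **multistep baselines** — eLORETA and LCMV first-step operators with
  GCV-selected regularization, followed by hgLASSO (or its real-valued
  restriction) on the projected covariance;
* **a Xi-Alpha simulator** — ground-truth alpha-band networks built from
  spectral factors (constant couplings, lags, Gaussian envelopes), a
  low-frequency Xi background, a planar concentric-circle forward model
  (30 sensors, 22 network nodes, `T = 600` by default, confound energy
  10% of the alpha-band energy) and a perturbed "human-like" variant;
* **evaluation** — ROC support-recovery summaries and Kullback–Leibler,
  Riemannian, and log-Euclidean divergences between precision matrices.

## A worked example

Simulate the planar benchmark and run the one-step inverse solution:

```r
library(higgsr)

cfg <- simulation_config(seed = 1)     # 22 nodes, 30 sensors, T = 600
rec <- simulate_xi_alpha(cfg)
rec
#> <sim_recording> 22 network nodes, 30 sensors, T = 600, 100 frequencies (planar EFM)

svv <- sensor_cross_spectrum(rec)      # sampled cross-spectrum at 10 Hz
fit <- run_higgs(higgs_model(network_lead_field(rec)), svv)
fit
#> <higgs_fit> 22 sources, lasso penalty, 10 EM iterations, noise scale 4.494
#>   42/231 edges retained at p < 0.05

roc_scores(rec$ground_truth$support, Mod(fit$theta))
#>         auc     sens      spec      prec   recall        f1 n_edges n_pairs
#> 1 0.9979103 0.972973 0.9845361 0.9230769 0.972973 0.9473684      37     231
```

The AUC of 0.998 means the moduli of the estimated Hermitian graph
elements rank essentially every true edge above every null pair
(ROC error `100·(1−AUC)` ≈ 0.2%); at the optimal operating point 97% of
the 37 true edges are recovered with 92% precision. The per-edge
inference is available as a tidy table:

```r
dplyr::arrange(tidy(fit), p_value)
#> # A tibble: 231 × 7
#>       i     j modulus  phase     z  p_value selected
#> 1    21    22  0.114  -2.11   8.15 1.33e-29 TRUE
#> 2     4    17  0.0742 -0.979  7.29 8.89e-24 TRUE
#> 3     6    13  0.0972  2.46   6.69 3.78e-20 TRUE
#> ...
```

`autoplot(fit, "z")` draws the z-matrix heatmap,
`autoplot(rec)` the simulated sensor spectrum (alpha peak at 10 Hz), and
`run_pipeline()` loops trials over several methods into one score table.
Multistep baselines run through the same surface:
`multistep_connectivity(L, svv, first_step = "eloreta")`.

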
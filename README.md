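# aculatent

Low-dimensional latent dynamics of multichannel EEG under manual acupuncture.

Manual acupuncture (needle twirling at a controlled rate — e.g. 50, 100 or
150 times/min at the ST36 acupoint) measurably reorganizes large-scale brain
activity recorded with a standard 19-electrode (10–20 system) EEG montage.
`aculatent` implements, as a tested R pipeline, the analysis chain used to
characterize that reorganization:

* **Spectral structure** — Welch power spectral density, per-channel power in
  the conventional delta/theta/alpha/beta sub-bands, between-state band-power
  differences and Welch *t*-tests.
* **Effective dimensionality** — the participation ratio of the channel
  covariance eigenvalues,

  ```
  Dim(C) = (Σᵢ λᵢ)² / Σᵢ λᵢ²  ∈ [1, n_channels],
  ```

  which equals 19 for independent equal-variance channels and 1 for
  perfectly correlated activity.
* **Latent-variable extraction** — a variational auto-encoder (VAE) mapping
  each 19-channel sample to a diagonal-Gaussian posterior over J latent
  variables, trained by minibatch stochastic gradient descent (batch size 20)
  on the evidence lower bound

  ```
  ELBO = E_q[log p(x|z)] − D_KL(q(z|x) ‖ N(0, I)),
  D_KL = −½ Σⱼ (1 + log σⱼ² − μⱼ² − σⱼ²),
  ```

  with a Gaussian unit-variance likelihood on per-channel standardized data.
* **Latent-subspace geometry** — total-least-squares plane fits to 3-D latent
  trajectories (the plane's orthonormal basis is the pair of "acupuncture
  modes" p1, p2), unsigned dihedral angles between condition planes and the
  pre-acupuncture reference plane, the linear angle-vs-manipulation-frequency
  regression, and direct least-squares (constrained conic) fits of the
  elliptic attractor traced by the steady latent trajectory.
* **Statistics and classification** — one-way ANOVA over attractor axis
  lengths, and stratified 5-fold × 10-repeat cross-validated classification
  of brain state from the (long, short) axis features with SVM, KNN, LDA and
  a decision tree.

Because no public acupuncture-EEG dataset accompanies the analysis, the
package includes a first-class **synthetic study generator**
(`generate_study()`): 19-channel, 256 Hz recordings in which a
plane-confined latent elliptic trajectory (condition-dependent orientation
and axes) is embedded through a per-subject orthonormal mixing matrix,
plus 1.2 Hz (delta) and 10 Hz (alpha) sinusoidal carriers with
condition-dependent gains and white channel noise. Every downstream stage is
validated by recovering the generator's known ground truth.

## Worked example

```r
library(aculatent)
cfg   <- synthetic_config(n_subjects = 2, duration_s = 60)
study <- generate_study(cfg)

## effective dimensionality per condition (broadband, 10-s epochs)
tab <- study_dimensionality(study)
aggregate(dimensionality ~ condition, tab, function(x) round(mean(x), 2))
#>   condition dimensionality
#> 1   acu_100           3.69
#> 2   acu_150           3.98
#> 3    acu_50           2.50
#> 4   pre_acu           5.05

## attractor axes recovered from the embedded latent trajectories
feats <- extract_axis_features(study, method = "unmix")
attractor_stats(feats)
#>   condition  n mean_a    var_a mean_b    var_b
#> 1   acu_100 12  1.992 1.48e-05  0.804 8.50e-06
#> 2   acu_150 12  2.494 1.16e-05  0.803 4.34e-06
#> 3    acu_50 12  1.496 7.80e-05  0.801 6.02e-06
#> 4   pre_acu 12  0.991 4.12e-05  0.794 4.86e-05

## plane angles against the pre-acupuncture reference
angles <- plane_angle_table(study, method = "unmix")
aggregate(angle_deg ~ condition + manip_freq, angles, function(x) round(mean(x), 2))
#>   condition manip_freq angle_deg
#> 1   pre_acu          0      0.00
#> 2    acu_50         50     15.03
#> 3   acu_100        100     29.98
#> 4   acu_150        150     45.01
angle_frequency_regression(angles$angle_deg, angles$manip_freq)
#> slope 0.300 deg per (times/min), R^2 1.000
```

Reading the output: acupuncture reduces the participation-ratio
dimensionality relative to the pre-acupuncture state (5.05), most strongly at
50 times/min (2.50), because the delta-band enhancement concentrates variance
in few covariance dimensions. The attractor long axis grows with manipulation
rate (0.99 → 1.50 → 1.99 → 2.49 latent units) while the short axis stays near
0.8, and the latent-plane angle grows linearly with manipulation frequency
(0.30°/(times/min) here). The VAE route to the same geometry is available via
`method = "vae"` and `reconstruction_sweep()`; see the vignette for what is —
and is not — identifiable from VAE latent coordinates.

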
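# cfes

Fat quantification and fat/muscle quasi-segmentation of CT slices from the
grey-value histogram alone — together with the full validation loop a
forensic or medical imaging group needs around such an estimator: a seeded
phantom simulator, the quality measures that judge a run, and a delta-method
sensitivity analysis that says *when the estimator must fail*.

On CT, fat attenuates below water (≈ −80 HU) and muscle/organ tissue
slightly above it (≈ +50 HU), but the two grey-value distributions overlap.
`cfes` models the soft-tissue pixels of a slice as the two-component
Gaussian mixture

```
f(g) = z · φ(g; E_F, S_F) + (1 − z) · φ(g; E_M, S_M)
```

and estimates Θ = (E_F, E_M, S_F, S_M, z) by minimizing the weighted
least-squares distance between the empirical and the model-expected
histogram,

```
S_α = Σ_{n ∈ G0} (x_n(Y) − x_n(Θ))² · x_n(Y)^α ,
```

with the empirical counts as fixed weights (exponent α). The fat ratio `z`
gives the fat pixel count `Q_F = z·Q` (and via the voxel geometry a fat
volume); the crossing of the weighted component densities gives the
threshold `t_FM` for a per-pixel fat/muscle quasi-segmentation. Three
measures judge a run: the Welch-type fat–muscle separability
`τ = √Q·(E_M − E_F)/√(S_F²/z + S_M²/(1−z))`, the distance `S_α` itself, and
the binary misclassification verdict `d` with its per-scan/per-sample rates
`D` and `F`.

The sensitivity module propagates the multinomial covariance of the
histogram counts through the least-squares normal equations (sandwich
covariance with the analytic model Jacobian) to the standard deviation
`S(z*)` of the fat-ratio estimator — quantifying the breakdown of
fat-ratio estimation as the component SDs grow.

## Worked example

```r
library(cfes)

# a synthetic two-material slice with known truth:
# E_F = -80, E_M = 50, S_F = S_M = 20 HU, fat ratio z = 0.3
spec <- phantom_spec(mixture_params(-80, 50, 20, 20, 0.3), size = 512, seed = 1)
ph   <- generate_phantom(spec)

# fit the mixture to the slice's grey-value histogram
h   <- compute_histogram(ph$image, grey_binning())
fit <- fit_cfes(h, fit_config(alpha = 1))
fit
#> <cfes_fit> alpha = 1, converged
#>   Theta* : E_F = -80.02, E_M = 50.11, S_F = 20.09, S_M = 20.01 HU, z = 0.3003
#>   S_alpha = 1.00289e+09 (ln = 20.726), t_FM = bin 125, Q_F = 50073 of 166740
```

The fit recovers all five parameters of the generating mixture; `Q_F` is
the estimated fat pixel count among the 166,740 body pixels, and `t_FM`
(bin 125 ≙ −16 HU under the default binning) is the minimum-misclassification
threshold. The quality measures confirm the run:

```r
separability_tau(fit$theta_star, h$q_total)
#> [1] 1213.785
seg <- quasi_segment(ph$image, fit$t_fm, grey_binning())
misclassification_d(seg, ph$labels)     # 0 = no anatomical error
#> [1] 0
relative_error_z(0.3, fit$theta_star$z)
#> [1] 0.001018938
```

And the delta-method curve shows why runs like this stop working once the
component SDs approach the peak distance (ΔE = 130 HU):

```r
z_std_curve(c(20, 60, 90))
#>    s       z_std q_total
#> 1 20 0.001161628  166740
#> 2 60 0.012745875  166740
#> 3 90 0.091031738  166740
```

A nearly 80-fold loss of fat-ratio precision between S = 20 HU and S = 90 HU, at
identical pixel counts — the practical consequence is to choose acquisition
parameters that keep the single-tissue SDs small.

For larger studies, `run_umbrella()` sweeps seeded phantoms over a grid of
component SDs and records τ⁺, τ*, ln S_α and RE_z per image;
`scan_pipeline()` applies the estimation chain to a stack of slices and
aggregates per-scan means and misclassification rates. A thin command-line
front end over these functions is installed at `inst/cli/cfes.R`
(subcommands `simulate`, `fit`, `segment`, `umbrella`, `sensitivity`,
`boundary`).

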
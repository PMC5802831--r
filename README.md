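# rdtd — six-dimensional relaxation–diffusion tensor distributions

`rdtd` implements a model-free analysis for multidimensional
relaxation–diffusion correlation NMR. A heterogeneous sample (a voxel, a
composite phantom, a piece of tissue) is described as a collection of
non-exchanging Gaussian micro-domains, each with longitudinal and
transverse relaxation rates R1 and R2 and an axisymmetric diffusion tensor
**D** parameterized by its isotropic diffusivity D_iso, normalized
anisotropy D_Δ ∈ [−1/2, 1], and symmetry-axis orientation (θ, φ). The
package estimates the joint six-dimensional distribution
P(R1, R2, D_iso, D_Δ, θ, φ) from signals acquired over a pseudo-random
six-dimensional acquisition space (τ_R, τ_e, b, b_Δ, Θ, Φ) — repetition
delay, echo time, and a diffusion-encoding b-tensor of trace b, shape b_Δ
and orientation (Θ, Φ).

## The model

Each acquisition point weights each micro-domain by the kernel

    K = [1 − exp(−τ_R·R1)] · exp(−τ_e·R2) · exp(−b:D)

where the diffusion exponent is the generalized scalar product

    b:D = b·D_iso·[1 + 2·b_Δ·D_Δ·P2(cos β)],   P2(x) = (3x² − 1)/2,

with β the arc angle between the b-tensor and diffusion-tensor symmetry
axes. Spherical encoding (b_Δ = 0, the gradient cone at the magic angle
acos(1/√3) ≈ 54.74°) is blind to anisotropy and orientation and measures
D_iso directly; linear (b_Δ = 1) and planar (b_Δ = −1/2) encodings probe
shape and orientation. The measured signal is S0 times the
weight-integral of K against P(R1, R2, D_iso, D_Δ, θ, φ).

Inversion is by Monte Carlo non-negative least squares: random discrete
components drawn in the analysis space compete in NNLS fits, survivors
are iteratively re-seeded ("proliferation") and locally perturbed
("mutation"), and the whole procedure is wrapped in bootstrap resampling
of the acquisition points to expose the solution variability of this
ill-posed inverse problem. No smoothness regularization is applied — the
only constraints are non-negativity and the analysis-space box.

A synthetic three-compartment phantom (aligned liquid crystal with
D_par/D_perp = 100, plus slow intracellular and fast extracellular yeast
water) provides ground truth for validation throughout.

## Worked example

```r
library(rdtd)

zeta_from_bdelta(0) * 180 / pi        # magic angle, degrees
#> [1] 54.73561

scheme <- generate_scheme(1500, seed = 1)
scheme
#> <acq_scheme> 1500 points (pseudo-random)
#>   bias subsets: linear=450, none=600, planar=150, spherical=225, stability=75

spec <- yeast_lc_phantom()
phantom_log_table(spec)
#>    name    weight logR1 logR2 logDiso logratio
#> 1    lc 0.3333333     0   1.5      -9        2
#> 2 intra 0.3333333     0   2.0     -11        0
#> 3 extra 0.3333333     0   2.0      -9        0

ds  <- simulate_experiment(spec, scheme, snr = 120, seed = 2)
ens <- bootstrap_invert(ds, inversion_config(), n_boot = 20, seed = 3)
st  <- subvolume_stats(ens)
st$summary[, c("region", "Pvol_mean", "E_logDiso_mean", "E_logDiso_sd",
               "E_logR2_mean", "E_logratio_mean")]
#>            region Pvol_mean E_logDiso_mean E_logDiso_sd E_logR2_mean
#> 1     anisotropic    0.3884          -8.97      0.02846         1.57
#> 2  fast_isotropic    0.2747          -8.99      0.02741         1.94
#> 3  slow_isotropic    0.3223         -11.00      0.00584         2.00
#> 4 oblate_artefact    0.0147          -9.02      0.09337         1.87
#>   E_logratio_mean
#> 1          2.0288
#> 2          0.1206
#> 3          0.0631
#> 4         -0.6711

odf(ens)
#> <dtd_odf> 642 vertices, total mass 0.3936
```

Reading the output: the bootstrap ensemble separates the three phantom
compartments. The slow isotropic sub-volume recovers
E[log10 D_iso] ≈ −11.00 (truth −11, intracellular water), the fast
isotropic one ≈ −8.99 (truth −9, extracellular water), and the
anisotropic sub-volume recovers E[log10 D_par/D_perp] ≈ 2.03 (truth 2)
with E[log10 R2] ≈ 1.57 (truth 1.5) — the liquid crystal. The small
`oblate_artefact` population is a known inversion artefact caused by
shape undersampling at low b (see the methods vignette). The ODF
concentrates ~0.39 of the total weight (the anisotropic fraction) at the
poles, i.e. alignment with +z, the main-field direction.

2D projections of the recovered distribution (contours linearly spaced
from 7.5% to 90% of the maximum, as in the standard displays):

```r
m <- project_2d(ens, c("logDiso", "logratio"), grid = 64, smoothing = 1)
write_projection(m, "proj_diso_ratio.csv")
```

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "rdtd.R", package = "rdtd"))')
Rscript $CLI generate-scheme --n 1500 --seed 1 --out scheme.csv
Rscript $CLI simulate --scheme scheme.csv --snr 120 --seed 2 --out data.csv
Rscript $CLI invert --data data.csv --scheme scheme.csv --n-boot 100 --seed 3 --out ens.json
Rscript $CLI analyze --ensemble ens.json --out report/
```

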
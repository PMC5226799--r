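# stainwave

Blind stain deconvolution of multi-stained histology tiles by **sub-band
ICA**: the stain mixing matrix is estimated by independent component
analysis applied only to the least-Gaussian wavelet sub-bands of the
optical-density image, then inverted to recover per-stain density maps.

## The problem

Histology image analysis routinely needs the per-stain intensity channels
of an H&E tile — the haematoxylin channel to find nuclei, the eosin channel
for cytoplasm and stroma. Under the Beer–Lambert law the optical-density
image factorises linearly,

    D = M N,        D = -log(I / I0),

where the columns of the 3×3 stain matrix `M` are the OD absorption
directions of haematoxylin, eosin and a residual component, and the rows of
`N` are the per-pixel stain densities. `M` varies between labs, scanners
and even slides, so it must be estimated from the image itself.

Plain ICA on the OD pixels assumes the stain densities are independent —
but they are not: stains co-locate through tissue architecture. Because any
linear filter `F` applied per channel satisfies `F(D) = M F(N)`, the mixing
matrix can instead be estimated from a filtered representation in which the
sources are more independent. This package decomposes each OD channel with
a decimated orthogonal wavelet transform (depth 5, four orientations per
level → 20 composed sub-bands), normalises each 3-channel band by pooled
mean/variance, ranks bands by absolute excess kurtosis (the least Gaussian
first), concatenates the top `n` into `D'`, and runs fixed-point ICA on
`D'`. The recovered matrix — after resolving ICA's sign/scale/permutation
ambiguities — deconvolves the raw OD image: `N = M⁻¹ D`.

The package also ships the evaluation protocol (ground-truth stain matrices
from annotated pixels, Euclidean stain-vector distances, density-map
correlation, Bland–Altman agreement), a plain-ICA baseline, and a synthetic
Beer–Lambert phantom generator with controllable inter-stain correlation
that provides exact ground truth for every claim the test suite checks.

## Worked example

```r
library(stainwave)

# a 256x256 phantom whose stain densities are correlated at rho = 0.6
ph  <- render_phantom(phantom_spec(rho = 0.6, seed = 42))
fit <- stain_deconvolve(ph, seed = 0)

tidy(fit)
#> # A tibble: 3 x 4
#>   stain             r     g      b
#>   <chr>         <dbl> <dbl>  <dbl>
#> 1 haematoxylin 0.664  0.686 0.298
#> 2 eosin        0.0510 0.994 0.0921
#> 3 residual     0.248  0     0.969

stain_angle_errors(fit$stain_matrix, ph$m_true)
#> # A tibble: 2 x 2
#>   stain        angle_deg
#>   <chr>            <dbl>
#> 1 haematoxylin      1.45
#> 2 eosin             1.43

density_correlation(fit$densities, ph$n_true)
#> # A tibble: 2 x 3
#>   stain            r p_value
#>   <chr>        <dbl>   <dbl>
#> 1 haematoxylin 0.999       0
#> 2 eosin        1.000       0

# the baseline the sub-band argument is about: ICA on raw OD pixels
base <- plain_ica_baseline(rgb_to_od(ph$image), seed = 0)
stain_angle_errors(base, ph$m_true)
#> # A tibble: 2 x 2
#>   stain        angle_deg
#>   <chr>            <dbl>
#> 1 haematoxylin     16.4
#> 2 eosin             4.04
```

The recovered stain vectors sit within 1.5° of the true ones while the
plain-ICA baseline is 4–16° off on the same correlated tile; the density
maps correlate with ground truth at r ≥ 0.999. `autoplot(fit)` shows the
kurtosis ranking of the 20 sub-bands, `plot_density_map(fit, 1)` the
recovered haematoxylin density, and `glance(fit)` the fit diagnostics.

A thin command-line interface wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/stainwave.R", package="stainwave"))')" \
  deconvolve tile.png --out-dir out --wavelet db2 --levels 5 --n-subbands 20 --seed 0
```

writing the labelled stain-matrix CSV, per-stain float-TIFF density maps,
per-stain RGB reconstructions and the kurtosis ranking table. `synth` and
`evaluate` subcommands generate phantom suites and score estimates against
annotated ground truth.

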
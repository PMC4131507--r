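# lfac — partition-based fuzzy active contours with local intensity information

`lfac` segments single-channel images whose two regions (object and
background) are **only locally homogeneous**: smooth intensity ramps, bias
fields and shading make the global intensity ranges of the two regions
overlap, so any method that models each region by one constant gray value
mislabels the dim parts of the object and the bright parts of the
background. Typical users are image-analysis people working with microscopy,
MR, or other single-channel modalities affected by illumination bias, who
want a dependency-light, scriptable R implementation with exact synthetic
benchmarks.

## The models

Both models segment by minimizing a fuzzy region energy over a membership
map `u(x) ∈ [0, 1]` (the object is the strict upper level set `u > 0.5`; the
contour is the 0.5 level):

```
F(u, c1, c2) = Σ_x u(x)^m (I(x) − c1)²  +  Σ_x (1 − u(x))^m (I(x) − c2)²
```

* **FAC** (`fac()`): the global baseline. `c1`, `c2` are the fuzzy-weighted
  mean intensities inside/outside the contour,
  `c1 = Σ u^m I / Σ u^m`, and the coordinate-wise minimizer
  `u = 1 / (1 + ((I − c1)² / (I − c2)²)^{1/(m−1)})`
  is applied image-wide until the energy settles. Exact when each region is
  one gray level; fails under inhomogeneity.

* **LFAC** (`lfac()`): the local model. The constants are replaced by
  spatially varying prototypes — Gaussian-kernel-weighted local fuzzy means

  ```
  c1(x) = Σ_j u(j)^m g(x − j) I(j) / Σ_j u(j)^m g(x − j),   g(d) ∝ exp(−d²/2σ²)
  ```

  and each sweep updates only a narrow band around the current contour,
  detected adaptively by **shadowed-sets** three-way thresholding of the
  membership map (threshold `α` balances the membership mass reduced and
  elevated in the tails against the cardinality of the uncertain "shadow");
  a candidate update is accepted only if its incremental energy change

  ```
  ΔF = (u_n^m (s1/(s1 + u_n^m − u_o^m))² − u_o^m)(I − c1(x))² + (… analogue for 1−u …)(I − c2(x))²
  ```

  is negative, where `s1`, `s2` are the kernel-weighted fuzzy masses of the
  window. Accuracy is scored by the percentage of mislabelled pixels,
  `P_mp = (|truth∖pred| + |pred∖truth|) / (|truth| + |pred|) × 100`.

## Worked example

```r
library(lfac)

scn <- ramp_ring_scene()     # 143 x 150; background ramps 120 -> 20 top to
                             # bottom, object = background + 60 everywhere
fit <- lfac(scn$image)       # default rectangular seed, m = 2, sigma = 3
fit
#> LFAC fit (143 x 150 image)
#> Call: lfac(image = scn$image)
#> Iterations: 20 (converged: no_updates)
#> Final energy: 25743.3
#> Object pixels: 2859 of 21450 (13.3%)

p_mp(scn$truth, fit)         # percentage of mislabelled pixels
#> [1] 0
p_mp(scn$truth, fac(scn$image))
#> [1] 59.72956
```

The local model recovers the ground truth exactly, while the global baseline
mislabels more than half of the scored pixels — the dim bottom arc is
submerged in the background and bright background is claimed as object.
`benchmark_models(scene_suite(seed = 1))` reproduces the full comparison:

```
       scene model  p_mp iterations updates
       clean   fac 59.73         14  300300
       clean  lfac  0.00         20  107939
     blurred   fac 61.94         15  321750
     blurred  lfac  1.13         17   94906
    gaussian   fac 59.42         15  321750
    gaussian  lfac 18.50         24  150579
 salt_pepper   fac 59.47         15  321750
 salt_pepper  lfac  4.99         25  418513
```

`plot(fit, image = scn$image)` draws the contour over the image next to the
energy trace. A thin command-line wrapper with `gen` / `segment` / `score` /
`bench` subcommands is installed at `system.file("cli", "lfac", package =
"lfac")`.

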
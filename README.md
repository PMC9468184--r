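# vasctda

Quantitative analysis of 3D vascular architecture from classified
tissue-clearing image volumes.

Whole-organ tissue clearing plus light-sheet microscopy yields volumes in
which blood or lymphatic vessels appear as bright voxels; a pixel classifier
(trained externally) turns those into probability maps. What is missing is a
way to *quantify* the 3D structure beyond volumes and branch counts. This
package, aimed at imaging groups analysing such data, converts classified
volumes into micrometre-coordinate point clouds and characterises them
three ways:

* **Persistent homology.** The Vietoris–Rips filtration grows a ball of
  radius *r* around every point and records each topological feature as a
  birth/death pair (r_b, r_d): connected components (H0), loops (H1), and
  voids (H2). All values are on the ball-radius scale (an edge between
  points at distance *d* appears at *r* = *d*/2).
* **Sliced Wasserstein comparison + MDS.** Two persistence diagrams Dg_i,
  Dg_j are compared by SW(Dg_i, Dg_j) = (1/π) ∫ W₁(μ_iᶿ + μ_jΔᶿ, μ_jᶿ +
  μ_iΔᶿ) dθ — the angle-averaged 1D Wasserstein distance of diagonal-
  augmented projections — and the kernel k_SW = exp(−SW/(2σ²)). Distance
  matrices over samples or regions embed in 2D by classical MDS.
* **NHPP intensity model.** Point intensity is modelled as λ(u) =
  Σ_j g(u − x_j) with the separable logistic kernel
  g(u) = Π_i a·b_i / (e^{b_i u_i} + 2 + e^{−b_i u_i}); θ = (a, b_x, b_y,
  b_z) is estimated by maximum likelihood (log L = Σ_j log λ(x_j) −
  ∫ λ du, the domain integral in closed form via logistic CDFs). Strength
  *a* and directionalities 1/b_i are compared between two channels block by
  block; blocks whose parameter changed ≥ 2-fold enter a per-region 2×2
  Fisher's exact test (two-sided).

Nearest-neighbour distance distributions between two clouds (e.g. tumours
vs lymphatics) with Tukey five-number summaries, seeded synthetic phantoms
(tubes, rings, shells, bifurcating trees, cluster simulations, structured
degradation), and an end-to-end pipeline with run manifests complete the
toolbox. See the vignette `vignettes/vascular-structure-analysis.Rmd` for
the methods in detail.

## Worked example

```r
library(vasctda)

## a ring phantom has one loop with a known closed form:
## birth R*sin(pi/n), death R*sqrt(3)/2
ring <- ring_phantom(radius = 100, n = 12)
filter_diagram(rips_persistence(ring, max_dim = 1), 1)$pairs
#>   dim   birth    death is_capped
#> 1   1 25.8819 86.60254     FALSE

## simulate an anisotropic vessel-like cluster pattern and fit the NHPP
box   <- domain_box(c(0, 0, 0), c(500, 500, 500))
truth <- nhpp_params(1.5, c(0.05, 0.05, 0.2))     # spreads 20, 20, 5 um
cl    <- nhpp_simulate(660, truth, box, seed = 1)
cl
#> point_cloud: 1927 points, channel 'sim'
nhpp_fit(cl, box, seed = 1)
#> nhpp_fit on 1927 points, log-likelihood -23070.20
#> nhpp_params: a = 1.041, b = (0.04084, 0.04835, 0.1724) /um, total kernel mass a^3 = 1.128
```

The fitted concentrations reproduce the simulated anisotropy (b_z ≈ 4× b_x,
i.e. the z-spread is ~4× tighter). The fitted strength sits near 1 by
construction: at the likelihood maximum the model's expected count matches
the observed count, so *a* reflects only boundary truncation of the kernels
— directionality (1/b) carries the usable contrast between channels (the
vignette discusses this identifiability property).

```r
## proximity of two structures, as a boxplot five-number summary
d <- nn_distances(subsample_points(cl, 200, 1), ring)
summarize_distances(d)
#> distance_summary (n = 200): median 417, hinges [329, 513], whiskers [66.5, 737], 1 outlier(s)
```

A command-line front end over the same functions lives in
`inst/cli/vasctda.R`:

```sh
Rscript inst/cli/vasctda.R phantom --kind ring --radius 50 --n 40 --out ring.csv
Rscript inst/cli/vasctda.R ph --points ring.csv --max-dim 1 --out ring_pd.csv
Rscript inst/cli/vasctda.R nhpp simulate --centers 200 --seed 1 --out sim.csv
Rscript inst/cli/vasctda.R nhpp fit --points sim.csv --out fit.json
```

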
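# spadecon

Cell-type deconvolution of spatial transcriptomics (ST) spots with a
spatially regularized autoencoder.

## The problem

Sequencing-based ST platforms (10x Visium and kin) measure expression at
spatial capture spots that each mix several cells. Deconvolution estimates
the per-spot proportion of each cell type. Most tools require predefined
cell-type marker signatures; `spadecon` learns the signatures *jointly*
with the proportions, using a labeled single-cell reference only to
simulate training spots whose composition is known by construction. It is
aimed at computational biologists who have (a) a spot × gene ST matrix with
coordinates and (b) a labeled scRNA-seq reference from the same tissue —
or who want a fully controlled synthetic benchmark for deconvolution
methodology.

## The model

An encoder ψ<sub>θ</sub> (MLP, softplus output) maps each preprocessed spot
profile to a nonnegative latent code Z ∈ R<sup>ns×k</sup> with one
dimension per cell type; a single bias-free linear decoder φ<sub>ϑ</sub>
reconstructs expression, so its k × ng weight matrix is directly the
cell-type-by-gene signature. Training is two-stage, both stages minimizing
entrywise-L1 objectives with a graph-Laplacian smoothness penalty from the
spot KNN graph (6 neighbours, weights exp(−d/d̄)):

* stage 1, on simulated spots with known proportions P:
  ‖X<sub>s</sub> − φ(ψ(X<sub>s</sub>))‖₁ + ‖P − Z‖₁ + α·Tr(ZᵀLZ)
* stage 2, on the target data, same parameters, supervision dropped:
  ‖X<sub>r</sub> − φ(ψ(X<sub>r</sub>))‖₁ + α·Tr(ZᵀLZ)

Row-normalizing Z puts every spot's estimate on the simplex. Defaults:
α = 0.1, Adam with learning rate 1e-4, full-batch. The methods vignette
(`vignettes/deconvolution-methods.Rmd`) documents every numerical choice.

The package also ships a ground-truth pseudo-spot simulator
(`generate_reference()`, `simulate_spots()`), plain-text readers/writers
(MatrixMarket and CSV layouts), the full metric suite (per-type PCC, SSIM
on rasterized proportion fields, Jensen–Shannon divergence, RMSE, Frobenius
distance, ARI, purity, Moran's I, Geary's C), and a `spadecon` command-line
tool (`simulate` / `train` / `deconvolve` / `evaluate`).

## Worked example

```r
library(spadecon)

ref <- generate_reference(k = 3, n_per_type = 60, ng = 90,
                          n_markers_per_type = 10, seed = 1)
sim <- simulate_spots(ref, grid = c(10, 8), seed = 2)   # 80 spots, truth known
fit <- spadecon(sim, control = spadecon_control(seed = 3))
fit
#> Spatially regularized autoencoder deconvolution fit
#>   80 spots, 3 cell types, 90 genes
#>   stage 1: 2000 epochs; stage 2: 1000 epochs
#>   alpha = 0.1, k_neighbors = 6, seed = 3

head(round(coef(fit), 3))
#>           type_1 type_2 type_3
#> spot_0001  0.999  0.001  0.000
#> spot_0002  0.998  0.002  0.000
#> spot_0003  0.770  0.224  0.006
#> spot_0004  0.981  0.016  0.003
#> spot_0005  0.697  0.303  0.000
#> spot_0006  0.687  0.313  0.000

evaluate_deconvolution(fit, sim)
#> PCC  0.888 +/- 0.027 (mean +/- sd over 3 cell types)
#> SSIM 0.775 (mean over cell types)
#> JSD  0.046 (mean over spots)
#> RMSE 0.163
#> Frobenius 2.528
```

`coef(fit)` rows are the estimated compositions (here the fit recovers the
striped domain structure: spots 1–2 are nearly pure `type_1`, later spots
mix). The score compares them with the simulator's ground truth: mean
per-type Pearson correlation 0.888 across spots, mean per-spot JS
divergence 0.046 — close agreement. `extract_signatures(fit)` returns the
learned type × gene signature matrix, and `plot(fit)` draws each type's
proportion field in space. On real data, pass your ST dataset as
`spadecon(sim, real = read_st("my_st_dir", format = "mtx_dir"))`; the
returned proportions are then for the real spots.

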
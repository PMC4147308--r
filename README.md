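# junctionquant

Per-cell quantification of junctional protein redistribution in
multi-channel fluorescence micrographs.

When adherens junctions strengthen, three measurable things happen to an
imaged cell: junction markers (E-cadherin, β-catenin) shift from the
cytoplasm to the cell border, the cell shares more of its boundary with
neighbors, and some regulators redistribute between membrane and
nucleus. This package implements the standard per-cell measurement chain
for those effects, for anyone doing quantitative confocal microscopy of
cell–cell adhesion: microscopists comparing treatment conditions cell by
cell, and method developers who need a testable reference implementation
of the conventions involved.

## What it computes

Every metric lives on a per-cell trio of masks — **cell** (supplied
outline), **membrane** (erosion ring of configurable width), **nucleus**
(DAPI strictly > 60 cts by default, largest connected component) — after
per-channel scalar (median) background subtraction.

* **Compartment distribution** — integrated intensities and the
  internally calibrated ratios

  ratio_membrane = Σ_membrane I / Σ_cell I,  ratio_nucleus = Σ_nucleus I / Σ_cell I,

  invariant under detector gain and zoom, plus size-normalized total
  intensity (Σ I / area).
* **Cell–cell contact** — %contact = 100 × shared perimeter / total
  perimeter, with explicit digital-perimeter conventions (8-connected
  boundary chain, √2 diagonals; 4-direction Crofton as alternative) and
  a Chebyshev contact tolerance; longitudinal/horizontal axis lengths
  from the ellipse of inertia.
* **Co-localization** — mask-restricted Manders split coefficients
  M1 = Σ{A_i : B_i > τ} / Σ A_i (τ = 0 after subtraction), PDM maps
  (A_i − Ā)(B_i − B̄), positive-PDM fractions and frequency scatter
  histograms, per compartment.
* **Condition reports** — per-cell groups compared with two-tailed
  Student's t (Welch optional), mean ± s.e.m, `*` P < 0.05 / `**`
  P < 0.01.
* **Synthetic scenes** — a seeded generator planting exact compartment
  fractions, contact geometry and co-localization levels, with Poisson +
  Gaussian noise, so the whole chain is verifiable against ground truth.

## Worked example

```r
library(junctionquant)

spec  <- scene_spec(n_cells = 12, seed = 7, adjacency_mode = "chained",
                    target_contact_fraction = 0.35, coloc_rho = 0.6)
scene <- generate_scene(spec)
res   <- run_scene_pipeline(scene)   # subtract -> segment -> measure

pa <- subset(res$profiles, channel == "markerA")
mean(pa$ratio_membrane)              # 0.518  (planted f_m = 0.50)
mean(pa$ratio_nucleus)               # 0.205  (planted f_n = 0.20)
mean(res$morphology$percent_contact) # 33.8   (planted 35% contact)
mean(res$coloc$M1, na.rm = TRUE)     # 0.90   (nuclear M1, planted rho = 0.6)

head(res$profiles[, c("cell_id", "channel", "I_total",
                      "ratio_membrane", "ratio_nucleus", "cell_area")], 3)
#   cell_id channel  I_total ratio_membrane ratio_nucleus cell_area
# 1       1 markerA 99799.03      0.5180425     0.2056163      2142
# 2       2 markerA 99255.86      0.5167458     0.2052025      2142
# 3       3 markerA 99013.80      0.5179665     0.2039346      2142
```

The planted membrane fraction is recovered to ~0.02 despite shot and
read noise; percent contact lands within ~1 point of the planted
geometry (chain ends share only one edge, which accounts for most of the
gap); nuclear M1 sits between its rho = 0 floor (≈ 0.8, set by the
texture sparsity) and 1.

## Analysis workflow

`analysis/` contains the numbered drivers that reproduce the package's
study-style analyses end to end, writing tables under `results/`:

1. `01_simulate_scenes.R` — control vs induced two-condition design
2. `02_compartment_ratios.R` — membrane/cell, nucleus/cell per condition
3. `03_contact_morphology.R` — %contact recovery across planted levels
4. `04_colocalization.R` — nuclear M1/M2 and PDM vs planted rho
5. `05_group_report.R` — mean ± s.e.m tables and t-test report bundle

Run them in order with `Rscript analysis/01_simulate_scenes.R` etc.

## Documentation

The methods vignette
(`vignettes/quantifying-junction-remodeling.Rmd`) documents the model,
the estimator conventions and their biases, the generator's design and
its limits, and every tunable parameter with its default and rationale.
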
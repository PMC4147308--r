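---
title: "Quantifying junctional protein redistribution per cell: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying junctional protein redistribution per cell: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(junctionquant)
```

## The measurement problem

Epithelial-type cells hold on to each other through adherens junctions
built on E-cadherin and β-catenin. When a perturbation strengthens those
junctions, three things happen in a fluorescence micrograph: junction
markers move from a diffuse cytoplasmic pattern to the cell border, cells
spend more of their boundary in contact with neighbors, and some
regulators shuttle between membrane and nucleus. None of these is a
single-number image property — they are all *per-cell* statistics, and
they must be comparable across images acquired with different detector
gain and zoom.

junctionquant implements that measurement chain: per-cell masks,
gain-invariant compartment ratios, contact geometry, nuclear
co-localization, and condition-level tests, plus a synthetic-scene
generator that plants known truth so every stage can be verified.

## The three-mask model

Each cell is reduced to three pixel sets:

* **cell** — the full outline (supplied as a polygon or label mask;
  outlining is a manual step on real data, so this package takes it as
  input rather than attempting automatic whole-cell segmentation);
* **membrane** — a ring of width `ring_width` pixels (default 3 px,
  ≈ 0.6 µm at the default 0.2 µm/px) obtained by subtracting from the
  cell mask its morphological erosion. On real specimens the membrane
  region is drawn by eye from DIC and a junction channel; an erosion ring
  is the reproducible, deterministic surrogate. The structuring element
  (box by default, disc optional) is recorded with the masks. Cells
  thinner than twice the ring width become all-membrane and their nucleus
  is forced empty;
* **nucleus** — pixels of the DAPI channel *strictly* above a count
  threshold (default 60 cts), minus any ring pixels (compartments must be
  disjoint), reduced to the largest 4-connected component so each cell
  carries one nucleus. Cells whose nucleus comes out empty are flagged
  and their nucleus metrics reported missing, never zero.

Two conventions deserve a note because the field leaves them open. First,
whether the DAPI threshold applies to raw or background-subtracted counts
is a genuine ambiguity; here the default pipeline applies it after
subtraction, the choice is a parameter, and the provenance is recorded on
the segmentation object. Second, nucleus/ring overlap resolution
(subtracting the ring from the nucleus) is our choice; any consistent
rule works because the ratios only need disjoint, reproducible masks.

Background is removed per channel as a single scalar — the whole-frame
median by default — clipped at zero. A scalar median is appropriate for
sparse fields where most pixels are background; on crowded fields (e.g.
dense chains where cells cover most of the frame) the median creeps into
cell-interior intensities and over-subtracts, which slightly inflates
membrane ratios and deflates per-area intensities. The synthetic recovery
analyses therefore use sparse layouts for intensity questions and dense
layouts only for geometry questions, and real-data users with crowded
fields should pass a fixed background value instead.

## Compartment ratios and internal calibration

For each cell and channel the package sums intensities over the three
masks and reports

$$\mathrm{ratio}_{membrane} = \frac{\sum_{i \in membrane} I_i}{\sum_{i \in cell} I_i},
\qquad
\mathrm{ratio}_{nucleus} = \frac{\sum_{i \in nucleus} I_i}{\sum_{i \in cell} I_i},$$

plus the size-normalized total $\sum I / \mathrm{area}$. Summed (not
averaged) intensities are the primitive. The ratios are *internally
calibrated*: a multiplicative detector gain cancels exactly, which is
what makes cells pooled from different acquisitions comparable
(`gain_invariance_check()` verifies this to 1e-9 on demand).
"Normalized to cell size" is interpreted as division by mask pixel area;
area is the only size scalar derivable from the masks alone, and the
interpretation is configurable by consumers that prefer perimeter.

Zero-total cells get missing ratios rather than zeros, so group means are
not dragged toward zero by empty cells.

## Contact geometry

The contact statistic is

$$\%\,contact = 100 \times \frac{\text{shared perimeter}}{\text{total perimeter}}.$$

Digital perimeters are convention-dependent, so the estimator is explicit
and recorded. The default is the Moore-traced 8-connected boundary chain
with diagonal steps weighted $\sqrt 2$: a 10×10 square measures 36 (its
36 boundary pixels traversed in unit steps) and a single pixel measures 4
by convention. The chain overestimates smooth boundaries by ≈ 5.5 % on
average (the classic staircase bias of the (1, √2) weights — we measure
+4.9 % on a radius-20 digital disk); the 4-direction Crofton estimator is
available where absolute lengths against a smooth reference matter (it is
within ≈ 2 % on disks but underestimates axis-aligned polygons). The
shared perimeter — boundary pixels within Chebyshev distance
`contact_distance` (default 2 px, tolerating 1-px rasterization gaps) of
another label — is always measured on the chain, because Crofton is not
defined on a boundary subset; percent contact is therefore a chain/chain
ratio in which the staircase bias cancels.

Cell elongation is reported as longitudinal/horizontal extents from the
ellipse of inertia (4 standard deviations along each principal axis,
orientation-free), with the minor extent floored at 1 px so ratios of
1-px-wide masks stay finite. The moment fit matches true ellipse axes to
a few percent but overestimates a uniform bar by ≈ 15 % (uniform vs
elliptical mass distribution); max/min Feret diameters are available as
the alternative.

## Co-localization

Manders split coefficients restricted to an explicit region mask:

$$M_1 = \frac{\sum_{i \in R,\; B_i > \tau} A_i}{\sum_{i \in R} A_i},$$

symmetrically for $M_2$, with co-occurrence threshold $\tau = 0$ after
background subtraction by default (the behavior of the classic
intensity-correlation plugins; $\tau$ is configurable and recorded). The
PDM map is $(A_i - \bar A)(B_i - \bar B)$ over the region; its regional
mean is definitionally the covariance, and the positive-PDM fraction and
a 64×64 linear-binned frequency scatter histogram accompany it. The
binning is our convention — published scatter plots rarely state theirs.
The region is always an explicit argument because nuclear restriction
changes the answer; whole-image Manders is deliberately not offered.

## The synthetic-scene generator

The generator emulates only the statistical structure the metrics assume:
sparse adherent cells (ellipses or rectangles) with elliptical nuclei, a
thin erosion ring, uniform background, Poisson shot noise plus Gaussian
read noise, and — the two planted quantities recovery tests care about —

* **compartment fractions**: each marker distributes
  `cell_amplitude × area` counts per cell with exactly `membrane_fraction`
  in the ring and `nucleus_fraction` in the nucleus. Exactness (not just
  expectation) is achieved by renormalizing the within-compartment
  texture to unit mean, so clean-image ratios equal the planted values to
  floating precision and every recovery error is attributable to noise
  and background handling;
* **co-localization**: in-cell marker texture is a sparse gamma field
  (default 70 % of pixels positive, gamma shape 4). The second marker
  copies the first marker's texture pixelwise with probability `coloc_rho`
  and draws an independent same-marginal value otherwise. This per-pixel
  mixture was chosen over the additive blend
  $B = \rho A + (1-\rho) A'$ deliberately: under a zero co-occurrence
  threshold the additive blend makes $B$ positive wherever $A$ is, for
  any $\rho > 0$, so thresholded Manders saturates at 1 and cannot
  resolve intermediate levels. The mixture keeps the desirable limits
  ($\rho = 0$ independence, $\rho = 1$ exact proportionality, covariance
  linear in $\rho$) while making $M_1$ strictly monotone in $\rho$.

Adjacency is geometric, mirroring the mask-based contact definition:
`chained` scenes place rectangles with coincident edges, and the target
contact fraction sets the aspect ratio (an interior cell of width $w$,
height $h$ shares $2h$ of its $2(w+h)$ perimeter, so
$h/(w+h) = t$). Chain ends share one edge instead of two, which is why
recovery runs use chains of ≥ 30 cells (the two ends then shift the mean
by < 2 points). Pixelization is center sampling — a pixel belongs to a
mask iff its center is inside the shape — stated once so truth and
measurement agree; polygon vertices at integer coordinates never collide
with half-integer pixel centers.

Defaults are chosen as plausible confocal conditions: 0.2 µm/px, 34-px
(≈ 7 µm) minor cell diameter, nucleus at 42 % of the cell axes, DAPI
amplitude 200 cts over a 5-ct background against the 60-ct nucleus
threshold, marker amplitudes 40–50 cts over ≈ 8-ct backgrounds. None of
these is load-bearing; recovery holds across the parameter grids the
tests sweep. All randomness flows from the single spec seed, so a spec
fixes its scene bit-for-bit — the determinism the pipeline tests rely on.

What the generator does *not* emulate — point-spread-function blur,
chromatic shift, organelle texture, bleed-through, photobleaching, 3D —
bounds what passing tests show: they validate the measurement chain (mask
algebra, estimator conventions, statistical calibration), not robustness
to optical artifacts of real confocal stacks.

## Statistics

The replication unit is the individual cell, typically 10–40 cells per
condition (the package warns outside that regime). Groups are compared
with the classic equal-variance two-tailed Student's t (Welch by flag,
since per-cell variances often differ), reported as mean ± s.e.m with
`*` for P < 0.05 and `**` for P < 0.01. Two conventions are deliberate
reproductions of common field practice rather than statistical
recommendations, and both are documented as limitations: cells from the
same image are treated as independent (no image-level clustering
correction), and no multiple-testing correction is applied by default (a
Benjamini–Hochberg toggle exists). Degenerate zero-variance comparisons
return a flagged missing p-value rather than a fabricated one. The
t-test's type-I error is itself under test (1000 null simulations must
land in [3.5 %, 6.5 %] at α = 0.05).

## Numerical and degenerate-input choices

* Strict inequality at the DAPI threshold: a uniform value exactly at the
  threshold yields an empty (flagged) nucleus.
* Median filtering (radius 1) exists only in the figure-export path
  (`presentation_median_filter()`); no metric touches filtered pixels.
* Images are stored as 16-bit TIFF counts; integer counts round-trip
  exactly, sub-integer noise is quantized to one count. Channel names
  travel in a plain-text sidecar because baseline TIFF writers carry no
  per-page description.
* Tie-breaks: equal-size nucleus components resolve to the first label
  returned by the connected-component pass; boundary tracing starts at
  the column-major-first foreground pixel. Both are deterministic.
* Problem sizes in the shipped analyses — 30 cells per planted level for
  intensity recovery, 32-cell chains for contact recovery, 20 cells per
  level for co-localization, 1000 simulations for test calibration — are
  the smallest sizes at which the standard errors are comfortably inside
  the recovery tolerances (±0.02 clean / ±0.05 noisy on fractions,
  ±5 points on percent contact).

## Known limitations

Manual outlines are trusted as given (no consistency check against the
image); the erosion ring has constant width, whereas hand-drawn membrane
regions vary locally; scalar background subtraction under-serves crowded
fields (see above); Costes-style automatic thresholding and
randomization tests for co-localization are out of scope; and the
statistics inherit the per-cell-independence convention discussed above.
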
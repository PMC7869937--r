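---
title: "Canopy roughness from UAS point clouds: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canopy roughness from UAS point clouds: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyr)
```

## The problem

Aboveground biomass (AGB, g/m²) is a central selection criterion in crop
breeding, but measuring it destructively — cutting, drying and weighing plants
plot by plot — does not scale to trials with hundreds of plots. Photogrammetric
point clouds reconstructed from overlapping nadir images taken by a small
unmanned aerial system (UAS) offer a nondestructive alternative: a colored 3D
cloud of the whole trial at centimeter resolution, from which plot-level canopy
traits can be computed automatically.

canopyr implements one such trait, **canopy roughness**, together with the full
processing chain from a raw colored point cloud to cross-validated per-plot
biomass estimates, and a synthetic field generator that makes every stage
testable without any field data.

## The trait

The **point roughness** of a point $p$ is its orthogonal distance (in meters)
to the total-least-squares plane fitted to all *other* points within a sphere
of radius $r$ (default $r = 0.10$ m) around $p$. A smooth, locally planar
canopy yields small distances; an irregular canopy with protruding stems and
uneven leaf layers yields large ones.

At the plot level the per-point values are pooled over the plot's interior rows
and summarized as the **canopy roughness**

$$\mathrm{CR} = \mathrm{IQR} \times \mathrm{med} \quad [\mathrm{m}^2],$$

the product of the interquartile range and the median of the point-roughness
distribution. The product form is what the trait's stated unit (m², a product
of two lengths) requires. The median captures the typical surface irregularity,
the IQR its spread; a perfectly uniform canopy — constant roughness, including
the degenerate all-zero planar case — has $\mathrm{CR} = 0$, and scaling all
roughness values by $k$ scales CR by $k^2$. A ratio variant
($\mathrm{IQR}/\mathrm{med}$, dimensionless) is available via
`canopy_roughness(variant = "ratio")` for sensitivity analysis, because the
product form, while the only unit-consistent reading, is an interpretation of a
tersely typeset definition.

Numerical conventions, fixed for bit-reproducibility:

* quantiles are linear interpolations of order statistics (R's default
  type 7);
* the query point is excluded from its own plane fit — including it would bias
  the distance toward zero;
* points with fewer than 3 neighbors, or with a collinear neighborhood (no
  unique plane), are *excluded* from the plot statistic rather than
  zero-filled, which would deflate the median on sparse plots; their count is
  reported.

## The pipeline

`run_pipeline()` executes the stages in a fixed order; each is also an exported
pipe-friendly function.

**1. Outlier filtering** (`statistical_outlier_removal()`,
`plane_fit_outlier_removal()`). Photogrammetric clouds contain isolated
spurious points. The first filter computes each point's mean distance to its
$k = 20$ nearest neighbors, fits a single Gaussian to those means over the
whole cloud, and removes points beyond $\mu + 3\sigma$; the second fits a local
total-least-squares plane to each point's 20 neighbors and applies the same
cloud-wide $3\sigma$ rule to the point-to-plane distances. Both thresholds are
one-sided: unusually *small* distances indicate agreement with the surface, not
outliers. A global Gaussian (not per-neighborhood) is fitted, the convention of
the standard point-cloud-library implementation of this filter. Points whose
neighborhoods are collinear have no defined plane; they are retained and
counted, never silently dropped. Both filters exclude the query point from its
own neighborhood statistics, consistently with the roughness definition.

The false-removal rate of the plane filter on structureless data is a property
worth knowing: for an isotropic Gaussian blob the point-to-plane distance
distribution is heavier-tailed than Gaussian, and the mass beyond
$\mu + 3\sigma$ is about 2.4%, not the 0.13% a normal tail would suggest. On
surface-like clouds (the intended regime) the distances are jitter-driven and
the two-stage chain removes injected gross outliers with recall 1.0 at under 1%
false removal, which the test suite verifies.

**2. Height calibration** (`adjust_height()`). Surveyed reference bars of known
elevation are compared with the cloud elevations read at the bars; the cloud is
shifted by the mean difference and per-bar residuals are reported. Bar
elevations are caller-supplied: locating bars in a cloud is a manual step, and
the toolkit does not pretend to automate it.

**3. Regularization** (`build_mesh()`, `repair_holes()`, `laplacian_smooth()`,
`sample_surface()`, `poisson_disk_thin()`; chained by `regularize_cloud()`).
SfM density varies with image texture, so the cloud is rebuilt at uniform
density: a Delaunay triangulation of the $(x,y)$ projection lifted to $z$
(crop canopies imaged from nadir are height fields, so the 2.5-D convention is
the right reading of "3D triangulation" — a true 3D Delaunay yields
tetrahedra, not a surface), hole repair by planar ear-clipping of interior
boundary loops, Laplacian smoothing over a 0.10 m metric radius, uniform
area-weighted resampling at 500 points/m², and dart-throwing Poisson-disk
thinning at 1 cm minimum spacing.

Three regularization choices deserve explanation:

* *Hole size limit.* Only interior loops with perimeter ≤ 0.5 m are filled
  (configurable): this fills within-row meshing gaps without bridging the
  0.76 m inter-row corridors. The limit is a package default, not an inferred
  value; the hole-repair log records every skipped loop.
* *Smoothing operator.* Each movable vertex is attracted to the unweighted
  centroid of all vertices within the radius, but only the component of the
  displacement along the local surface normal is applied. This anti-drift
  variant makes every locally coplanar neighborhood an exact fixed point — a
  planar mesh passes through unchanged — whereas the plain centroid update
  would slide vertices tangentially on any irregularly sampled surface and,
  on strip-shaped crop canopies, visibly erode row edges. Boundary vertices
  are pinned. An optional vertex mask supports the workflow where smoothing
  is applied only around selected problem locations; the default smooths all
  interior vertices once.
* *Poisson-disk thinning* visits points in a seeded random order and accepts a
  point iff no previously accepted point lies within 1 cm. The output is
  maximal: every rejected point is within 1 cm of an accepted one. Both
  properties are brute-force-verified in the tests.

**4. Vegetation/soil classification** (`classify_vegetation()`). A single
cut-off at 115 on the 8-bit green band, the value appropriate for a dense
green soybean canopy over bare soil at the full-flowering stage. Which side of
the cut-off is vegetation depends on sensor and soil radiometry, so the
direction is an explicit flag (`veg_ge_cutoff` by default, boundary
inclusive). `audit_classification()` emulates the manual accuracy check used
with real data: a seeded sample of 1000 points crossed against reference
labels, reporting overall accuracy and Cohen's kappa.

**5. Row segmentation** (`extract_rows()`, `drop_border_rows()`). Each plot's
vegetation cloud is discretized into a 0.15 m voxel grid anchored at the
plot's minimum corner (anchoring per plot makes the result independent of
global coordinates); occupied voxels are joined into connected components
(26-connectivity by default — diagonal contact keeps a plant row together; 6
is available), and components with fewer than 50 points are discarded as
unable to represent homogeneous plant growth. Components are ordered by their
mean cross-row coordinate, and the two border rows are dropped before trait
computation to avoid edge effects: an 8-row plot contributes its 6 interior
rows.

**6. Regression** (`fit_model()`, `loocv()`, `reject_plot_outliers()`,
`genotype_report()`). Five univariate trend-line families relate AGB to CR:
linear, power, exponential, quadratic polynomial, and logarithmic. Power and
exponential models are fitted by least squares in log space and
back-transformed — the deterministic spreadsheet-trendline convention, chosen
over iterative nonlinear least squares for bit-reproducibility. Validation is
leave-one-out: each plot is predicted by a model fitted to all others, and
four errors are computed from the out-of-fold predictions:

$$\mathrm{RMSE} = \sqrt{\tfrac1n\textstyle\sum_i(\hat y_i - y_i)^2}, \qquad
\mathrm{RRMSE} = 100\,\mathrm{RMSE}/\bar y,$$
$$\mathrm{ASE} = \tfrac{100}{n}\textstyle\sum_i \frac{\hat y_i - y_i}{y_i}
\ \text{(signed bias)}, \qquad
\mathrm{MPSE} = \tfrac{100}{n}\textstyle\sum_i
\frac{|\hat y_i - y_i|}{y_i},$$

so $\mathrm{MPSE} \ge |\mathrm{ASE}|$ always. The headline $R^2$ is the
squared Pearson correlation of out-of-fold predictions with observations (the
1:1 scatter validation); the in-sample variant is reported alongside for
transparency. Before validation, plots with standardized residuals beyond
$\pm 2$ are removed iteratively — fit, standardize by the residual standard
deviation, drop all offenders, refit — until the bound holds, mirroring how
gross plot-level anomalies (lodging, stand failure) are excluded in field
practice. Per-genotype error tables recompute the four metrics over each
genotype's out-of-fold predictions, omitting genotypes with fewer than 3
plots and flagging the best and worst by RRMSE.

## The synthetic field generator

`generate_field()` produces a colored cloud with complete ground truth: per
point the class (vegetation / soil / outlier) and row id, per plot the
genotype and the roughness-driving amplitude. The geometry emulates the layout
of a row-crop trial at full flowering:

| parameter | default | why |
|---|---|---|
| rows per plot / spacing | 8 / 0.76 m | standard planter configuration for such trials |
| row strip width | 0.30 m | visually separable rows, ~40% canopy cover, matching the ~31% vegetation-point share of real clouds |
| canopy height | 0.6 m | soybean at full flowering |
| edge taper | 0.08 m | canopy edges arch to the ground; a literal vertical cliff is not something nadir SfM can produce, and its mesh skirts would dominate area-weighted resampling |
| surface | $z = h\cdot\mathrm{prof}(x) + a\sin(2\pi x/\lambda)\sin(2\pi y/\lambda) + \epsilon$ | single-frequency bump field with analytically known roughness ordering |
| bump wavelength $\lambda$ | 0.4 m | close to, but above, the 0.10 m roughness neighborhood, so plane fits see curvature |
| jitter $\epsilon$ | sd 5 mm | photogrammetric depth noise, ~2× the ground sample distance |
| point density | 700 /m² | the order delivered by the real surveys |
| green bands | veg [150, 220], soil [60, 110] | disjoint across the 115 cut-off |
| field margin | 0.4 m | rows continue past the plot polygons, as plots clipped from a continuous field do; without it, mesh edge skirts at the row ends leak vegetation-colored points into every row gap |
| AGB simulation | mean 150.3, sd 42.3 g/m² | the scale of real per-plot biomass at this growth stage |

The bump and jitter terms ride on top of the tapered base height unscaled
(clamped at ground level), so the roughness signal covers the entire strip
rather than only its flat core — otherwise the taper shoulders, which carry
most of the resampled points because of their 3-D area, would dilute the
amplitude signal.

Gross outliers are placed uniformly in an inflated bounding box; dropout
carves random circular holes (radius 0.15 m) until the requested fraction of
points is removed. One random stream is split per plot, so any plot can be
regenerated alone. `simulate_agb()` maps per-plot CR through a chosen model
family plus Gaussian noise truncated at zero; by default it calibrates a
linear model to the target mean and spread given the realized CR values.

**What the generator does and does not emulate.** It reproduces the features
the pipeline's correctness depends on: row layout, color separation,
density, holes, gross outliers, and a monotone link between a known
per-plot parameter and true surface irregularity. It does not attempt leaf
architecture, view-dependent color mixing, occlusion, shadows, or
reconstruction artifacts beyond white noise. Passing tests therefore
demonstrate algorithmic correctness on clouds with known structure — not
end-to-end accuracy on real imagery, whose headline numbers depend on field
data that no synthetic stand-in can certify.

A consequence worth stating plainly: meshing and area-weighted resampling of
a synthetic canopy *attenuate* the roughness statistic (resampled points lie
on piecewise-planar facets, and uncorrelated vertex jitter is partially
frozen out), so CR measured after full regularization is compressed relative
to CR measured on the generated cloud directly. The monotonicity guarantee —
CR strictly increasing in bump amplitude, Spearman $\rho \ge 0.9$ across
plots — is therefore validated on the generator's own uniform-density output,
which is also the regime the regularization stage is *for*: real SfM clouds
need density homogenization before the trait is comparable across plots;
synthetic clouds are born homogeneous.

## Problem sizes

The test suite and the acceptance script run every stage at sizes that keep a
complete run in minutes while still exercising each code path many times
over: fields of 2–24 plots with 1–2 m rows at 250–700 points/m², oracle
comparisons on clouds of up to 2000 points (against $O(n^2)$ brute force),
Poisson-disk checks on 10⁴-point clouds, and 100-replicate parameter-recovery
studies. These are the package's own choices of experimental scale; all
thresholds (k = 20, 3σ, 115, 0.15 m, 50 points, 0.10 m, residual limit 2,
3-plot genotype minimum) are the pipeline's operating defaults, exposed in
`pipeline_config()`.

## Known limitations

* LAZ (compressed LAS) and ESRI Shapefile inputs are not read; uncompressed
  LAS 1.2, PLY, XYZ text, and CSV/GeoJSON plot maps are.
* The 2.5-D meshing convention assumes a height-field canopy; it is wrong for
  crops with substantial overhang.
* The green-band cut-off is a single global threshold; no vegetation-index
  classifier is provided, by design.
* Power and exponential fits minimize log-space error, which weights small
  observations more heavily than direct nonlinear least squares would.
* Quantile-based CR is duplication-invariant only asymptotically under the
  interpolating quantile convention (exact under duplication only for
  order-statistic quantile types).
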
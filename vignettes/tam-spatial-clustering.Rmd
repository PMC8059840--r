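---
title: "Quantifying tumor-associated macrophage clustering with normalized cross-type Ripley's K"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tumor-associated macrophage clustering with normalized cross-type Ripley's K}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tamspat)
```

## The problem

Immune infiltration of tumors is conventionally summarised as a cell
density — marker-positive cells per mm² of tissue. Density ignores spatial
arrangement: two regions with identical macrophage density can differ
radically in how closely those macrophages press against tumor cells, and
paracrine tumor–macrophage signalling acts over tens of micrometres, not
over the whole field. `tamspat` quantifies that local arrangement for
multiplex-IHC data and carries the resulting metric through to survival
analysis.

The input is the standard digital-pathology export: one row per segmented
cell with Cartesian coordinates (µm), a tumor/stroma/other compartment
class, and independent 0/1 positivity flags for myeloid and immune markers
(CD68, CD163, CD206, PD-L1). Each region of interest (ROI) is a rectangular
field at the tumor–stroma interface; the default window is 678 × 506 µm
(a 1356 × 1012 pixel field at 0.5 µm/pixel, 0.343 mm²).

## The statistic

For reference cells of type A (e.g. tumor cells) and target cells of type B
(e.g. CD68+ cells) in window $W$, the cross-type Ripley's K estimator is

$$\hat K_{AB}(r) = \frac{|W|}{n_A\, n_B} \sum_{i \in A}\sum_{j \in B}
  w(x_i, \lVert x_i - x_j\rVert)\; 1\{\lVert x_i - x_j\rVert \le r\},$$

the edge-corrected average number of B cells within distance $r$ of an A
cell, normalised by the B intensity. Under complete spatial randomness
(CSR) its expectation is $\pi r^2$, so the package reports

$$nK(r) = \frac{\hat K_{AB}(r)}{\pi r^2},$$

a dimensionless observed-over-expected ratio: 1 under CSR, above 1 for
clustering, below 1 for dispersion, range $[0, \infty)$. An nK of 1.30
reads as "30% more B cells within $r$ of each A cell than expected if cells
were placed at random". The pipeline fixes $r = 25$ µm — about twice a
tumor-cell radius, i.e. the immediate paracrine neighbourhood — and calls
the value nK(25).

Conventions that matter for exactness:

* **Isotropic edge correction.** $w$ is the reciprocal of the fraction of
  the circle of radius $\lVert x_i - x_j\rVert$ centred at the *reference*
  cell that lies inside the rectangle, computed in closed form
  (per-edge exterior arcs $2\cos^{-1}(d/r)$ with corner overlaps added
  back). A slow numeric arc-integration twin
  (`isotropic_weight_numeric()`) validates the closed form to better than
  1e-9. Weights are bounded by 4 for any centre when $r$ is small relative
  to the window, and since 25 µm ≪ 506 µm no cap is applied.
* **Self-pairs and duplicates.** The same cell record never pairs with
  itself (relevant when a CD68+ cell is also tumor-classed, since marker
  flags and compartment class are independent axes); for identical
  reference and target selectors the divisor is $n(n-1)$. Distinct cells at
  distance 0 (co-located centroids from segmentation) contribute with
  weight 1, the interior limit. The distance indicator is a closed ball.
* **Directionality.** "Tumor/CD68+" anchors the search circle — and the
  edge weight — at the tumor cell and counts CD68+ neighbours. The
  estimator is numerically near-symmetric but not exactly so; the package
  always reports the reference-anchored value.

## Eligibility and aggregation

Sparse populations make $\hat K$ unstable, so an ROI enters the spatial
analysis for a (compartment, marker) pairing only if it has at least 10
marker-positive cells **and** at least 10 reference-compartment cells
(`min_count`, configurable). The published rule states only the
marker-count half; extending it to the reference set is deliberately
stricter and avoids estimates anchored on a handful of cells. Ineligible
pairings are missing values with their eligibility flag recording why —
never zeros.

Patient-level values are the unweighted mean of available per-ROI values
over the patient's *primary*-sample ROIs (metastasis samples are excluded
from survival analysis; patients with only metastasis ROIs drop out). The
aggregation rule is configurable (`mean`/`median`/`max`); mean is the
default as the least-structured choice, since no standard exists for
combining 3 interface ROIs into a patient value.

## Survival analysis

Continuous patient-level variables (density, nK(25)) are dichotomized at
the **optimal cut-point**: the observed value minimizing the two-group
log-rank p for overall survival, scanning all unique values, discarding
splits that leave a group below 10% of patients (and never below 3), ties
broken toward the smaller threshold. The scan uses an internal vectorized
risk-table tabulation and is tested for exact equality against an
exhaustive `survival::survdiff()` scan.

The minimized p is **anti-conservative**: it is the minimum of many
correlated tests. It is reported uncorrected, matching field practice, and
`optimal_cutpoint(..., n_perm = )` offers a permutation-adjusted p that
re-optimizes per permutation. The anti-conservatism propagates to any
downstream Cox fit that reuses the same data: in our null calibration
(pure-noise biomarker, n = 200, ~80% events), the Wald CI of the
dichotomized covariate excludes 1 in roughly 40% of fits. Conclusions
about a cut-point-selected covariate should therefore lean on the
permutation-adjusted p or external validation; the package reproduces the
conventional workflow but does not pretend the selection is free.

Multivariable Cox regression (Efron ties, via the survival package) enters
the dichotomized density and clustering variables jointly — the default
reading of "as separate covariates" — plus age in years (untransformed)
and IMDC risk group as a categorical factor with level 1 as reference.
A combined stratum (high density AND high clustering) is also fitted as a
single binary covariate. The post-hoc power summary is the minimum
detectable hazard ratio for a standardized continuous covariate,
$\mathrm{MDHR} = \exp\!\big((z_{1-\alpha/2} + z_{\mathrm{power}})/\sqrt{d}\big)$
with $d$ the expected number of events; at $n = 35$, 80% events,
$\alpha = 0.05$ two-sided and power 0.80 this is 1.70.

## What the generators emulate — and what they do not

Since multiplex-IHC cohorts are rarely shareable, validation runs on
synthetic marked point patterns with known spatial structure:

* `simulate_csr()` — independent homogeneous Poisson components; the CSR
  null with nK ≡ 1 in expectation.
* `simulate_shared_parent_thomas()` — a Poisson(κ) parent process whose
  parents emit Gaussian(σ)-displaced offspring of both the reference and
  the target type. Shared parents induce cross-type clustering with the
  closed form $nK(r) = 1 + \big(1 - e^{-r^2/(4\sigma^2)}\big)/(\kappa\pi r^2)$,
  the package's independent oracle. Parents are simulated on the window
  dilated by 4σ so the pattern restricted to the ROI is the *stationary*
  cluster process the closed form describes; without the dilation,
  clusters seeded just outside the field are missing, near-edge intensity
  is depleted, and the estimate is biased upward by several percent.
  Offspring falling outside the window are discarded, so the isotropic
  correction is exercised exactly as on real bounded ROIs.
* `simulate_cross_inhibition()` — CSR followed by probabilistic deletion
  of target cells within `d_inhibit` of a reference cell; dispersion with
  nK < 1, and exactly 0 under full thinning at `d_inhibit` ≥ r.
* `simulate_cohort()` — patients with a standardized latent clustering
  level $z$ mapped to the Thomas dispersion
  $\sigma_i = 20\,e^{-0.5 z_i}$ µm (clamped to 4–100 µm): small σ means
  tight tumor/CD68 clusters and high nK(25), while the expected CD68
  density $\kappa\mu$ is unchanged. Density instead carries an independent
  lognormal patient factor (sd 0.25 on the log scale), keeping density and
  clustering near-orthogonal — mirroring the weak correlation seen in
  tissue. Defaults emulate the reference cohort scale: 35 patients, 3
  interface ROIs per sample, ~37% of patients contributing an extra
  metastasis sample, ~50/50 tumor/stroma composition (~690 tumor and ~690
  stromal cells per 0.343 mm² ROI), ~100 CD68+ cells per ROI, sparse
  CD163+/CD206+ populations that frequently fail eligibility (as in real
  cohorts), age ~ N(58, 9²), IMDC 1/2/3+ at 37/49/14%. Survival is
  exponential with rate $h_0 e^{\beta z}$, $h_0 = 0.03$/month, censored
  administratively at 60 months, giving ~80% events; $\beta = \log 2$ by
  default (hazard doubles per SD of latent clustering).

The generators deliberately omit: nuclear morphology and intensity values,
correlated marker co-expression (flags are independent), inhomogeneous
tissue architecture (tumor nests vs sheets), random loss to follow-up
(censoring is administrative only), and any density–survival link. Passing
tests therefore demonstrate estimator correctness, calibration, and
power to recover a clustering-driven hazard under these idealized
conditions — not that any particular tissue cohort will show such an
effect.

## Numerical choices and problem sizes

* CSR calibration uses 500 replicate ROIs at ~343 cells per type
  (intensity 1e-3/µm² in the default window); the Monte-Carlo SE of the
  mean nK(25) is ~0.002, comfortably resolving the ±0.03 calibration band.
* The Thomas validation uses κ = 1e-4/µm², µ = 10, σ = 10 µm (analytic
  nK(25) = 5.03) with 120–200 replicates and a 3-SE band at r ∈
  {10, 25, 40} µm.
* The cohort recovery experiment uses 50 replicate cohorts of 200
  patients × 3 ROIs; the clustering effect (true HR 2/SD) is recovered in
  every replicate.
* The cut-point scan treats p-ties strictly (first, i.e. smallest,
  candidate wins); log-rank variance terms with a single subject at risk
  are zero by convention.
* Degenerate inputs: empty reference or target selections abort with an
  eligibility hint rather than returning 0; all-tied paired comparisons
  report p = 1; constant covariates and zero-event datasets abort Cox
  fits with explicit messages.

## Known limitations

* Windows are rectangles; annotated polygonal ROIs must be bounded first.
* The isotropic correction's closed form assumes r ≤ min(width, height);
  the pipeline's 25 µm is far inside that regime.
* Patient-level aggregation assumes exchangeable ROIs within a sample.
* The optimal-cut-point workflow is reproduced as practised, including
  its anti-conservatism; see above.
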
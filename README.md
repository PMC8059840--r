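# tamspat

Spatial analysis of tumor-associated macrophage (TAM) infiltration from
multiplex-IHC cell coordinates.

Immune infiltration is usually reported as a cell density (cells/mm²),
which is blind to spatial arrangement — yet TAMs act on tumor cells through
short-range paracrine signalling, so *how closely* CD68+/CD163+/CD206+
cells pack around tumor versus stromal cells can carry prognostic
information that density misses. `tamspat` quantifies that local clustering
and carries it through to survival analysis:

* **Normalized cross-type Ripley's K.** For reference cells A and target
  cells B in a rectangular window W,

  K̂<sub>AB</sub>(r) = |W| / (n<sub>A</sub> n<sub>B</sub>) · Σ<sub>i∈A</sub> Σ<sub>j∈B</sub> w(x<sub>i</sub>, ‖x<sub>i</sub>−x<sub>j</sub>‖) · 1{‖x<sub>i</sub>−x<sub>j</sub>‖ ≤ r}

  with an exact closed-form isotropic edge correction w, normalized as
  **nK(r) = K̂(r)/(πr²)** — equal to 1 under complete spatial randomness,
  &gt;1 for clustering, &lt;1 for dispersion. The pipeline uses r = 25 µm
  ("nK(25)"), the immediate paracrine neighbourhood of a tumor cell.
* **Per-ROI metrics with eligibility filtering** (≥10 marker-positive and
  ≥10 reference-compartment cells), patient-level aggregation over
  primary-sample ROIs, paired Wilcoxon tumor-vs-stroma compartment
  affinity tests, and density-vs-clustering Spearman correlation.
* **Survival statistics**: optimal cut-point stratification (minimizing
  the log-rank p, with an optional permutation-adjusted p), Kaplan–Meier,
  multivariable Cox regression (age + IMDC risk group as covariates), and
  the minimum-detectable-hazard-ratio power relation.
* **Generators with known ground truth** — CSR, a shared-parent Thomas
  cluster process with closed-form cross-nK, cross-type inhibition, and a
  survival-linked synthetic cohort simulator — used to validate the whole
  chain end to end.

See `vignettes/tam-spatial-clustering.Rmd` for the model, conventions and
design choices.

## Worked example

Simulate one ROI where tumor cells and CD68+ macrophages share Thomas
cluster parents (κ = 1e-4/µm², σ = 10 µm — analytic nK(25) = 5.03), then a
35-patient cohort whose hazard doubles per SD of latent clustering while
CD68+ density is independent of survival, and run the full pipeline:

```r
library(tamspat)

p <- simulate_shared_parent_thomas(kappa = 1e-4, mu_ref = 10, mu_target = 10,
                                   sigma = 10, seed = 7)
nk25(p, "tumor", "cd68")
#> 3.57            # one noisy ROI; the mean over replicates converges to 5.03

coh <- simulate_cohort(n_patients = 35, seed = 1)
res <- run_full_analysis(coh$cells, coh$clinical)

res$comparisons$cd68
#> CD68 compartment affinity: tumor median 2.83 vs stroma median 1.00,
#> Wilcoxon p = 2.2e-25 over 144 ROIs   # CD68+ cells cluster with tumor cells

res$correlation
#> Spearman rho = -0.09 (p = 0.29)      # density and clustering not redundant

res$cutpoints$clustering
#> optimal cut-point 2.209 (n = 35: 13 low / 22 high); log-rank chi2 = 14.39

res$cox
#> Cox proportional hazards: n = 35, events = 24
#>              term    hr ci_lower ci_upper  p_value
#> 1    high_density 0.618    0.253     1.51 0.291363
#> 2 high_clustering 6.629    2.160    20.34 0.000945
#> 3             age 1.006    0.954     1.06 0.823551
#> 4           imdc2 1.477    0.538     4.06 0.449492
#> 5          imdc3+ 1.017    0.232     4.46 0.982457

res$mdhr
#> 1.77   # minimum detectable HR for this cohort's size and event count
```

High tumor/CD68+ clustering is flagged (HR 6.6, p < 0.001) while CD68+
density — independent of survival by construction — is not: the contrast a
density-only analysis would miss. Note the caveat in the vignette about
the anti-conservatism of cut-point-selected covariates.

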
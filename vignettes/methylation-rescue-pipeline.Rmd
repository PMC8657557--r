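---
title: "Methods: rescue-site methylation analysis, BMIQ, and phenotype quantification"
author: "methylRescue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rescue-site methylation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylRescue)
```

# Scope and model

methylRescue analyses four-group (C0/C5/Z0/Z5: control or knockdown
cells under vehicle or 5-azacytidine) EPIC-style methylation array
experiments. The estimand is the set of *rescue sites*: CpG probes
whose methylation rises upon knockdown (Z0 > C0) and falls again under
the demethylating drug (Z5 < Z0), both at Benjamini–Hochberg
q ≤ 0.05. Analysis operates on beta values directly; an M-value option
exists (`useMValues`) but is off by default because the group contrast
of interest is expressed and reported on the beta scale.

The pipeline is QC → BMIQ normalization → per-probe equal-variance
t-tests → BH-FDR → rescue filter → gene table. Each stage is an
exported function over a `MethylationExperiment`
(a `SummarizedExperiment` carrying `beta`, `detP` and `beadCount`
assays, the probe manifest as `rowData` and the sample sheet as
`colData`), and `runPipeline()` chains them with validation, atomic
output writing and a funnel-count JSON.

# Probe QC

Three presets: `raw` (none), `partial` (detection p-value, bead count,
non-CpG), `full` (those plus SNP-associated, multi-mapping and XY
probes). Parameters, with defaults:

* detection p-value threshold 0.01, failing-sample fraction 0
  (any-sample rule — one failing sample removes the probe). The
  fraction is configurable because the field uses both dialects.
* bead-count minimum 3, failing-sample fraction 0.05, *inclusive*
  ("at least 5% of samples"): with 20 samples, exactly one failing
  sample removes the probe.
* annotation flags are manifest inputs; this package does not maintain
  SNP or cross-reactivity databases.

The cascade runs in the fixed order detection p → bead count →
non-CpG → SNP → multi-mapping → XY, and each removed probe is counted
at its first failing stage. Per-stage counts are therefore
order-dependent (a probe failing both SNP and XY counts under SNP);
the conservation property — survivors plus stage counts equal the
input — holds for every preset and is tested. Presets nest:
full survivors ⊆ partial survivors ⊆ raw.

# BMIQ normalization

Type II probes read compressed toward 0.5. Per sample, a three-state
Beta mixture (unmethylated U, hemimethylated H, methylated M) is
fitted to the type I and type II betas separately; type II betas are
then mapped onto the type I distribution. U-state probes map by
quantile matching of the fitted Beta components,
β′ = F⁻¹(F(β; a₂U, b₂U); a₁U, b₁U), M-state probes likewise with
upper tails, and H-state probes undergo a shift-and-dilation that
preserves the empirical gaps to the neighbouring states. Type I betas
are returned bit-identical; the transform is monotone within each
state; outputs stay in [0,1].

Numerical choices:

* EM initialisation is deterministic: threshold assignment
  (β < 0.25 → U, 0.25–0.75 → H, > 0.75 → M) followed by per-state
  method-of-moments shapes. Convergence tolerance 1e-4 on the
  log-likelihood, at most 100 iterations (a warning, not an error, on
  reaching the cap).
* The M-step solves the weighted Beta maximum-likelihood equations
  exactly (Newton on the digamma system in (log a, log b)), so the EM
  log-likelihood is non-decreasing — a tested invariant.
* Shapes are bounded to [e⁻⁶, 50]. The upper bound excludes degenerate
  point-mass components that a near-empty state would otherwise
  collapse into; a constrained M-step keeps the EM monotone.
* Betas are clipped to [1e-6, 1−1e-6] before likelihood evaluation to
  avoid boundary singularities of the Beta density.
* Posterior ties are broken toward H, the mid-range state by
  construction.
* Degenerate inputs (fewer than 100 values, or all identical) are
  errors; an H state empty at mapping time degrades to proportional
  interpolation across the U–M gap.

# Differential testing and rescue filtering

Per probe: pooled-variance two-tailed t-test,
t = (x̄_A − x̄_B)/(s_p √(1/n_A + 1/n_B)), df = n_A + n_B − 2. The
reported effect `delta_beta` is mean_B − mean_A, so the statistic and
effect have opposite signs for a gain in B — the statistic follows the
`t.test(A, B)` convention. Zero pooled variance with equal means gives
t = 0, p = 1; with unequal means p = 0, flagged `degenerate`.
q-values use the BH step-up rule q₍ᵢ₎ = min_{j≥i} p₍ⱼ₎·m/j, capped at
1, applied per contrast across all surviving probes (the two contrasts
are separate filtered tests, not a joint family).

The rescue filter requires q ≤ 0.05 in both contrasts with
Δ_{C0Z0} > 0 and Δ_{Z0Z5} < 0. Two modes:

* `sign` (default): direction only. On noisy replicate data a literal
  equality of the gain and the reversal would match almost nothing, so
  direction-plus-significance is the workable reading of
  "Z0−C0 = −(Z5−Z0)".
* `strict`: additionally |Δ_{Z0Z5} + Δ_{C0Z0}| ≤ tol·Δ_{C0Z0} with
  tol = 0.5 by default, for users who want the reversal to cancel most
  of the gain. The strict set is nested in the sign set (tested).

Gene annotation is a manifest join: sites with empty symbols are kept
(no silent drops), genes deduplicated with site counts.

# The synthetic-data generator

The generator defines the conditions under which the pipeline is
validated; its defaults are fixed once and are not tuning knobs.

* Design: 4 groups × 4 replicates, matching the study design the
  pipeline targets.
* Baselines: 0.5·Beta(2,10) + 0.5·Beta(10,2) — the bimodal
  unmethylated/methylated structure of array data, exercising the
  mixture model's state assumptions.
* Planted effects: 200 differential probes gain Δβ = 0.3 in Z0 (and
  Z5 when not rescued); 100 of them revert to baseline in Z5; C5
  mirrors C0. Planted probes are restricted to unflagged probes with
  headroom (baseline + Δβ ≤ 1): a planted hypermethylation event of
  full size is only meaningful at a site that can still gain that
  much, and without the restriction the planted truth conflates
  boundary clipping with the statistics under test. Clipping remains
  as a guard for configurations where headroom cannot hold.
* Technical model: type II betas compressed as
  β_obs = 0.5 + c(β − 0.5), c = 0.8, before Gaussian replicate noise
  (SD 0.03); observed betas bounded to [0.001, 0.999] because array
  betas are offset intensity ratios that never reach the boundary
  exactly (exact 0/1 values would sit on Beta-likelihood
  singularities no real sample produces).
* Failures: detection p-values ~Uniform(0, 0.001) for passing cells
  and Uniform(0.01, 1) for failing cells; bead counts Poisson(12)
  floored at 3, or 0–2 for failing cells. Per-cell failure rates
  (2.4e-4 and 2e-3) and annotation-flag fractions (SNP 0.11, XY
  0.019, non-CpG 0.0034, multi-map 1.3e-5) are calibrated so that a
  full-scale array would shed probes in the proportions reported for
  EPIC QC cascades.
* A fixed seed determines every output exactly (tested byte-identical
  reruns).

What the generator does **not** emulate: genomic autocorrelation of
methylation, probe-specific variance structure, batch/slide effects,
raw IDAT intensities, or sample-level QC failures. Passing the planted
recovery checks therefore demonstrates correctness of the statistics
and plumbing, not performance on real arrays.

Cell outlines are polygonized ellipses whose axis ratio is the
analytic roundness; population classes draw ratios from
truncated-normal distributions (epithelial 0.93 ± 0.02, mixed
0.50 ± 0.05, mesenchymal 0.10 ± 0.02) chosen to be well separated from
control-derived cutoffs so that class recovery is a geometry test, not
a boundary-overlap measurement. Assay masks use integer pixel
geometry, so quantifier round-trips are exact by construction.

# Morphology scoring

Roundness = AA/EA with AA the shoelace polygon area and EA = π(d/2)²
for d the maximum Feret diameter (largest pairwise vertex distance,
computed on the convex hull). For an ellipse this is exactly b/a. The
"longest axis" reading as max Feret matches line-tracing practice and
coincides with any manually drawn long axis for convex cells. The
score is invariant to translation, rotation and uniform scaling
(tested to 1e-9/1e-6).

Cutoffs come from control populations: epithelial cut = mean − SD of
epithelial controls, mesenchymal cut = mean + SD of mesenchymal
controls, with sample (n−1) SD. Overlapping cutoffs are a
configuration error, not a silent reorder. Boundary rules are
inclusive (score ≥ epithelial cut → epithelial, ≤ mesenchymal cut →
mesenchymal); the choice is documented here because the underlying
procedure is silent about ties, and it is deterministic and tested.

# Assay quantification

* Wound closure: the wound is the largest cell-free connected
  component of the t0 mask; its bounding box is the analysis window,
  tracked at later timepoints. Closure% = 100(A₀ − A_t)/A₀, clipped to
  [0,100] with the raw value and a flag preserved (retraction is
  flagged, not hidden).
* Spheroid invasion: occupied-area gain × pixel-size², floored at 0
  with flag.
* BrdU: 100·positive/total from connected-component counts.
* FOV summaries: mean ± SEM (sample SD/√n); a single field returns
  SEM 0 with a flag.

# Problem sizes

Validation runs use 20,000 probes for the planted-recovery and null
checks (the chain including BMIQ at that scale), 10,000 probes for
normalization distribution checks, 1,000-probe fixtures for exhaustive
QC oracles, 250-cell populations (750 per control arm) for morphology,
and small integer-geometry masks for the assays. These sizes give the
binomial/multinomial test bounds used in the suite comfortable
resolution while keeping the whole suite quick to run.

# Known limitations

* BMIQ here fits two mixtures per sample and maps type II onto type I;
  it does not implement cross-sample normalization, SWAN, funnorm or
  quantile alternatives.
* No region-level (DMR) calling, covariate adjustment or cell-type
  deconvolution; the unit of inference is the single probe.
* Detection p-values are inputs; the package does not recompute them
  from control-probe intensities, and raw IDAT ingestion is out of
  scope.
* The generator's distributions are stand-ins chosen for testability;
  they are not estimates of any particular cell line's biology.
* Segmentation is out of scope for both morphology (inputs are
  outlines) and assays (inputs are masks).
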
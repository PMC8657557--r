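# methylRescue

Differential-methylation "rescue site" analysis for drug-reversal
experiments on Illumina EPIC-style arrays, with companion tools for
cell-morphology scoring and mask-based functional assays.

## The problem

In partial epithelial-to-mesenchymal (p-EMT) cell models, knocking down
an EMT transcription factor can *increase* aggressiveness together with
gains in DNA methylation at specific CpG sites, and a global
demethylating drug (5-azacytidine) can revert both. The analytical
question is: **which CpG sites gain methylation upon knockdown and lose
it again under the drug?** The design has four groups — control and
knockdown cells, each under vehicle (DMSO) or 5-aza: C0, C5, Z0, Z5 —
with 4 replicates per group.

methylRescue implements that analysis end to end for probe-level array
data (beta values β ∈ [0,1] with per-cell detection p-values and bead
counts):

1. **Probe QC** — three presets: `raw` (none), `full` (detection
   p > 0.01 in any sample; bead count < 3 in ≥ 5% of samples; then
   non-CpG, SNP-associated, multi-mapping and XY probes) and `partial`
   (detection p, bead count, non-CpG only). Removals are attributed to
   the first failing stage, so per-stage counts plus survivors always
   sum to the input.
2. **BMIQ normalization** — type II probes read compressed toward 0.5
   relative to type I probes. Per sample, a three-state beta mixture
   (unmethylated U / hemimethylated H / methylated M) is fitted by EM to
   each design type; type II U and M states are quantile-mapped onto
   the type I Beta components
   (β′ = F⁻¹₁(F₂(β))), and the H state is shifted and dilated onto the
   gap between the transformed states.
3. **Differential testing** — per probe, a two-tailed unpaired
   equal-variance t-test, t = (x̄_A − x̄_B) / (s_p √(1/n_A + 1/n_B)) on
   n_A + n_B − 2 df, with Benjamini–Hochberg step-up q-values.
4. **Rescue filtering** — a site is *rescued* when Z0 − C0 > 0 and
   Z5 − Z0 < 0, both at q ≤ 0.05; `strict` mode additionally requires
   the reversal to cancel the gain,
   |Δ_{Z0Z5} + Δ_{C0Z0}| ≤ tol·Δ_{C0Z0}, operationalizing
   "Z0−C0 = −(Z5−Z0)". Sites collapse to a gene-level table.
5. **Morphology** — roundness = AA/EA: polygon area over the area of
   the circle whose diameter is the maximum Feret diameter; cutoffs are
   control means ∓ SD; cells classify as epithelial / mixed /
   mesenchymal.
6. **Assay quantifiers** — percent wound closure, spheroid invasion
   area, per-FOV mean ± SEM, BrdU-positive percentage, computed from
   binary masks or counts.

A synthetic-data module generates EPIC-like datasets with planted
differential and rescue sites (plus cell outlines and assay masks), so
every stage is testable offline against known ground truth.

## Worked example

```r
library(methylRescue)

cfg <- simulationConfig(nProbes = 5000, nDifferential = 80, nRescue = 40, seed = 7)
sim <- simulateMethylation(simulateManifest(cfg), cfg)
qc  <- runQC(sim$experiment, "full")
qc$report
#> QcReport (preset 'full'): 5000 probes in, 4229 surviving
#>   detection_p  removed 25
#>   bead_count   removed 147
#>   non_cpg      removed 14
#>   snp          removed 509
#>   multimap     removed 1
#>   xy           removed 75

norm <- bmiqNormalize(qc$experiment)
d1 <- ttestProbes(norm, "C0", "Z0")   # knockdown gain
d2 <- ttestProbes(norm, "Z0", "Z5")   # drug reversal
rescue <- identifyRescueSites(d1, d2, manifest = probeManifest(norm))
nrow(rescue)
#> [1] 39
head(rescue[, c("probe_id", "delta_C0Z0", "delta_Z0Z5", "q_C0Z0", "q_Z0Z5")], 3)
#>     probe_id delta_C0Z0 delta_Z0Z5       q_C0Z0       q_Z0Z5
#> 1 cg00000191  0.3191705 -0.3121482 0.0004047128 0.0015011679
#> 2 cg00000194  0.3367301 -0.3415280 0.0001050826 0.0009166343
#> 3 cg00000215  0.3139894 -0.2690582 0.0003071159 0.0020605924
```

Each retained site gained ~0.3 β upon knockdown (`delta_C0Z0`) and lost
it again under the drug (`delta_Z0Z5`), both below the 0.05 FDR cutoff.
Against the planted truth this run recovers 39 of 40 rescue sites with
no false positives (recall 0.97, precision 1.00). `runPipeline()` wires
the same chain behind a single validated config and writes all tables,
a funnel-count JSON and a log to a run directory.

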
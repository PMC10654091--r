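# vaxbiome

Statistical pipeline for longitudinal infant-cohort studies linking
early-life microbiome and metabolome features and antibiotic exposure to
vaccine response — aimed at biostatisticians and microbiome researchers
analysing birth cohorts with antibody titer panels, prescription logs,
16S/metagenomic count tables and metabolite profiles.

## What it implements

- **Vaccine-response outcomes.** Single-pass titer QC (remove values
  more than 3 SD from the per-antigen, per-timepoint mean), low/normal
  vaccine responder (LVR/NVR) classification — LVR when ≥ 4 of the six
  DTaP/Hib titers fall below protective thresholds (DT 0.1 IU/mL, TT
  0.1 IU/mL, PRP 0.15 µg/mL, PT 8 EU/mL, PRN 8 IU/mL, FHA 8 IU/mL) —
  and min-max normalized median composites (cross-vaccine, DTaP/Hib,
  PCV).
- **Antibiotic exposure testing.** Day-union cumulative oral exposure,
  at-birth / recent / current use flags, a zero-inflated Poisson (ZIP)
  model `P(0) = π + (1−π)e^(−λ)` with closed-form MLE, a two-group
  omnibus likelihood-ratio test (2 df) with zero/count component
  decomposition, and grouped **double FDR** (two-stage
  Benjamini–Hochberg: group-level BH on per-group minima, then BH
  within groups, final p = pairwise maximum).
- **Community metrics.** Seeded rarefaction without replacement,
  richness / Shannon (bits) / Pielou evenness, Bray–Curtis distances,
  and gene→KO aggregation with equal count splitting.
- **Association screens.** Mann–Whitney U (categorical outcome) and
  tie-aware Spearman (continuous composites) per feature, BH-corrected
  within each (timepoint × outcome × assay) family.
- **KEGG-module enrichment.** One-sided Fisher exact tests of nominally
  significant KOs against the detected-KO universe, dropping modules
  with fewer than five detected KOs, BH across tested modules, gene
  ratio k/n.
- **Synthetic cohort generator.** A 101-subject cohort emulator with
  configurable ground truth: ~16.7% LVR, block-correlated 19-antigen
  titers, ZIP oral exposure (π ≈ 0.47/0.50, λ = 10/28 by responder
  group), irregular visits with dropout, Dirichlet-multinomial count
  tables with planted KO/metabolite effects, and a synthetic module map.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on a
seeded synthetic cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R       # cohort TSVs -> results/cohort/
Rscript analysis/02_titer_outcomes.R
Rscript analysis/03_exposure_tests.R
Rscript analysis/04_diversity.R
Rscript analysis/05_associations.R
Rscript analysis/06_enrichment.R
```

Stage 3 prints the exposure battery (ten hypotheses, four double-FDR
groups). On the default seed:

```
     hypothesis          group    test    p_raw p_adjusted    decision
 cumulative_1yr cumulative_use zip_lrt 1.59e-17   6.37e-17 significant
   use_at_birth   use_at_birth  fisher 4.73e-02   6.31e-02 significant
 ...
Zero component: 62% unexposed (LVR) vs 47% (NVR), Fisher p = 0.37
Count component: median 28 vs 10 days among exposed, rank-sum p = 0.00039
```

i.e. cumulative oral use at one year separates low from normal
responders through the count component (28 vs 10 exposed days), not the
zero component — exactly the structure the generator plants. Stage 6
recovers the planted module from the association screen:

```
stool_ko:2mo:median_cross     23 nominal KOs -> enriched modules: M00001
   family                    k K  n   N        p adjusted_p gene_ratio
 stool_ko:2mo:median_cross   8 8 23 200 8.90e-09   1.78e-07      0.348
```

The same functions are available interactively:

```r
library(vaxbiome)
co  <- generate_cohort(cohort_config(seed = 101))
out <- titer_outcomes(co$titers)$outcomes       # LVR/NVR + composites
et  <- exposure_test_suite(co$exposures, out)   # double-FDR battery
```

`run_pipeline(pipeline_config(in_dir, out_dir))` executes every stage on
a cohort directory and reproduces its output tables byte-for-byte under
a fixed seed; `validate_inputs(in_dir)` gives a report-only schema check.

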
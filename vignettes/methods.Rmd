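---
title: "Methods: linking infant microbiome and antibiotic exposure to vaccine response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking infant microbiome and antibiotic exposure to vaccine response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaxbiome)
```

# The scientific problem

Infant vaccine response is heterogeneous: a minority of children fail to
reach protective antibody levels against several antigens of the routine
DTaP/Hib series even after a full schedule. `vaxbiome` implements a
statistical pipeline for longitudinal birth-cohort studies that ask
whether early-life gut and nasopharyngeal microbiome composition,
microbial gene function, stool metabolites and antibiotic exposure are
associated with later vaccine response. Every stage is exercised
end-to-end against a synthetic cohort generator with known ground truth,
so the operating characteristics of each test (calibration, power,
false-discovery behaviour) are themselves under test.

# Outcome construction

**Titer QC.** Within each (antigen, timepoint) group, a measurement more
than three standard deviations from the group mean is removed. The pass
is deliberately single-pass — mean and SD are computed over the full
group including the candidate, with the sample (n−1) SD — because an
iterated rule has no natural stopping definition and a one-shot rule
yields one removal count per time point. Values exactly at 3 SD are
retained (the rule is strict). Groups of size one cannot be tested and
are retained but logged.

**Responder classification.** A subject is a low vaccine responder (LVR)
at a timepoint when four or more of the six DTaP/Hib titers (DT, TT, PT,
FHA, PRN, PRP) fall strictly below their protective thresholds (0.1
IU/mL, 0.1 IU/mL, 8 EU/mL, 8 IU/mL, 8 IU/mL, 0.15 µg/mL respectively).
With incomplete panels we classify LVR as soon as four measured titers
are sub-threshold, NVR only when all six antigens were measured, and
`unknown` otherwise: a missing titer can only add to the sub-threshold
count, so this rule avoids manufacturing false NVR labels from
missingness while never withholding a certain LVR call.

**Continuous composites.** Titers are min-max transformed within each
(antigen, timepoint) group — preserving each distribution's shape while
placing all antigens on [0, 1] — after outlier removal (normalizing
first would let a single outlier compress the whole group's scale). A
constant group carries no information; its members are set to 0.5, which
leaves medians unbiased, with a logged warning. Three per-subject
composites are the medians across all 19 antigens (cross-vaccine),
across the 6 DTaP/Hib antigens, and across the 13 PCV serotypes, each
over whatever antigens are available.

# Antibiotic exposure model

Exposure variables come from a prescription log of (route, start day,
duration) courses. Topical courses are excluded throughout; "systemic"
means oral, IM or IV. Cumulative oral exposure at age *t* is the number
of *distinct* days of life before *t* covered by oral courses —
overlapping prescriptions are not double counted. "Use at birth" is any
systemic course starting in the first 7 days of life (the window is a
config knob; the study design says only "at the time of birth").

Cumulative oral days in a birth cohort are dominated by never-exposed
children, so the working model is a zero-inflated Poisson (ZIP):
$P(0) = \pi + (1-\pi)e^{-\lambda}$, $P(k) = (1-\pi)\lambda^k
e^{-\lambda}/k!$. The MLE has a closed profile form: the fitted zero
probability equals the observed zero fraction, and $\lambda$ solves the
zero-truncated mean equation $\lambda/(1-e^{-\lambda}) = \bar{x}_{+}$
(mean of the positive counts), found by root bracketing. When the data
show *fewer* zeros than a plain Poisson would predict the solution lies
on the $\pi = 0$ boundary and the fit collapses to Poisson(mean); an
all-zero sample is degenerate ($\pi \to 1$) and flagged rather than
returned as a number. Two responder groups are compared with an omnibus
likelihood-ratio test (separate vs pooled fits, 2 df), and the omnibus
result is decomposed for interpretation: the zero components are
compared by Fisher exact test on the exposed/unexposed table, the count
components by a Wilcoxon rank-sum test restricted to strictly positive
counts (the count-component test is a design choice of this package;
exact when tie-free and small, normal approximation otherwise).

**Grouped double FDR.** The default battery tests ten hypotheses in four
groups — cumulative use at 2 mo/4 mo/6 mo/1 yr, recent use (7-day
look-back) at 2 mo/4 mo/6 mo, current use at 2 mo/4 mo, and use at birth
— and the hypotheses within a group are strongly dependent. The
correction is a two-stage Benjamini–Hochberg: stage 1 BH-adjusts each
group's minimum raw p across groups; stage 2 BH-adjusts within each
group; a hypothesis's final adjusted p is the maximum of its
within-group value and its group's stage-1 value, so rejection requires
both the group and the hypothesis to survive. With one group the
procedure reduces exactly to BH, and the adjusted value always dominates
the raw one. The concrete staging is fixed and documented here because
published descriptions of grouped FDR control differ in detail; control
is applied at level q = 0.1 by default.

# Community metrics

Count tables are rarefied by subsampling without replacement
(multivariate hypergeometric) to a fixed depth, dropping shallower
samples; rarefaction is seeded and deterministic. Alpha diversity is
richness (features > 0), Shannon diversity $H = -\sum p_i \log_2 p_i$ in
bits, and Pielou evenness $H / \log_2 S$, undefined at richness 1. The
log base is a documented choice (the formulas are base-agnostic up to a
constant; evenness is base-invariant). Bray–Curtis dissimilarity is
$1 - 2\sum_i \min(x_i, y_i) / (\sum x + \sum y)$. Gene-level counts are
aggregated to KEGG Orthology (KO) groups by splitting each gene's count
equally among the m KOs it maps to, conserving mapped mass; fractional
KO counts are kept as reals since downstream rank-based tests are
scale-free. Default depths follow study-scale practice (2.5 M reads for
stool metagenomes, 10,000 for nasal 16S); the synthetic analyses in this
repository run at desk-scale depths (10,000 / 5,000) chosen so the whole
workflow and its tests execute in minutes — rarefaction noise is larger
at these depths, which the power properties below absorb.

# Association screens and enrichment

Samples are assigned to nominal timepoints by configurable age windows
(2 mo = [46, 75], 4 mo = [107, 137], 6 mo = [168, 198], 1 yr =
[335, 395] days; the study protocol does not print window bounds, so
these are declared defaults). When a subject has several samples in a
window, the one closest to the window center is used. Features are
tested by Mann–Whitney U against the categorical outcome (exact by full
enumeration for combined n ≤ 12 and tie-free data, tie-corrected normal
approximation otherwise — the approximation tracks enumeration within
0.02 whenever both groups have ≥ 4 observations, and the exact path
covers everything smaller) and by tie-aware Spearman correlation against
the three continuous composites. BH correction is applied strictly
within each (timepoint × outcome × assay) family and never across
families.

Module enrichment takes the nominally significant KOs (raw p < 0.05,
optionally filtered by correlation sign) from a single family and tests
each KEGG-like module by a one-sided Fisher exact (hypergeometric upper
tail) against the universe of KOs *detected in the experiment* — not the
full catalogue — after removing modules with fewer than five detected
KOs. BH runs across exactly the modules tested. The reported gene ratio
is k/n (significant KOs in the module over all significant KOs), with
k/K also emitted.

# The synthetic cohort generator

The generator emulates the structure of a 101-infant cohort followed to
age two; its defaults are the study conditions, not tuning knobs:

- **Responder structure:** each subject is LVR at year 1 with
  probability 12/72 ≈ 0.167; year-1 titer panels are assessable for a
  72/101 fraction and year-2 panels for 56/101, with 2/56 remaining LVR
  at year 2.
- **Titers:** 19 antigens drawn log-normal with a block correlation
  matrix — intra-PCV 0.7, intra-DTaP/Hib 0.4, cross-panel 0.25 —
  reflecting the empirically stronger correlation among PCV serotype
  responses. Requests outside the positive semi-definite cone are
  rejected with the offending parameters named. Designated LVR subjects
  have their six DTaP/Hib log-means shifted one log-SD below threshold
  and are then *verified* against the threshold classifier, halving
  titers until the label fires (a closed loop, so the design rate is
  realised without leaking labels into any non-planted feature).
- **Exposure:** cumulative oral days per subject are ZIP with
  $\pi =$ (0.47 NVR, 0.50 LVR) and $\lambda =$ (10, 28) — zero fractions
  matched between groups, exposure intensity not. The day total is split
  into non-overlapping 3–10-day courses inside days 14–364 whose day
  union reconstructs the total exactly. Birth exposure (prevalence 3/12
  LVR, 2/60 NVR) is emitted as an IM course so the binary at-birth
  variable and the oral ZIP variable stay decoupled; topical courses and
  second-year oral courses are added as noise that downstream stages
  must exclude or clip.
- **Visits and samples:** nominal well-visit ages (7, 14, 21, 30, 61,
  122, 183, 274, 365, 456, 548, 730 days) with ±10-day jitter and 15%
  per-visit dropout; stool specimens at 80% of kept visits, metabolite
  aliquots at 80% of those, nasal swabs at every kept visit — yielding
  sample-per-subject counts in the range reported for real cohorts of
  this design.
- **Features:** Dirichlet-multinomial counts over 200 KOs, 40 genera
  and 100 OTUs with log-normal baseline abundances. Planted KOs (the
  eight members of the first synthetic module) have a monotone shift in
  log-abundance proportional to the subject's cross-vaccine composite;
  the slope behind the `planted_ko_effect` knob was calibrated once so
  the knob reads in Spearman-rho units (effect 0.5 yields median
  |rho| ≈ 0.5 at ~60 complete cases under the default noise), and one
  metabolite carries a negative effect by the same mechanism. A
  four-KO module is always emitted to exercise the size filter.

**What the generator does not emulate:** compositional interactions or
real taxon covariance (features are exchangeable given the planted
set), age trends in diversity, indication confounding (sick visits
triggering both antibiotics and sampling), batch effects, or assay
noise beyond multinomial sampling. Passing tests therefore demonstrate
that the statistics recover the effects they were designed for under a
faithful null and a clean planted alternative — not that real-data
effect sizes will match.

# Numerical and degenerate-input choices

- Sample SD uses n−1 throughout; strict inequalities implement "more
  than 3 SD" and "below threshold".
- Spearman p-values use the t approximation (tie-safe); constant
  vectors yield missing results rather than NaN.
- All-tie rank-sum comparisons carry no evidence and return p = 1.
- ZIP fits with no positive counts are flagged degenerate; a degenerate
  group propagates a flagged LRT result (p = 1), never a silent number.
- p-values are clamped above 1e-300 before BH to avoid log-domain
  underflow in downstream sorting; adjusted values are capped at 1.
- All randomness flows from one root seed via named substreams; the
  generator and rarefaction restore the caller's RNG state.

# Verification scale

The test suite checks every statistic against an independent brute-force
oracle (hypergeometric enumeration for Fisher tests, step-up
recomputation for BH, full permutation enumeration for rank tests,
rank-then-Pearson for Spearman, a 50×50 grid search for the ZIP
likelihood) and measures calibration by simulation at fixed seeds:
20 ZIP recovery replicates at n = 5000, 1000 null and 200 alternative
LRT simulations, 20 planted-signal and 20 null cohort replicates, and
1000-seed rarefaction means — sizes chosen so the whole suite runs in
a few minutes on one core while leaving Monte-Carlo error well inside
the asserted bands. The `analysis/` scripts run the same pipeline at the
full synthetic-cohort scale and write their tables under `results/`.

# Known limitations

- The ten-hypothesis exposure battery is the documented default; the
  original roster of hypotheses behind grouped exposure testing is not
  printed in the study design, so the battery is configurable.
- The double-FDR staging is one concrete member of the family of
  two-stage BH procedures; alternatives differ in how the group-level
  p is formed.
- Enrichment treats modules as flat KO sets; completeness scoring and
  pathway topology are out of scope.
- The generator's missingness is completely at random; informative
  missingness (sicker children sampled more) is not modelled.
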
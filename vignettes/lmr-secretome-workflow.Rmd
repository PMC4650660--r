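---
title: "Methods: LMr secretome biomarker discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LMr secretome biomarker discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lmrsecretome)
```

## Overview

This package implements a biomarker-discovery workflow for
low-molecular-mass (LMr, < 15 kDa) proteins secreted or shed by cancer
cell lines, together with the clinical statistics used to verify
candidates. The workflow has five computational stages — identification
filtering with decoy-based error control, true-LMr classification by
theoretical mass, secretion-route triage, tumor-versus-normal
transcriptome meta-analysis, and cross-omics integration — plus a
verification layer (H-scores, rank tests, survival analysis). Every stage
is exercised end to end on synthetic data with known ground truth.

## Identification filtering and decoy error control

Peptide-spectrum matches arrive as a table with a score, peptide- and
protein-level identification probabilities, and a target/decoy flag. The
decoy database contains one entry per target entry with the residue order
randomly permuted, preserving length and composition exactly. Within each
score interval the false-positive rate is estimated as
`random / (random + normal)` hits; empty intervals are reported as
missing rather than zero, since a rate of 0/0 carries no information.
Score intervals default to 20 equal-width bins over the observed range;
the bin count is a parameter because interval widths are a reporting
convention, not part of the estimator.

A protein is reported for a cell line when its protein probability
exceeds `protein_prob_min` (default 0.95, strict inequality) and it has
at least `min_unique_peptides` (default 2) distinct peptide sequences
each with peptide probability above `peptide_prob_min` (default 0.95).
The unique-peptide criterion is sometimes phrased ambiguously ("more
than two") in the literature; we follow the standard Scaffold-style
convention of ≥ 2, and the threshold is configurable for users who want
the stricter reading.

## Theoretical mass and LMr classification

Intact protein mass is the sum of residue masses plus one water, with
average (IUPAC/ExPASy convention) or monoisotopic tables, cysteine
unmodified by default (carbamidomethylation is available as a flag, but
sequence-database MW columns conventionally report the unmodified
chain). A protein is a "true" LMr protein when its average mass is
strictly below 15 000 Da; the threshold is a parameter. Note that
published sequence-database MW values for the same protein can differ by
about ±1 Da between software packages owing to slightly different
average atomic masses and rounding conventions; tests therefore validate
the mass computation against an independent residue-mass oracle rather
than against any single software's printout.

## Secretion-route triage

Three predictor outputs are consumed as features: a signal-peptide
decision (call or score, positive iff ≥ 0.5), a non-classical-secretion
neural-network score in [0, 1] (positive iff ≥ 0.5, the predictor's own
published convention), and a transmembrane-helix count (positive iff
≥ 1). Routes are assigned with precedence
classical > non-classical > shedding, else unassigned. The precedence is
a design decision: the three published route counts are disjoint and
signal-peptide-positive membrane proteins occur in the reference
candidate table, which is only consistent with classical taking priority
over the membrane-shedding call. The full per-protein score table behind
the published 248-protein route split is not public, so precedence is
validated on synthetic data and on the packaged 33-row reference table.

## Transcriptome meta-analysis

Each expression dataset is a probe × sample intensity matrix with
tumor/normal labels and a probe→gene map, and a scale flag
(`linear`/`log2`) because public microarray datasets are deposited on
both scales and the deposited scale is not always documented; the flag
is a generator/input option, never inferred. Per probe we use the
pooled-variance (Student) two-sample t-test — the default in the
microarray literature of the period; Welch is available — and the
tumor/normal ratio of mean linear intensities (log2 inputs are
exponentiated first). Selection keeps probes with P < 0.05 and ratio
> 1, collapses many-to-one probe maps to the best probe (largest ratio)
per gene to avoid double-counting, ranks by ratio, and retains at most
`floor(0.025 × number of probes)` genes. The denominator is the whole
probe list rather than the significant subset — "top 2.5% of genes"
reads most naturally as a fraction of the genome-wide list — and both
the fraction and `alpha` are parameters. Ties in ratio are broken by
smaller p-value, then probe identifier, so selection is deterministic.
Aggregation across datasets is a union with per-dataset membership
flags; one dataset suffices for a gene to qualify.

## Integration

Candidates are the accessions that are simultaneously (i) below 15 kDa,
(ii) detected in ≥ 1 cell-line secretome and (iii) upregulated in ≥ 1
dataset, joined with detection flags, dataset flags and routes. Missing
predictor rows for a candidate are a join error (listing the orphans)
rather than a silent drop. The output is sorted by ascending mass with
accession as tiebreak — the published table's own ordering is irregular,
so the sort rule is ours. The packaged reference table transcribes the
published 33-candidate list verbatim ("+" flags, Y/N predictor calls,
integer masses); re-running the integration on its split inputs yields
exactly 33 candidates.

## Clinical verification statistics

The H-score of an intensity panel `(p0, p1, p2, p3)` (percentages of
cells at intensity 0–3, summing to 100) is `Σ k·pk ∈ [0, 300]`.
Dichotomization: high/low at a cutoff of 160 for a cytoplasmic marker —
the boundary direction is not fixed by convention, we take score ≥ 160
as "high" and make the cutoff configurable — and present/absent (score
> 0) for a nuclear marker invisible in normal epithelium. Rank tests use
exact enumeration for small tie-free samples and the
continuity-corrected normal approximation with midranks otherwise; all
p-values are two-sided by default. Survival uses the Kaplan–Meier
product-limit estimate (5-year survival read from the step function at
60 months), the 1-df log-rank test, and Cox proportional-hazards
regression via the survival package with Breslow tie handling (Efron
optional; Breslow is adequate at cohort scale and matches the simplest
partial-likelihood definition), convergence tolerance 1e-9, at most 50
iterations, and an explicit error on suspected monotone likelihood.
Covariate coding for multivariate models (e.g. continuous versus
dichotomized age) is left to the caller; the analysis script uses
continuous age and binary indicators.

## The synthetic-data generator

The generator's defaults define the emulated study conditions:

- `n_proteins = 2000`, `lmr_fraction = 0.084`: sequence lengths are
  log-normal (`sdlog = 0.55`, matching the heavy right tail of proteome
  mass distributions) with the location parameter solved so that the
  expected-mass length threshold for 15 kDa sits at the `lmr_fraction`
  quantile; the realized sub-15 kDa share is then within binomial
  sampling error of the target (verified at proteome scale in the
  tests). 8.4% is the sub-15 kDa share of the human reference proteome.
- `route_fractions = (0.10, 0.60, 0.03, 0.27)`: the approximate
  classical/non-classical/shedding/unassigned split reported for LMr
  secretomes.
- PSM scores: correct matches N(60, 10), incorrect N(20, 8), incorrect
  rate 10%, split evenly between target and decoy entries — so the
  expected decoy share is half the incorrect rate. Peptide probabilities
  are a logistic transform of the score; protein probabilities combine
  peptides as `1 − Π(1 − p)`. Each truly detected protein gets ≥ 2
  unique peptides so the identification filter is attainable by
  construction.
- Expression: `n_datasets = 9`, 20 tumor + 20 normal samples, 2000
  probes covering every gene at least once (surplus probes duplicate
  random genes, giving many-to-one maps), log2-scale Gaussian noise
  (sd 1), 2% spiked genes with a +2 log2 tumor shift shared across
  datasets.
- Cohort: `n_patients = 215`, marker prevalence 0.5, baseline hazard
  log(2)/60 per month (median survival 60 months in the marker-low
  group), hazard ratio 2, administrative uniform censoring with the
  horizon solved numerically for a 30% censoring fraction (the simplest
  proportional-hazards-compatible scheme). Tumor panels concentrate mass
  at high intensities for marker-high patients; normal panels at zero.

What the generator does **not** emulate: spectra and chromatography,
protein degradation products (the main reason real secretome lists
contain mostly > 15 kDa fragments), correlated probes, batch and
platform effects across datasets, informative censoring, and covariate–
marker dependence. Passing tests therefore demonstrate correctness of
the statistical machinery under idealized sampling, not robustness to
those real-data artifacts.

## Numerical choices and degenerate inputs

- Degenerate t-test inputs (both groups constant) give t = 0, p = 1 for
  equal means and p = 0 otherwise.
- A non-positive normal-group mean makes the T/N ratio undefined; the
  probe is excluded with a warning.
- All-zero paired differences give p = 1 for the signed-rank test.
- Empty FDR bins are `NA`, never 0.
- Generators save and restore the caller's RNG state, so a fixed
  configuration seed gives byte-identical outputs regardless of the
  surrounding random stream.

## Problem sizes used by the test suite

The packaged tests run the calibration checks at 10^4 probes (t-test
null), 10^3 replicates (rank tests and log-rank null), 200 replicates of
n = 1000 cohorts (Cox coverage of HR = 2), 20 replicates of PSM mixtures
(decoy-share recovery), and a 400-protein noise-free end-to-end run
whose candidate set must equal the spiked ∩ secreted ∩ LMr truth set
exactly. These sizes give 3σ binomial bands tight enough to detect
miscalibration of a few percentage points while keeping the suite fast.

## Known limitations

- Secretion-route precedence among simultaneously positive predictors is
  inferred (see above), not documented by the predictors' authors.
- The route split of a real LMr secretome cannot be recomputed without
  the underlying predictor scores, which are not public; only the 33-row
  reference subset is packaged.
- The meta-analysis assumes independent probes and datasets; no
  cross-dataset effect-size model (fixed/random effects) is attempted —
  membership flags only.
- Association tables and survival rates of the original patient cohort
  cannot be reproduced because patient-level data are not public; the
  clinical layer is validated against enumeration oracles and simulation
  truth instead.
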
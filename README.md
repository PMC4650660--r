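# lmrsecretome

Discovery of low-molecular-mass (LMr, < 15 kDa) candidate biomarkers from
cancer cell-line secretomes, with the statistics used to verify candidates
in a clinical cohort. The package is aimed at proteomics/bioinformatics
analysts who combine cell-line secretome profiling with public
tumor-versus-normal transcriptome data, here in the setting of oral cavity
squamous cell carcinoma (OSCC).

Small secreted proteins are routinely missed by standard gel-based
proteomics, yet include cytokines, chemokines and growth factors of high
biomarker value. The workflow implemented here takes peptide-spectrum
matches (PSMs) from a search of five OSCC cell-line secretomes, controls
identification error with a shuffled-decoy database, classifies "true" LMr
proteins by theoretical intact mass, triages their likely secretion route,
intersects them with genes upregulated in tumor tissue across multiple
expression datasets, and assesses the resulting candidates with
immunohistochemistry scores and survival statistics.

## The method

- **Decoy false-positive rate.** Each target sequence is randomly shuffled
  to build a decoy database. Within each score interval the false-positive
  rate is estimated as
  `random hits / (random hits + normal hits)`,
  where random hits are matches to decoy entries.
- **Identification filter.** A protein is reported per cell line when its
  protein-level probability exceeds 0.95 and it has ≥ 2 unique peptides,
  each with peptide probability > 0.95.
- **True-LMr classification.** Theoretical intact mass is the sum of
  residue masses plus one water (average or monoisotopic tables); proteins
  with mass < 15 000 Da are "true" LMr proteins.
- **Secretion-route triage.** From signal-peptide, non-classical-secretion
  (NN-score ≥ 0.5) and transmembrane-helix predictions, each protein gets
  one route under the precedence classical > non-classical > shedding,
  else unassigned.
- **Transcriptome meta-analysis.** Per dataset: pooled two-sample t-tests
  (P < 0.05), tumor/normal mean-intensity ratios, ranking by ratio and
  retention of the top 2.5% of genes; selections are aggregated across
  datasets as per-dataset membership flags.
- **Integration.** Candidates are true-LMr secretome proteins that are
  upregulated in at least one expression dataset.
- **Clinical verification.** H-score `Σ intensity × percentage` in
  [0, 300], marker dichotomization (e.g. high/low at 160), Wilcoxon
  signed-rank and rank-sum tests, Kaplan–Meier curves with 5-year rates,
  log-rank tests and Cox proportional-hazards regression (Breslow ties).

A synthetic-data module generates every input — sequence database, PSM
tables, predictor features, expression matrices, clinical cohort — with
known ground truth, so the full pipeline is testable without any external
downloads.

## Worked example

The analysis scripts under `analysis/` run the whole workflow on
synthetic data:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_proteomics_id.R
Rscript analysis/03_secretion_classify.R
Rscript analysis/04_transcriptome_meta.R
Rscript analysis/05_integrate.R
Rscript analysis/06_clinical_stats.R
```

Output from a run (seed fixed inside the scripts):

```
generated 2000 proteins (149 LMr, 7.4%), 23388 PSMs over 5 cell lines,
9 expression datasets (40 spiked genes), 215 patients (HR 2.0)
union 1948 proteins, 147 (7.5%) true LMr; 85 detected in all lines (9 LMr)
decoy FPR among PSMs with score >= 40: 0.0002
of 147 true LMr secretome proteins:
  classical       11 (7.48%)
  nonclassical    91 (61.90%)
  shedding         4 (2.72%)
  unassigned      41 (27.89%)
spiked-gene recall in the aggregate: 1.00
synthetic integration: 7 candidates (LMr secretome 147 x upregulated 127)
5-year survival: 49.4% (low) vs 23.9% (high); log-rank chi2 20.75, P = 5.22e-06
univariate Cox HR (marker high vs low): 2.09 [1.51, 2.89], P = 8.06e-06
```

Reading: of 2000 simulated proteins, 147 of the 149 sub-15 kDa proteins
were recovered in the merged secretome after decoy-controlled filtering
(decoy FPR 0.02%); route triage matches the generator's ground truth;
the meta-analysis recovers every spiked gene; integration leaves the
candidates that are simultaneously LMr, secreted and upregulated; and the
survival layer recovers the simulated hazard ratio of 2 with the expected
separation of 5-year survival.

The packaged reference table (`inst/extdata/oscc_lmr_candidates.tsv`)
carries the published 33-candidate OSCC biomarker list — masses,
per-cell-line detection flags, per-dataset upregulation flags and
predictor calls — and `intersect_candidates()` reproduces exactly 33
candidates from it.

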
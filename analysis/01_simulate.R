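#!/usr/bin/env Rscript
# Step 1: generate every pipeline input with known ground truth.
#
# The configuration below defines the study conditions emulated throughout
# the workflow: a proteome-scale sequence database in which ~8.4% of
# entries fall below 15 kDa, five cell-line secretomes, PSM score
# distributions separating correct from incorrect matches, nine
# tumor-versus-normal expression datasets with a known spiked gene set,
# and a ~215-patient cohort with a hazard ratio of 2 for the marker-high
# group.

suppressPackageStartupMessages(library(lmrsecretome))

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 20260926)

dbt <- generate_protein_database(cfg)
write_protein_fasta(dbt$db, file.path(out, "proteins.fasta"))
write_protein_fasta(shuffle_decoy_database(dbt$db, seed = cfg$seed),
                    file.path(out, "proteins_decoy.fasta"))
write_ground_truth(dbt$truth, file.path(out, "protein_truth.json"))

psm <- generate_psm_tables(dbt, cfg)
write_tsv_table(psm$psms, file.path(out, "psms.tsv"))
write_ground_truth(psm$truth, file.path(out, "detection_truth.json"))

pred <- generate_predictor_table(dbt, cfg)
write_tsv_table(pred, file.path(out, "predictors.tsv"))

ex <- generate_expression_datasets(cfg, names(dbt$db))
for (d in ex$datasets) {
  write_tsv_table(data.frame(probe = rownames(d$matrix), d$matrix,
                             check.names = FALSE),
                  file.path(out, paste0(d$dataset_id, "_matrix.tsv")))
  write_tsv_table(data.frame(sample = colnames(d$matrix), group = d$groups),
                  file.path(out, paste0(d$dataset_id, "_groups.tsv")))
  write_tsv_table(data.frame(probe = names(d$probe_map),
                             accession = unname(d$probe_map)),
                  file.path(out, paste0(d$dataset_id, "_probe_map.tsv")))
}
write_ground_truth(ex$truth, file.path(out, "expression_truth.json"))

cc <- generate_clinical_cohort(cfg)
write_tsv_table(cc$cohort, file.path(out, "cohort.tsv"))

cat(sprintf("generated %d proteins (%d LMr, %.1f%%), %d PSMs over %d cell lines,\n",
            cfg$n_proteins, sum(dbt$truth$is_lmr),
            100 * mean(dbt$truth$is_lmr), nrow(psm$psms), cfg$n_cell_lines))
cat(sprintf("%d expression datasets (%d spiked genes), %d patients (HR %.1f)\n",
            cfg$n_datasets, sum(ex$truth$spiked), cfg$n_patients,
            cfg$marker_hazard_ratio))
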
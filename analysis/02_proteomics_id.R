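#!/usr/bin/env Rscript
# Step 2: PSM filtering, decoy false-positive rate, LMr classification.
#
# Reads the simulated PSM tables and sequence database, estimates the
# score-binned decoy false-positive rate, applies the probability and
# unique-peptide identification filters per cell line, merges the
# per-cell-line lists, and classifies true LMr proteins by theoretical
# mass.

suppressPackageStartupMessages(library(lmrsecretome))

sim <- "results/sim"
psms <- read_tsv_table(file.path(sim, "psms.tsv"))
db <- read_protein_fasta(file.path(sim, "proteins.fasta"))

fdr <- estimate_false_positive_rate(psms, bin_edges = 20L, threshold = 40)
write_tsv_table(fdr$bins, "results/fdr_bins.tsv")

ids <- filter_identifications(psms)
sec <- merge_secretomes(ids)
mass <- compute_theoretical_mass(db[sec$union])
lmr <- classify_lmr(mass)

protein_list <- data.frame(
  accession = sec$union, mass_da = round(mass),
  is_lmr = lmr, as.data.frame(sec$detected),
  stringsAsFactors = FALSE, row.names = NULL)
write_tsv_table(protein_list, "results/secretome_proteins.tsv")

s <- secretome_summary(sec, setNames(lmr, sec$union))
cat(sprintf("per-cell-line identifications: %s\n",
            paste(sprintf("%s=%d", names(ids), lengths(ids)), collapse = ", ")))
cat(sprintf("union %d proteins, %d (%.1f%%) true LMr; %d detected in all lines (%d LMr)\n",
            s$n_total, s$n_lmr, s$pct_lmr, s$n_common, s$n_common_lmr))
cat(sprintf("decoy FPR among PSMs with score >= 40: %.4f\n", fdr$overall_rate))
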
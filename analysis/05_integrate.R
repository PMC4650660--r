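#!/usr/bin/env Rscript
# Step 5: cross-omics candidate integration.
#
# Intersects the true-LMr secretome with the transcriptome-upregulated
# gene set, joins detection flags, dataset flags and secretion routes,
# and writes the candidate biomarker table. Also re-runs the same
# integration on the packaged 33-row reference table as a fixed check.

suppressPackageStartupMessages(library(lmrsecretome))

prot <- read_tsv_table("results/secretome_proteins.tsv")
agg <- read_tsv_table("results/upregulated_genes.tsv")
routes <- read_tsv_table("results/lmr_secretion_routes.tsv")

lmr_tab <- prot[prot$is_lmr, setdiff(names(prot), "is_lmr")]
for (cl in setdiff(names(lmr_tab), c("accession", "mass_da")))
  lmr_tab[[cl]] <- as.logical(lmr_tab[[cl]])
for (ds in setdiff(names(agg), c("accession", "n_datasets")))
  agg[[ds]] <- as.logical(agg[[ds]])

cand <- intersect_candidates(lmr_tab, agg, routes)
write_candidate_table(cand, "results/candidate_biomarkers.tsv")

truth <- read_ground_truth("results/sim/expression_truth.json")
spiked <- truth$accession[truth$spiked]
cat(sprintf("synthetic integration: %d candidates (LMr secretome %d x upregulated %d)\n",
            nrow(cand), nrow(lmr_tab), nrow(agg)))
cat(sprintf("candidates that are truly spiked genes: %d/%d\n",
            sum(cand$accession %in% spiked), nrow(cand)))

ref <- load_reference_candidates()
ref_cand <- intersect_candidates(ref$lmr_proteins, ref$upregulated,
                                 ref$predictors)
cat(sprintf("reference-table integration: %d candidates\n", nrow(ref_cand)))
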
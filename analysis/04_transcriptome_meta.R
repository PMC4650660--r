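#!/usr/bin/env Rscript
# Step 4: tumor-versus-normal meta-analysis over the expression datasets.
#
# For each dataset: per-probe pooled t-tests (P < 0.05), T/N
# mean-intensity ratios on the linear scale, ranking by ratio and
# retention of the top 2.5% of genes; then aggregation of the selected
# sets across datasets into per-gene membership flags.

suppressPackageStartupMessages(library(lmrsecretome))

sim <- "results/sim"
ids <- sub("_matrix.tsv", "", basename(
  list.files(sim, pattern = "_matrix.tsv$")))

selections <- lapply(ids, function(id) {
  mt <- read_tsv_table(file.path(sim, paste0(id, "_matrix.tsv")))
  m <- as.matrix(mt[, -1]); rownames(m) <- mt$probe
  gr <- read_tsv_table(file.path(sim, paste0(id, "_groups.tsv")))
  pm <- read_tsv_table(file.path(sim, paste0(id, "_probe_map.tsv")))
  ds <- list(dataset_id = id, matrix = m,
             groups = gr$group[match(colnames(m), gr$sample)],
             probe_map = setNames(pm$accession, pm$probe), scale = "log2")
  sel <- select_top_upregulated(ds, alpha = 0.05, top_fraction = 0.025)
  cat(sprintf("%s: %d/%d probes significant & upregulated, %d genes kept (cap %d)\n",
              id, sum(sel$stats$p < 0.05 & sel$stats$ratio > 1, na.rm = TRUE),
              nrow(sel$stats), length(sel$selected), sel$cap))
  sel
})

agg <- aggregate_upregulated(selections)
write_tsv_table(agg, "results/upregulated_genes.tsv")

truth <- read_ground_truth(file.path(sim, "expression_truth.json"))
spiked <- truth$accession[truth$spiked]
cat(sprintf("aggregated: %d genes upregulated in >= 1 dataset, %d in all\n",
            nrow(agg), sum(agg$n_datasets == length(ids))))
cat(sprintf("spiked-gene recall in the aggregate: %.2f\n",
            mean(spiked %in% agg$accession)))
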
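#!/usr/bin/env Rscript
# Step 3: secretion-route triage of the true LMr secretome.
#
# Joins the predictor feature table onto the filtered LMr protein list
# and assigns each protein one of four routes (classical signal-peptide
# secretion, non-classical secretion, membrane shedding, unassigned)
# under the precedence classical > nonclassical > shedding.

suppressPackageStartupMessages(library(lmrsecretome))

pred <- read_tsv_table("results/sim/predictors.tsv")
prot <- read_tsv_table("results/secretome_proteins.tsv")

lmr_acc <- prot$accession[prot$is_lmr]
routes <- classify_secretion_route(pred[pred$accession %in% lmr_acc, ])
write_tsv_table(routes[, c("accession", "signalp_score",
                           "secretomep_nn_score", "tm_helix_count",
                           "secretion_route")],
                "results/lmr_secretion_routes.tsv")

s <- route_summary(routes)
cat(sprintf("of %d true LMr secretome proteins:\n", nrow(routes)))
for (i in seq_len(nrow(s)))
  cat(sprintf("  %-13s %4d (%.2f%%)\n", s$route[i], s$n[i], s$pct[i]))
cat(sprintf("secreted/shed via the three routes: %.2f%%\n",
            attr(s, "pct_secreted")))
cat(sprintf("route agreement with generator truth: %.1f%%\n",
            100 * mean(as.character(routes$secretion_route) == routes$route)))
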
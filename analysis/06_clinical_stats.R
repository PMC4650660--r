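#!/usr/bin/env Rscript
# Step 6: clinical verification statistics on the simulated cohort.
#
# H-scores for paired tumor and adjacent-normal IHC panels, a paired
# signed-rank comparison, marker dichotomization, rank-sum associations
# with clinicopathological groups, Kaplan-Meier 5-year survival,
# log-rank testing, and univariate plus multivariate Cox regression.

suppressPackageStartupMessages(library(lmrsecretome))

co <- read_tsv_table("results/sim/cohort.tsv")

tum_score <- combined_ihc_score(co[paste0("t_p", 0:3)])
nor_score <- combined_ihc_score(co[paste0("n_p", 0:3)])
sr <- wilcoxon_signed_rank(tum_score, nor_score)
cat(sprintf("tumor vs normal H-score: %.1f +/- %.1f vs %.1f +/- %.1f (signed-rank P = %.3g)\n",
            mean(tum_score), sd(tum_score), mean(nor_score), sd(nor_score),
            sr$p.value))

grp <- dichotomize_marker(tum_score, "MIF")
assoc <- do.call(rbind, lapply(c("stage_34", "perineural"), function(v) {
  w <- wilcoxon_rank_sum(tum_score[co[[v]]], tum_score[!co[[v]]])
  data.frame(variable = v, p = w$p.value)
}))
write_tsv_table(assoc, "results/clinical_associations.tsv")
cat(sprintf("association p-values: %s\n",
            paste(sprintf("%s=%.3f", assoc$variable, assoc$p), collapse = ", ")))

km <- km_estimate(co$time, co$event, grp)
lr <- logrank_test(co$time, co$event, grp)
cat(sprintf("5-year survival: %.1f%% (low) vs %.1f%% (high); log-rank chi2 %.2f, P = %.3g\n",
            100 * km$low$surv_horizon, 100 * km$high$surv_horizon,
            lr$chi2, lr$p.value))

uni <- cox_ph_fit(co$time, co$event, as.integer(grp == "high"))
multi <- cox_ph_fit(co$time, co$event, data.frame(
  marker_high = as.integer(grp == "high"),
  age = co$age, male = as.integer(co$gender == "male"),
  stage_34 = as.integer(co$stage_34),
  perineural = as.integer(co$perineural)))
write_tsv_table(rbind(cbind(model = "univariate", uni),
                      cbind(model = "multivariate", multi)),
                "results/cox_models.tsv")
cat(sprintf("univariate Cox HR (marker high vs low): %.2f [%.2f, %.2f], P = %.3g\n",
            uni$hr, uni$hr_lower95, uni$hr_upper95, uni$p))
cat(sprintf("multivariate Cox HR for the marker: %.2f, P = %.3g\n",
            multi$hr[multi$term == "marker_high"],
            multi$p[multi$term == "marker_high"]))
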
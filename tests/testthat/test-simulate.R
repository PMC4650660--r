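test_that("configuration validation rejects out-of-range parameters", {
  expect_error(sim_config(lmr_fraction = 1.2), "proportion")
  expect_error(sim_config(route_fractions = c(0.5, 0.5, 0.1, 0.1)),
               "summing to 1")
  expect_error(sim_config(n_proteins = 0), ">= 1")
  expect_error(sim_config(marker_hazard_ratio = -1), "> 0")
  expect_error(sim_config(censor_rate = -0.1), "proportion")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("all generators are deterministic under a fixed seed", {
  cfg <- sim_config(seed = 99, n_proteins = 80, n_datasets = 2,
                    n_probes = 120, n_patients = 40)
  d1 <- generate_protein_database(cfg)
  d2 <- generate_protein_database(cfg)
  expect_identical(d1, d2)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_protein_fasta(d1$db, f1); write_protein_fasta(d2$db, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(generate_psm_tables(d1, cfg), generate_psm_tables(d1, cfg))
  expect_identical(generate_predictor_table(d1, cfg),
                   generate_predictor_table(d1, cfg))
  expect_identical(generate_expression_datasets(cfg, names(d1$db)),
                   generate_expression_datasets(cfg, names(d1$db)))
  expect_identical(generate_clinical_cohort(cfg),
                   generate_clinical_cohort(cfg))
})

test_that("database size, construction targets and ground-truth keys", {
  cfg <- sim_config(seed = 1, n_proteins = 100, lmr_fraction = 0.5)
  dbt <- generate_protein_database(cfg)
  expect_length(dbt$db, 100)
  expect_equal(nrow(dbt$truth), 100)
  expect_identical(dbt$truth$accession, names(dbt$db))
  expect_false(anyDuplicated(dbt$truth$accession) > 0)
  # about half below 15 kDa at the 0.5 setting (3 sigma binomial band)
  expect_lt(abs(sum(dbt$truth$is_lmr) - 50), 3 * sqrt(100 * 0.25) + 1)
  # truth masses match recomputation from the sequences
  expect_equal(dbt$truth$mass_da, compute_theoretical_mass(dbt$db),
               tolerance = 1e-9)
})

test_that("realized proportions converge to configured values (3 sigma)", {
  n <- 10000
  cfg <- sim_config(seed = 2, n_proteins = n, lmr_fraction = 0.084)
  dbt <- generate_protein_database(cfg)
  expect_lt(abs(sum(dbt$truth$is_lmr) - n * 0.084),
            3 * sqrt(n * 0.084 * 0.916))
  rt <- table(factor(dbt$truth$route,
                     c("classical", "nonclassical", "shedding", "unassigned")))
  for (r in names(rt)) {
    p <- cfg$route_fractions[[r]]
    expect_lt(abs(rt[[r]] - n * p), 3 * sqrt(n * p * (1 - p)))
  }
})

test_that("LMr share at proteome scale matches the configured rate", {
  # full Swiss-Prot-sized database: the realized sub-15 kDa count lies in
  # the binomial 99% band around 8.4% of 20306 entries
  cfg <- sim_config(seed = 1, n_proteins = 20306, lmr_fraction = 0.084)
  dbt <- generate_protein_database(cfg)
  expected <- 0.084 * 20306
  half <- qnorm(0.995) * sqrt(20306 * 0.084 * 0.916)
  expect_lt(abs(sum(dbt$truth$is_lmr) - expected), half)
})

test_that("PSM tables honor detection truth and decoy bookkeeping", {
  cfg <- sim_config(seed = 3, n_proteins = 60, n_cell_lines = 2)
  dbt <- generate_protein_database(cfg)
  ps <- generate_psm_tables(dbt, cfg)
  expect_setequal(unique(ps$psms$cell_line), c("CL1", "CL2"))
  # every truly detected protein has >= 2 unique correct peptides
  cor <- ps$psms[ps$psms$is_correct, ]
  for (cl in c("CL1", "CL2")) {
    det <- ps$truth$accession[ps$truth$cell_line == cl]
    sub <- cor[cor$cell_line == cl, ]
    npep <- tapply(sub$peptide, sub$accession, function(p) length(unique(p)))
    expect_setequal(names(npep), det)
    expect_true(all(npep >= 2))
  }
  # decoy records are never correct; correct records are never decoys
  expect_true(all(!ps$psms$is_correct[ps$psms$is_decoy]))
  expect_true(all(!ps$psms$is_decoy[ps$psms$is_correct]))
  expect_true(all(ps$psms$peptide_prob >= 0 & ps$psms$peptide_prob <= 1))
})

test_that("zero incorrect-match rate gives an all-correct table and zero FPR", {
  cfg <- sim_config(seed = 4, n_proteins = 50, psm_incorrect_rate = 0)
  dbt <- generate_protein_database(cfg)
  ps <- generate_psm_tables(dbt, cfg)
  expect_true(all(ps$psms$is_correct))
  est <- estimate_false_positive_rate(ps$psms, threshold = -Inf)
  expect_equal(est$overall_rate, 0)
})

test_that("expression datasets carry coherent shapes, maps and spike truth", {
  cfg <- sim_config(seed = 6, n_proteins = 200, n_datasets = 3,
                    n_probes = 300, n_tumor = 5, n_normal = 4)
  dbt <- generate_protein_database(cfg)
  ex <- generate_expression_datasets(cfg, names(dbt$db))
  expect_length(ex$datasets, 3)
  for (d in ex$datasets) {
    expect_equal(dim(d$matrix), c(300, 9))
    expect_equal(sum(d$groups == "tumor"), 5)
    expect_setequal(names(d$probe_map), rownames(d$matrix))
    # every gene in the universe has at least one probe
    expect_setequal(unique(unname(d$probe_map)), names(dbt$db))
  }
  expect_equal(sum(ex$truth$spiked), round(0.02 * 200))
  expect_error(generate_expression_datasets(
    sim_config(n_tumor = 1), names(dbt$db)), "2 samples")
})

test_that("null expression data yields ~5% significant probes", {
  cfg <- sim_config(seed = 7, n_proteins = 5000, n_datasets = 1,
                    n_probes = 10000, log2_effect = 0)
  dbt <- generate_protein_database(cfg)
  ex <- generate_expression_datasets(cfg, names(dbt$db))
  sel <- select_top_upregulated(ex$datasets[[1]])
  nsig <- sum(sel$stats$p < 0.05)
  expect_lt(abs(nsig - 500), 3 * sqrt(10000 * 0.05 * 0.95))
})

test_that("clinical cohort panels, groups and censoring are coherent", {
  cfg <- sim_config(seed = 8, n_patients = 400, censor_rate = 0.3)
  cc <- generate_clinical_cohort(cfg)
  co <- cc$cohort
  expect_equal(nrow(co), 400)
  expect_equal(rowSums(co[paste0("t_p", 0:3)]), rep(100, 400),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(rowSums(co[paste0("n_p", 0:3)]), rep(100, 400),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(co$time >= 0))
  expect_true(all(co$event %in% 0:1))
  # realized censoring near the configured rate
  expect_lt(abs(mean(1 - co$event) - 0.3), 3 * sqrt(0.3 * 0.7 / 400) + 0.02)
  expect_identical(cc$truth$marker_group, co$marker_group)
})

test_that("null marker effect gives ~5% log-rank rejections over replicates", {
  rej <- vapply(1:200, function(r) {
    cfg <- sim_config(seed = 5000 + r, n_patients = 120,
                      marker_hazard_ratio = 1)
    co <- generate_clinical_cohort(cfg)$cohort
    logrank_test(co$time, co$event, co$marker_group)$p.value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})
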
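test_that("pooled t-test matches the hand-computed textbook formula", {
  a <- c(5, 6, 7, 8); b <- c(1, 2, 3, 4)
  # independent hand computation of the pooled statistic
  sp2 <- ((3) * var(a) + (3) * var(b)) / 6
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  p_hand <- 2 * pt(-abs(t_hand), df = 6)
  res <- two_sample_t_test(a, b)
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$p.value, p_hand, tolerance = 1e-12)
})

test_that("t-test degenerate and symmetric cases", {
  expect_equal(two_sample_t_test(c(2, 3, 4), c(2, 3, 4))$statistic, 0)
  expect_equal(two_sample_t_test(c(1, 1), c(1, 1)),
               list(statistic = 0, p.value = 1))
  expect_equal(two_sample_t_test(c(2, 2), c(1, 1))$p.value, 0)
  expect_error(two_sample_t_test(1, c(1, 2)), "2 values")
})

test_that("T/N ratio is a ratio of linear-scale means", {
  expect_equal(tn_ratio(c(10, 10), c(10, 10)), 1)
  expect_equal(tn_ratio(c(15, 25), c(5, 15)), 2)
  # log2 inputs are exponentiated first: (8,8)/(4,4) = 2
  expect_equal(tn_ratio(c(3, 3), c(2, 2), scale = "log2"), 2)
  expect_warning(r <- tn_ratio(c(1, 2), c(-3, 1)), "not positive")
  expect_true(is.na(r))
})

make_meta_dataset <- function(n_probes = 200, n_per_group = 10, effect = 0,
                              spiked = integer(0), seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_probes * 2 * n_per_group, 8, 1), nrow = n_probes)
  groups <- rep(c("tumor", "normal"), each = n_per_group)
  m[spiked, groups == "tumor"] <- m[spiked, groups == "tumor"] + effect
  rownames(m) <- sprintf("P%04d", seq_len(n_probes))
  list(dataset_id = "T1", matrix = m, groups = groups,
       probe_map = setNames(sprintf("ACC%04d", seq_len(n_probes)),
                            rownames(m)),
       scale = "log2")
}

test_that("selection cap follows the floor rule over all probes", {
  ds <- make_meta_dataset(n_probes = 1000, spiked = 1:80, effect = 3)
  sel <- select_top_upregulated(ds, top_fraction = 0.025)
  expect_equal(sel$cap, 25)
  expect_length(sel$selected, 25)   # >= 25 qualify, exactly 25 kept
  # all selected genes are significant and upregulated
  st <- sel$stats[match(names(ds$probe_map)[match(sel$selected, ds$probe_map)],
                        sel$stats$probe), ]
  expect_true(all(st$p < 0.05 & st$ratio > 1))
})

test_that("spiked probes with large effect are selected when under the cap", {
  ds <- make_meta_dataset(n_probes = 400, spiked = 1:8, effect = 4, seed = 3)
  sel <- select_top_upregulated(ds)
  expect_equal(sel$cap, 10)
  expect_true(all(sprintf("ACC%04d", 1:8) %in% sel$selected))
})

test_that("per-probe statistics agree with the scalar test", {
  ds <- make_meta_dataset(n_probes = 20, seed = 7)
  sel <- select_top_upregulated(ds)
  i <- 13
  ref <- two_sample_t_test(ds$matrix[i, ds$groups == "tumor"],
                           ds$matrix[i, ds$groups == "normal"])
  expect_equal(sel$stats$t[i], ref$statistic, tolerance = 1e-10)
  expect_equal(sel$stats$p[i], ref$p.value, tolerance = 1e-10)
  expect_equal(sel$stats$ratio[i],
               tn_ratio(ds$matrix[i, ds$groups == "tumor"],
                        ds$matrix[i, ds$groups == "normal"], scale = "log2"),
               tolerance = 1e-10)
})

test_that("selection is monotone in alpha and top_fraction", {
  ds <- make_meta_dataset(n_probes = 300, spiked = 1:30, effect = 1.5,
                          seed = 11)
  s1 <- select_top_upregulated(ds, alpha = 0.01, top_fraction = 0.02)
  s2 <- select_top_upregulated(ds, alpha = 0.05, top_fraction = 0.02)
  s3 <- select_top_upregulated(ds, alpha = 0.05, top_fraction = 0.1)
  expect_true(all(s1$selected %in% s2$selected))
  expect_true(all(s2$selected %in% s3$selected))
})

test_that("many-to-one probe maps collapse to the best probe per gene", {
  ds <- make_meta_dataset(n_probes = 100, spiked = 1:10, effect = 3, seed = 5)
  # map probes pairwise onto 50 genes
  ds$probe_map <- setNames(sprintf("ACC%04d", rep(1:50, each = 2)),
                           rownames(ds$matrix))
  sel <- select_top_upregulated(ds, top_fraction = 0.05)
  expect_false(anyDuplicated(sel$selected) > 0)
  # spiked probes 1:10 cover genes 1:5
  expect_true(all(sprintf("ACC%04d", 1:5) %in% sel$selected))
})

test_that("aggregation flags membership per dataset and equals brute-force union", {
  sels <- list(A = c("g1", "g2"), B = c("g2", "g3"), C = character(0))
  agg <- aggregate_upregulated(sels)
  expect_setequal(agg$accession, c("g1", "g2", "g3"))
  expect_equal(agg$n_datasets[agg$accession == "g2"], 2L)
  expect_true(agg$A[agg$accession == "g1"])
  expect_false(agg$B[agg$accession == "g1"])
  # a gene selected in a single dataset still qualifies
  expect_true("g3" %in% agg$accession)
  expect_true(all(agg$n_datasets >= 1L))
})
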
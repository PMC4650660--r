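#' Pooled-variance two-sample t-test
#'
#' Student's two-sided two-sample t-test with pooled variance, the standard
#' per-probe test for tumor-versus-normal microarray comparisons. When both
#' groups are constant with equal means the test is degenerate and `t = 0`,
#' `p = 1` by convention; constant groups with unequal means give
#' `p = 0` (infinite evidence under the pooled model).
#'
#' @param tumor_values,normal_values Numeric vectors, at least 2 finite
#'   values each.
#' @param var_equal Pooled (Student, default `TRUE`) or Welch (`FALSE`).
#' @return List with `statistic` and `p.value`.
#' @export
two_sample_t_test <- function(tumor_values, normal_values, var_equal = TRUE) {
  stopifnot(is.numeric(tumor_values), is.numeric(normal_values),
            all(is.finite(tumor_values)), all(is.finite(normal_values)))
  if (length(tumor_values) < 2L || length(normal_values) < 2L)
    stop("need at least 2 values per group")
  if (stats::var(tumor_values) == 0 && stats::var(normal_values) == 0) {
    if (mean(tumor_values) == mean(normal_values))
      return(list(statistic = 0, p.value = 1))
    return(list(statistic = sign(mean(tumor_values) - mean(normal_values)) * Inf,
                p.value = 0))
  }
  ht <- stats::t.test(tumor_values, normal_values, var.equal = var_equal)
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Tumor/normal mean-intensity ratio
#'
#' Ratio of mean tumor intensity to mean normal intensity on the linear
#' scale. Log2-scale inputs are exponentiated before averaging, so the
#' ratio is always a ratio of mean linear intensities.
#'
#' @param tumor_values,normal_values Numeric vectors of probe intensities.
#' @param scale `"linear"` (default) or `"log2"`.
#' @return The T/N ratio, or `NA` (with a warning) when the normal-group
#'   mean is not positive.
#' @export
tn_ratio <- function(tumor_values, normal_values,
                     scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  stopifnot(is.numeric(tumor_values), is.numeric(normal_values),
            length(tumor_values) >= 1L, length(normal_values) >= 1L)
  if (scale == "log2") {
    tumor_values <- 2^tumor_values
    normal_values <- 2^normal_values
  }
  mn <- mean(normal_values)
  if (mn <= 0) {
    warning("normal-group mean is not positive; T/N ratio undefined")
    return(NA_real_)
  }
  mean(tumor_values) / mn
}

#' Select the top tumor-upregulated genes of one expression dataset
#'
#' Per-probe pooled t-tests and T/N mean-intensity ratios, followed by the
#' standard two-stage selection: keep probes significant at `alpha` with
#' ratio > 1, collapse many-to-one probe maps to the best probe (largest
#' ratio) per gene, rank by ratio descending, and retain at most the top
#' `floor(top_fraction * number of probes)` genes. Ties in ratio are broken
#' by smaller p-value, then lexicographic probe id.
#'
#' @param dataset List with `matrix` (numeric probe x sample matrix with
#'   probe rownames), `groups` (character vector over samples with values
#'   `"tumor"`/`"normal"`), `probe_map` (named character vector probe ->
#'   accession), `scale` (`"linear"` or `"log2"`), and optionally
#'   `dataset_id`.
#' @param alpha Per-probe significance level; default 0.05.
#' @param top_fraction Selected fraction; the cap is
#'   `floor(top_fraction * nrow(matrix))` (denominator = all probes in the
#'   dataset). Default 0.025.
#' @param var_equal Passed to [two_sample_t_test()].
#' @return Object of class `dataset_selection`: list with `dataset_id`,
#'   `stats` (per-probe data frame: `probe`, `accession`, `t`, `p`,
#'   `ratio`), `selected` (character vector of selected accessions) and
#'   `cap`.
#' @export
select_top_upregulated <- function(dataset, alpha = 0.05,
                                   top_fraction = 0.025, var_equal = TRUE) {
  stopifnot(is.list(dataset), is.matrix(dataset$matrix))
  m <- dataset$matrix
  groups <- as.character(dataset$groups)
  if (length(groups) != ncol(m))
    stop("groups must label every sample column")
  if (!all(groups %in% c("tumor", "normal")))
    stop("groups must be 'tumor' or 'normal'")
  if (sum(groups == "tumor") < 2L || sum(groups == "normal") < 2L)
    stop("need at least 2 samples per group")
  scale <- if (is.null(dataset$scale)) "linear" else dataset$scale
  probe_map <- dataset$probe_map
  if (is.null(probe_map) || is.null(names(probe_map)))
    stop("dataset must carry a named probe_map (probe -> accession)")
  probes <- rownames(m)
  if (is.null(probes)) stop("expression matrix must have probe rownames")
  miss <- setdiff(probes, names(probe_map))
  if (length(miss))
    stop("probe_map is missing probe(s): ", paste(utils::head(miss, 5), collapse = ", "))

  tum <- m[, groups == "tumor", drop = FALSE]
  nor <- m[, groups == "normal", drop = FALSE]

  # vectorised pooled t over probes
  n1 <- ncol(tum); n2 <- ncol(nor)
  m1 <- rowMeans(tum); m2 <- rowMeans(nor)
  v1 <- apply(tum, 1L, stats::var); v2 <- apply(nor, 1L, stats::var)
  if (isTRUE(var_equal)) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- ifelse(se > 0, (m1 - m2) / se, ifelse(m1 == m2, 0, Inf * sign(m1 - m2)))
  p <- ifelse(is.finite(tstat), 2 * stats::pt(-abs(tstat), df),
              ifelse(tstat == 0, 1, 0))

  if (scale == "log2") {
    lt <- rowMeans(2^tum); ln <- rowMeans(2^nor)
  } else {
    lt <- m1; ln <- m2
  }
  ratio <- ifelse(ln > 0, lt / ln, NA_real_)

  st <- data.frame(probe = probes,
                   accession = unname(probe_map[probes]),
                   t = unname(tstat), p = unname(p), ratio = unname(ratio),
                   stringsAsFactors = FALSE)

  cap <- floor(top_fraction * nrow(m))
  elig <- st[!is.na(st$ratio) & st$p < alpha & st$ratio > 1, , drop = FALSE]
  selected <- character(0)
  if (nrow(elig) > 0L && cap > 0L) {
    # best probe (largest ratio) per accession, then rank genes by ratio
    elig <- elig[order(-elig$ratio, elig$p, elig$probe), , drop = FALSE]
    elig <- elig[!duplicated(elig$accession), , drop = FALSE]
    selected <- utils::head(elig$accession, cap)
  }
  structure(list(
    dataset_id = if (is.null(dataset$dataset_id)) NA_character_ else dataset$dataset_id,
    stats = st, selected = selected, cap = cap
  ), class = "dataset_selection")
}

#' @export
print.dataset_selection <- function(x, ...) {
  cat(sprintf("Dataset %s: %d probes, %d genes selected (cap %d)\n",
              x$dataset_id, nrow(x$stats), length(x$selected), x$cap))
  invisible(x)
}

#' Aggregate per-dataset upregulated gene selections
#'
#' Union of the selected accessions across datasets with one membership
#' flag per dataset. A gene qualifies overall when it is selected in at
#' least one dataset; genes selected nowhere do not appear.
#'
#' @param selections List of `dataset_selection` objects (or named list of
#'   accession character vectors).
#' @return Data frame: `accession`, one logical column per dataset,
#'   `n_datasets`.
#' @export
aggregate_upregulated <- function(selections) {
  stopifnot(is.list(selections), length(selections) >= 1L)
  sets <- lapply(selections, function(s) {
    if (inherits(s, "dataset_selection")) s$selected else as.character(s)
  })
  ids <- vapply(seq_along(selections), function(i) {
    s <- selections[[i]]
    id <- if (inherits(s, "dataset_selection")) s$dataset_id else names(selections)[i]
    if (is.null(id) || is.na(id)) paste0("dataset", i) else id
  }, character(1))
  if (anyDuplicated(ids)) stop("dataset ids must be unique")
  acc <- sort(unique(unlist(sets, use.names = FALSE)))
  flags <- vapply(sets, function(s) acc %in% s, logical(length(acc)))
  flags <- matrix(flags, nrow = length(acc), dimnames = list(NULL, ids))
  out <- data.frame(accession = acc, flags, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out$n_datasets <- as.integer(rowSums(flags))
  out
}
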
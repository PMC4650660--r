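#' Decoy-based false-positive rate of peptide-spectrum matches
#'
#' Bins PSM scores and, within each scoring interval, estimates the
#' false-positive rate as
#' `random hits / (random hits + normal hits)`,
#' where random hits are matches against the shuffled decoy database and
#' normal hits are matches against the target database. Also reports the
#' cumulative rate among all matches scoring at or above a threshold.
#'
#' @param psms Data frame of PSM records with at least columns `score`
#'   (numeric) and `is_decoy` (logical).
#' @param bin_edges Numeric vector of bin edges covering the observed score
#'   range, or a single integer giving the number of equal-width bins over
#'   the observed range (default 20).
#' @param threshold Optional score threshold; when given, the overall rate
#'   among PSMs with `score >= threshold` is reported.
#' @return Object of class `fdr_estimate`: a list with `bins` (data frame
#'   with `lower`, `upper`, `normal_hits`, `random_hits`, `rate`; empty
#'   bins have `rate = NA`), and, when `threshold` is supplied,
#'   `threshold` and `overall_rate`.
#' @export
estimate_false_positive_rate <- function(psms, bin_edges = 20L,
                                         threshold = NULL) {
  stopifnot(is.data.frame(psms))
  if (nrow(psms) == 0L) stop("no PSM records: false-positive rate undefined")
  if (!all(c("score", "is_decoy") %in% names(psms)))
    stop("psms must have 'score' and 'is_decoy' columns")
  stopifnot(is.numeric(psms$score), is.logical(psms$is_decoy),
            !anyNA(psms$score), !anyNA(psms$is_decoy))
  if (length(bin_edges) == 1L) {
    rng <- range(psms$score)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    bin_edges <- seq(rng[1], rng[2], length.out = as.integer(bin_edges) + 1L)
  }
  bin_edges <- sort(bin_edges)
  if (min(psms$score) < min(bin_edges) || max(psms$score) > max(bin_edges))
    stop("bin_edges do not cover the observed score range")
  idx <- findInterval(psms$score, bin_edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  nb <- length(bin_edges) - 1L
  random_hits <- tabulate(idx[psms$is_decoy], nbins = nb)
  normal_hits <- tabulate(idx[!psms$is_decoy], nbins = nb)
  tot <- random_hits + normal_hits
  rate <- ifelse(tot > 0L, random_hits / tot, NA_real_)
  out <- list(bins = data.frame(
    lower = bin_edges[-length(bin_edges)],
    upper = bin_edges[-1L],
    normal_hits = normal_hits,
    random_hits = random_hits,
    rate = rate
  ))
  if (!is.null(threshold)) {
    keep <- psms$score >= threshold
    n_rand <- sum(psms$is_decoy[keep])
    n_norm <- sum(!psms$is_decoy[keep])
    out$threshold <- threshold
    out$overall_rate <- if (n_rand + n_norm > 0L) n_rand / (n_rand + n_norm)
                        else NA_real_
  }
  class(out) <- "fdr_estimate"
  out
}

#' @export
print.fdr_estimate <- function(x, ...) {
  cat("Decoy-based false-positive rate estimate\n")
  print(x$bins, row.names = FALSE)
  if (!is.null(x$overall_rate))
    cat(sprintf("overall rate at score >= %g: %.4g\n",
                x$threshold, x$overall_rate))
  invisible(x)
}

#' Filter peptide-spectrum matches to confident protein identifications
#'
#' Applies the standard Scaffold-style protein-inference filter: a protein
#' is reported for a cell line only when its protein-level identification
#' probability exceeds `protein_prob_min` and it carries at least
#' `min_unique_peptides` distinct peptide sequences each with peptide-level
#' probability exceeding `peptide_prob_min`. Decoy records never appear in
#' the reported lists.
#'
#' @param psms Data frame with columns `cell_line`, `peptide`, `accession`,
#'   `peptide_prob`, `protein_prob` and `is_decoy`.
#' @param protein_prob_min Protein probability threshold (strict `>`);
#'   default 0.95.
#' @param peptide_prob_min Peptide probability threshold (strict `>`);
#'   default 0.95.
#' @param min_unique_peptides Minimum number of distinct qualifying peptide
#'   sequences per protein; default 2.
#' @return Named list (one element per cell line, in order of first
#'   appearance) of sorted character vectors of retained accessions.
#' @export
filter_identifications <- function(psms, protein_prob_min = 0.95,
                                   peptide_prob_min = 0.95,
                                   min_unique_peptides = 2L) {
  need <- c("cell_line", "peptide", "accession", "peptide_prob",
            "protein_prob", "is_decoy")
  miss <- setdiff(need, names(psms))
  if (length(miss))
    stop("psms is missing required column(s): ", paste(miss, collapse = ", "))
  stopifnot(is.numeric(psms$peptide_prob), is.numeric(psms$protein_prob),
            all(psms$peptide_prob >= 0 & psms$peptide_prob <= 1, na.rm = TRUE),
            all(psms$protein_prob >= 0 & psms$protein_prob <= 1, na.rm = TRUE))
  tgt <- psms[!psms$is_decoy, , drop = FALSE]
  cls <- unique(as.character(psms$cell_line))
  out <- lapply(cls, function(cl) {
    sub <- tgt[tgt$cell_line == cl & tgt$protein_prob > protein_prob_min &
                 tgt$peptide_prob > peptide_prob_min, , drop = FALSE]
    if (nrow(sub) == 0L) return(character(0))
    npep <- tapply(sub$peptide, sub$accession,
                   function(p) length(unique(p)))
    sort(names(npep)[npep >= min_unique_peptides])
  })
  names(out) <- cls
  out
}

#' Combine per-cell-line protein lists into a secretome set
#'
#' Computes the union (proteins detected in any cell line), the
#' intersection (detected in all cell lines), and a per-accession detection
#' matrix.
#'
#' @param per_cell_line Named list of accession character vectors, one per
#'   cell line.
#' @return Object of class `secretome_set`: list with `per_cell_line`,
#'   `union`, `intersection`, and `detected` (logical matrix, accession x
#'   cell line).
#' @export
merge_secretomes <- function(per_cell_line) {
  stopifnot(is.list(per_cell_line), length(per_cell_line) >= 1L,
            !is.null(names(per_cell_line)))
  sets <- lapply(per_cell_line, function(x) unique(as.character(x)))
  u <- sort(unique(unlist(sets, use.names = FALSE)))
  detected <- vapply(sets, function(s) u %in% s,
                     logical(length(u)))
  detected <- matrix(detected, nrow = length(u),
                     dimnames = list(u, names(sets)))
  structure(list(
    per_cell_line = sets,
    union = u,
    intersection = u[rowSums(detected) == length(sets)],
    detected = detected
  ), class = "secretome_set")
}

#' @export
print.secretome_set <- function(x, ...) {
  cat(sprintf("Secretome set over %d cell lines: %d proteins in union, %d in all\n",
              length(x$per_cell_line), length(x$union), length(x$intersection)))
  invisible(x)
}

#' Secretome composition summary
#'
#' Counts and percentages of the low-molecular-mass subset of a merged
#' secretome, in the form conventionally reported for secretome profiling
#' (LMr share of the union, LMr share of the core set detected in all cell
#' lines).
#'
#' @param secretome A `secretome_set` from [merge_secretomes()].
#' @param is_lmr Named logical vector (accession -> LMr flag) covering the
#'   union.
#' @param digits Decimal places for percentages; default 1.
#' @return List with `n_total`, `n_lmr`, `pct_lmr`, `n_common`,
#'   `n_common_lmr`.
#' @export
secretome_summary <- function(secretome, is_lmr, digits = 1) {
  stopifnot(inherits(secretome, "secretome_set"))
  miss <- setdiff(secretome$union, names(is_lmr))
  if (length(miss))
    stop("is_lmr is missing accession(s): ", paste(utils::head(miss, 5), collapse = ", "))
  n_total <- length(secretome$union)
  n_lmr <- sum(is_lmr[secretome$union])
  list(
    n_total = n_total,
    n_lmr = n_lmr,
    pct_lmr = round(100 * n_lmr / n_total, digits),
    n_common = length(secretome$intersection),
    n_common_lmr = sum(is_lmr[secretome$intersection])
  )
}
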
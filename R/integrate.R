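.CELL_LINES <- c("OC3", "OECM1", "SAS", "SCC4", "SCC25")
.EXPR_DATASETS <- c("E-MEXP-44", "E-TABM-302", "E-UMCU-11", "GDS1062",
                    "GDS1584", "GDS2520", "E-GEOD-13601", "GSE9349",
                    "GSE9844")

#' Intersect the true-LMr secretome with transcriptome-upregulated genes
#'
#' The candidate-integration step: candidates are the accessions that are
#' (i) true LMr proteins detected in at least one cell-line secretome and
#' (ii) upregulated in at least one expression dataset. Each candidate is
#' joined with its detection flags, dataset flags and secretion-route
#' annotation, and the table is sorted by ascending mass (gene symbol as
#' tiebreak).
#'
#' @param lmr_proteins Data frame of true-LMr secretome proteins:
#'   `accession`, `mass_da`, one logical (or `"+"`/`""`) detection column
#'   per cell line, optionally `protein_name`.
#' @param upregulated Data frame from [aggregate_upregulated()]:
#'   `accession` plus one logical flag column per dataset.
#' @param predictor_routes Data frame with `accession`, the three predictor
#'   columns and a `secretion_route` column (see
#'   [classify_secretion_route()]).
#' @param cell_lines,datasets Column names holding the detection and
#'   dataset flags; defaults are taken from the columns shared with the
#'   respective inputs.
#' @return Data frame of candidate records, one row per candidate, sorted
#'   by `mass_da` then `accession`.
#' @export
intersect_candidates <- function(lmr_proteins, upregulated, predictor_routes,
                                 cell_lines = NULL, datasets = NULL) {
  stopifnot(is.data.frame(lmr_proteins), is.data.frame(upregulated),
            is.data.frame(predictor_routes))
  for (d in list(lmr_proteins, upregulated, predictor_routes))
    if (!"accession" %in% names(d))
      stop("all inputs must be keyed by an 'accession' column")
  if (!"mass_da" %in% names(lmr_proteins))
    stop("lmr_proteins must carry 'mass_da'")

  if (is.null(cell_lines))
    cell_lines <- setdiff(names(lmr_proteins),
                          c("accession", "protein_name", "mass_da", "is_lmr"))
  if (is.null(datasets))
    datasets <- setdiff(names(upregulated), c("accession", "n_datasets"))
  if (length(cell_lines) == 0L) stop("no cell-line detection columns found")
  if (length(datasets) == 0L) stop("no dataset flag columns found")

  to_flag <- function(x) {
    if (is.logical(x)) return(x)
    trimws(as.character(x)) == "+"
  }
  det <- vapply(lmr_proteins[cell_lines], to_flag,
                logical(nrow(lmr_proteins)))
  det <- matrix(det, nrow = nrow(lmr_proteins), dimnames = list(NULL, cell_lines))
  upf <- vapply(upregulated[datasets], to_flag, logical(nrow(upregulated)))
  upf <- matrix(upf, nrow = nrow(upregulated), dimnames = list(NULL, datasets))

  lmr_ok <- lmr_proteins$mass_da < 15000 & rowSums(det) >= 1L
  lmr_acc <- lmr_proteins$accession[lmr_ok]
  up_acc <- upregulated$accession[rowSums(upf) >= 1L]
  cand <- intersect(lmr_acc, up_acc)
  if (length(cand) == 0L) {
    out <- data.frame(accession = character(0), mass_da = numeric(0))
    return(out)
  }

  orphans <- setdiff(cand, predictor_routes$accession)
  if (length(orphans))
    stop("candidate accession(s) missing from predictor_routes: ",
         paste(orphans, collapse = ", "))
  if (anyDuplicated(lmr_proteins$accession) ||
      anyDuplicated(upregulated$accession) ||
      anyDuplicated(predictor_routes$accession))
    stop("accession keys must be unique within each input")

  li <- match(cand, lmr_proteins$accession)
  ui <- match(cand, upregulated$accession)
  ri <- match(cand, predictor_routes$accession)

  out <- data.frame(accession = cand, stringsAsFactors = FALSE)
  if ("protein_name" %in% names(lmr_proteins))
    out$protein_name <- lmr_proteins$protein_name[li]
  out$mass_da <- lmr_proteins$mass_da[li]
  out <- cbind(out, as.data.frame(det[li, , drop = FALSE]))
  updf <- as.data.frame(upf[ui, , drop = FALSE], check.names = FALSE)
  out <- cbind(out, updf)
  keep_pred <- intersect(c("signalp", "secretomep", "secretomep_nn_score",
                           "tm_helix_count", "tmhmm", "secretion_route"),
                         names(predictor_routes))
  out <- cbind(out, predictor_routes[ri, keep_pred, drop = FALSE])
  out <- out[order(out$mass_da, out$accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read the candidate biomarker table
#'
#' Tab-separated serialisation of the candidate table with logical flags
#' rendered as `"+"` / empty, matching the conventional published layout.
#' `read_candidate_table()` inverts it losslessly.
#'
#' @param candidates Candidate data frame from [intersect_candidates()].
#' @param path Output file path.
#' @return `write_candidate_table()` returns `path` invisibly;
#'   `read_candidate_table()` returns the candidate data frame.
#' @export
write_candidate_table <- function(candidates, path) {
  stopifnot(is.data.frame(candidates))
  out <- candidates
  for (nm in names(out))
    if (is.logical(out[[nm]])) out[[nm]] <- ifelse(out[[nm]], "+", "")
    else if (is.factor(out[[nm]])) out[[nm]] <- as.character(out[[nm]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_candidate_table
#' @export
read_candidate_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE, na.strings = NULL)
  flag_cols <- intersect(c(.CELL_LINES, .EXPR_DATASETS), names(df))
  for (nm in flag_cols) df[[nm]] <- trimws(as.character(df[[nm]])) == "+"
  for (nm in intersect(c("mass_da", "mw_da", "secretomep_nn_score",
                         "tm_helix_count"), names(df)))
    df[[nm]] <- as.numeric(df[[nm]])
  if ("secretion_route" %in% names(df))
    df$secretion_route <- factor(df$secretion_route,
                                 levels = c("classical", "nonclassical",
                                            "shedding", "unassigned"))
  df
}

#' Load the packaged reference candidate table
#'
#' Reads the packaged transcription of the published 33-candidate OSCC LMr
#' biomarker list (per-protein mass, five cell-line detection flags, nine
#' expression-dataset upregulation flags, and the three secretion-predictor
#' calls) and splits it into the three inputs expected by
#' [intersect_candidates()], so the integration step can be exercised end
#' to end on reference data.
#'
#' @return List with `lmr_proteins`, `upregulated`, `predictors` (the
#'   latter already route-annotated via [classify_secretion_route()]), and
#'   `raw` (the table as read).
#' @export
load_reference_candidates <- function() {
  path <- system.file("extdata", "oscc_lmr_candidates.tsv",
                      package = "lmrsecretome", mustWork = TRUE)
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, na.strings = NULL)
  lmr <- data.frame(accession = raw$gene_symbol,
                    protein_name = raw$protein_name,
                    mass_da = as.numeric(raw$mw_da),
                    stringsAsFactors = FALSE)
  for (cl in .CELL_LINES) lmr[[cl]] <- trimws(raw[[cl]]) == "+"
  up <- data.frame(accession = raw$gene_symbol, stringsAsFactors = FALSE)
  for (ds in .EXPR_DATASETS) up[[ds]] <- trimws(raw[[ds]]) == "+"
  pred <- data.frame(accession = raw$gene_symbol,
                     signalp = raw$signalp,
                     secretomep = raw$secretomep,
                     tmhmm = raw$tmhmm,
                     stringsAsFactors = FALSE)
  pred <- classify_secretion_route(pred)
  list(lmr_proteins = lmr, upregulated = up, predictors = pred, raw = raw)
}
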
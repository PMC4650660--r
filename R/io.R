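#' FASTA input/output for protein databases
#'
#' Thin wrappers around Biostrings for the sequence-database interchange
#' format. Sequences are held internally as named character vectors.
#'
#' @param db Named character vector of amino-acid sequences.
#' @param path File path.
#' @return `write_protein_fasta()` returns `path` invisibly;
#'   `read_protein_fasta()` returns a named character vector.
#' @export
write_protein_fasta <- function(db, path) {
  stopifnot(is.character(db), !is.null(names(db)))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(db), path)
  invisible(path)
}

#' @rdname write_protein_fasta
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Tab-separated table input/output
#'
#' The interchange format for PSM tables, predictor tables, expression
#' matrices, probe maps and clinical tables.
#'
#' @param df Data frame.
#' @param path File path.
#' @return `write_tsv_table()` returns `path` invisibly;
#'   `read_tsv_table()` returns a data frame.
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Ground-truth JSON sidecar
#'
#' Serialises a generator's ground-truth record alongside its generated
#' files so downstream accuracy checks can reload it.
#'
#' @param truth List or data frame of ground-truth values.
#' @param path File path.
#' @return `write_ground_truth()` returns `path` invisibly;
#'   `read_ground_truth()` returns the deserialised object.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
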
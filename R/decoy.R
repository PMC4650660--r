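#' Build a shuffled decoy sequence database
#'
#' Creates one decoy entry per target entry by randomly permuting the order
#' of residues within each sequence. Length and residue composition are
#' preserved exactly; only the order changes. Decoy accessions carry a
#' distinguishing prefix so downstream code can separate target from decoy
#' hits.
#'
#' @param db Named character vector of amino-acid sequences, or a
#'   [Biostrings::AAStringSet].
#' @param seed Integer seed; shuffling is deterministic given the seed.
#' @param prefix Accession prefix for decoy entries (default `"DECOY_"`).
#' @return Object of the same class as `db` (named character vector or
#'   `AAStringSet`) with one shuffled entry per input entry.
#' @export
shuffle_decoy_database <- function(db, seed = 1L, prefix = "DECOY_") {
  was_aass <- methods::is(db, "AAStringSet")
  seqs <- if (was_aass) as.character(db) else db
  if (length(seqs) == 0L) stop("empty database: nothing to shuffle")
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  decoys <- with_seed(seed, vapply(seqs, function(s) {
    res <- strsplit(s, "", fixed = TRUE)[[1L]]
    paste(res[sample.int(length(res))], collapse = "")
  }, character(1), USE.NAMES = FALSE))
  names(decoys) <- paste0(prefix, names(seqs))
  if (was_aass) Biostrings::AAStringSet(decoys) else decoys
}

# Save/restore the global RNG state so generators are deterministic under
# their own seed without clobbering the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Run expr with a locally pinned seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  expr
}
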
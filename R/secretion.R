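#' Assign secretion routes from predictor scores
#'
#' Partitions proteins into four mutually exclusive secretion routes from
#' three standard predictor outputs: classical secretion (N-terminal signal
#' peptide), non-classical secretion (signal-peptide-independent export,
#' neural-network score), and membrane-protein ectodomain shedding
#' (predicted transmembrane helices). Precedence is
#' classical > non-classical > shedding; proteins negative on all three
#' predictors are unassigned. A signal-peptide-positive membrane protein is
#' therefore classed as classical, not shedding.
#'
#' @param scores Data frame with column `accession` plus either a
#'   signal-peptide call column `signalp` (`"Y"`/`"N"`, logical, or a
#'   numeric decision score thresholded at `sp_threshold`), a
#'   non-classical-secretion column `secretomep_nn_score` (numeric in
#'   \[0,1\], or `"Y"`/`"N"` under the name `secretomep`), and a
#'   transmembrane-helix count `tm_helix_count` (or `"Y"`/`"N"` under the
#'   name `tmhmm`).
#' @param nn_threshold Non-classical NN-score cutoff; a protein is
#'   non-classical-positive iff its score is `>=` this value. Default 0.5.
#' @param sp_threshold Signal-peptide decision-score cutoff when `signalp`
#'   is numeric; positive iff `>=`. Default 0.5.
#' @return The input data frame with an added factor column
#'   `secretion_route` with levels `classical`, `nonclassical`, `shedding`,
#'   `unassigned`.
#' @export
classify_secretion_route <- function(scores, nn_threshold = 0.5,
                                     sp_threshold = 0.5) {
  stopifnot(is.data.frame(scores))
  if (!"accession" %in% names(scores))
    stop("scores must have an 'accession' column")

  as_flag <- function(x, what, threshold = NULL) {
    if (is.logical(x)) return(x)
    if (is.character(x) || is.factor(x)) {
      x <- toupper(as.character(x))
      bad <- setdiff(unique(x[!is.na(x)]), c("Y", "N"))
      if (length(bad)) stop(what, " call column must be Y/N")
      return(x == "Y")
    }
    if (is.numeric(x)) {
      if (is.null(threshold))
        stop(what, " numeric column requires a threshold")
      return(x >= threshold)
    }
    stop("cannot interpret ", what, " column")
  }

  sp <- if ("signalp_score" %in% names(scores)) {
    s <- scores$signalp_score
    stopifnot(is.numeric(s))
    s >= sp_threshold
  } else if ("signalp" %in% names(scores))
    as_flag(scores$signalp, "signal-peptide", sp_threshold)
  else stop("missing signal-peptide column ('signalp_score' or 'signalp')")

  nc <- if ("secretomep_nn_score" %in% names(scores)) {
    s <- scores$secretomep_nn_score
    stopifnot(is.numeric(s), all(s >= 0 & s <= 1, na.rm = TRUE))
    s >= nn_threshold
  } else if ("secretomep" %in% names(scores)) {
    as_flag(scores$secretomep, "non-classical-secretion")
  } else stop("missing non-classical-secretion column ('secretomep_nn_score' or 'secretomep')")

  tm <- if ("tm_helix_count" %in% names(scores)) {
    h <- scores$tm_helix_count
    stopifnot(is.numeric(h), all(h >= 0, na.rm = TRUE))
    h >= 1
  } else if ("tmhmm" %in% names(scores)) {
    as_flag(scores$tmhmm, "transmembrane")
  } else stop("missing transmembrane column ('tm_helix_count' or 'tmhmm')")

  if (anyNA(sp) || anyNA(nc) || anyNA(tm))
    stop("predictor columns must not contain missing values")

  route <- ifelse(sp, "classical",
           ifelse(nc, "nonclassical",
           ifelse(tm, "shedding", "unassigned")))
  scores$secretion_route <- factor(
    route, levels = c("classical", "nonclassical", "shedding", "unassigned"))
  scores
}

#' Secretion-route composition summary
#'
#' Counts and percentages per route, plus the total secreted/shed share
#' (everything except unassigned), as conventionally reported for a
#' secretome list.
#'
#' @param routes Factor or character vector of routes, or a data frame with
#'   a `secretion_route` column.
#' @param digits Decimal places for percentages; default 2.
#' @return Data frame with `route`, `n`, `pct`, plus an attribute
#'   `pct_secreted` for the combined three-route share.
#' @export
route_summary <- function(routes, digits = 2) {
  if (is.data.frame(routes)) routes <- routes$secretion_route
  routes <- factor(as.character(routes),
                   levels = c("classical", "nonclassical", "shedding",
                              "unassigned"))
  if (anyNA(routes)) stop("unknown route label")
  n <- as.integer(table(routes))
  total <- length(routes)
  out <- data.frame(
    route = levels(routes),
    n = n,
    pct = round(100 * n / total, digits)
  )
  attr(out, "pct_secreted") <-
    round(100 * sum(n[1:3]) / total, digits)
  out
}
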
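# Residue masses for the 20 standard amino acids (Da).
# Average values follow the IUPAC/ExPASy convention used by search engines
# when reporting sequence-database MW; monoisotopic values are the standard
# lightest-isotope sums.
.AVG_RESIDUE_MASS <- c(
  G = 57.0519,  A = 71.0788,  S = 87.0782,  P = 97.1167,  V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

.MONO_RESIDUE_MASS <- c(
  G = 57.02146,  A = 71.03711,  S = 87.03203,  P = 97.05276,  V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

.WATER_AVG  <- 18.01528
.WATER_MONO <- 18.010565

# carbamidomethylation of cysteine (+C2H3NO), optional fixed modification
.CAM_AVG  <- 57.0513
.CAM_MONO <- 57.02146

#' Theoretical intact protein mass
#'
#' Computes the theoretical molecular mass of an intact polypeptide as the
#' sum of its residue masses plus one water, in Daltons. The average variant
#' uses average atomic masses (the convention behind sequence-database MW
#' columns); the monoisotopic variant uses lightest-isotope masses.
#'
#' @param sequence Character vector of amino-acid sequences over the 20
#'   standard one-letter codes (case-insensitive).
#' @param variant `"average"` (default) or `"monoisotopic"`.
#' @param carbamidomethyl If `TRUE`, add the carbamidomethyl fixed
#'   modification (+57.05 Da average) per cysteine. Off by default: intact
#'   sequence-database MW is conventionally reported unmodified.
#' @return Numeric vector of masses in Daltons.
#' @examples
#' compute_theoretical_mass("G")             # 75.07
#' compute_theoretical_mass("AG")            # 146.15
#' compute_theoretical_mass("PEPTIDE", variant = "monoisotopic")
#' @export
compute_theoretical_mass <- function(sequence,
                                     variant = c("average", "monoisotopic"),
                                     carbamidomethyl = FALSE) {
  variant <- match.arg(variant)
  if (length(sequence) == 0L) return(numeric(0))
  stopifnot(is.character(sequence))
  tab   <- if (variant == "average") .AVG_RESIDUE_MASS else .MONO_RESIDUE_MASS
  water <- if (variant == "average") .WATER_AVG else .WATER_MONO
  cam   <- if (variant == "average") .CAM_AVG else .CAM_MONO
  vapply(sequence, function(s) {
    if (is.na(s) || !nzchar(s))
      stop("empty sequence: theoretical mass is undefined")
    res <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
    bad <- setdiff(unique(res), names(tab))
    if (length(bad))
      stop("non-standard residue(s) in sequence: ", paste(bad, collapse = ", "))
    m <- sum(tab[res]) + water
    if (carbamidomethyl) m <- m + cam * sum(res == "C")
    m
  }, numeric(1), USE.NAMES = FALSE)
}

#' Classify a protein as true low-molecular-mass (LMr)
#'
#' A protein is a "true" LMr protein when its theoretical intact mass is
#' strictly below the threshold (default 15 kDa). The strict inequality
#' means a protein of exactly 15000 Da is not LMr.
#'
#' @param mass_da Numeric vector of theoretical masses in Daltons.
#' @param threshold_da Mass cutoff in Daltons; default 15000.
#' @return Logical vector.
#' @export
classify_lmr <- function(mass_da, threshold_da = 15000) {
  stopifnot(is.numeric(mass_da), all(mass_da > 0, na.rm = TRUE),
            is.numeric(threshold_da), length(threshold_da) == 1L)
  mass_da < threshold_da
}
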
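#' Simulation configuration
#'
#' Builds and validates the configuration object driving every synthetic
#' generator: the protein database, the peptide-spectrum-match tables, the
#' secretion-predictor table, the expression datasets and the clinical
#' cohort. Defaults emulate the study conditions of an LMr secretome
#' screen: a proteome in which ~8.4% of entries fall below 15 kDa, five
#' cell lines, a route split of roughly 10/60/3/27% among
#' classical/non-classical/shedding/unassigned for detected LMr proteins,
#' nine expression datasets and a ~200-patient cohort.
#'
#' @param seed Integer master seed; each generator derives its own
#'   sub-seed from it.
#' @param n_proteins Number of database entries.
#' @param lmr_fraction Target fraction of entries with theoretical mass
#'   < 15 kDa.
#' @param route_fractions Named or positional proportions for
#'   `classical`, `nonclassical`, `shedding`, `unassigned`; must sum to 1.
#' @param n_cell_lines Number of cell-line secretomes.
#' @param detect_fraction Fraction of database proteins truly present in
#'   each cell line's conditioned medium.
#' @param psm_correct_score_mean,psm_correct_score_sd Score distribution of
#'   correct matches.
#' @param psm_incorrect_score_mean,psm_incorrect_score_sd Score
#'   distribution of incorrect matches.
#' @param psm_incorrect_rate Fraction of PSM records that are incorrect
#'   (split evenly between target and decoy entries).
#' @param n_datasets,n_tumor,n_normal Expression meta-analysis dimensions.
#' @param n_probes Probes per expression dataset.
#' @param spiked_fraction Fraction of genes truly upregulated in tumors.
#' @param log2_effect Mean log2 shift of spiked genes in tumor samples.
#' @param expr_noise_sd Per-sample Gaussian noise SD on the log2 scale.
#' @param n_patients Cohort size.
#' @param marker_prevalence Fraction of patients in the marker-high group.
#' @param marker_hazard_ratio Hazard multiplier for the marker-high group.
#' @param baseline_hazard Event rate (per month) for the marker-low group.
#' @param censor_rate Target overall censoring proportion (administrative
#'   uniform censoring).
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_proteins = 2000L,
                       lmr_fraction = 0.084,
                       route_fractions = c(classical = 0.10,
                                           nonclassical = 0.60,
                                           shedding = 0.03,
                                           unassigned = 0.27),
                       n_cell_lines = 5L,
                       detect_fraction = 0.6,
                       psm_correct_score_mean = 60,
                       psm_correct_score_sd = 10,
                       psm_incorrect_score_mean = 20,
                       psm_incorrect_score_sd = 8,
                       psm_incorrect_rate = 0.10,
                       n_datasets = 9L,
                       n_tumor = 20L,
                       n_normal = 20L,
                       n_probes = 2000L,
                       spiked_fraction = 0.02,
                       log2_effect = 2,
                       expr_noise_sd = 1,
                       n_patients = 215L,
                       marker_prevalence = 0.5,
                       marker_hazard_ratio = 2,
                       baseline_hazard = log(2) / 60,
                       censor_rate = 0.3) {
  cfg <- list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
              lmr_fraction = lmr_fraction,
              route_fractions = route_fractions,
              n_cell_lines = as.integer(n_cell_lines),
              detect_fraction = detect_fraction,
              psm_correct_score_mean = psm_correct_score_mean,
              psm_correct_score_sd = psm_correct_score_sd,
              psm_incorrect_score_mean = psm_incorrect_score_mean,
              psm_incorrect_score_sd = psm_incorrect_score_sd,
              psm_incorrect_rate = psm_incorrect_rate,
              n_datasets = as.integer(n_datasets),
              n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
              n_probes = as.integer(n_probes),
              spiked_fraction = spiked_fraction, log2_effect = log2_effect,
              expr_noise_sd = expr_noise_sd,
              n_patients = as.integer(n_patients),
              marker_prevalence = marker_prevalence,
              marker_hazard_ratio = marker_hazard_ratio,
              baseline_hazard = baseline_hazard,
              censor_rate = censor_rate)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  props <- c("lmr_fraction", "detect_fraction", "psm_incorrect_rate",
             "spiked_fraction", "marker_prevalence", "censor_rate")
  for (p in props)
    if (!is.numeric(cfg[[p]]) || cfg[[p]] < 0 || cfg[[p]] > 1)
      stop("configuration error: ", p, " must be a proportion in [0,1]")
  rf <- cfg$route_fractions
  if (length(rf) != 4L || any(rf < 0) || abs(sum(rf) - 1) > 1e-9)
    stop("configuration error: route_fractions must be 4 proportions summing to 1")
  counts <- c("n_proteins", "n_cell_lines", "n_datasets", "n_tumor",
              "n_normal", "n_probes", "n_patients")
  for (p in counts)
    if (cfg[[p]] < 1L)
      stop("configuration error: ", p, " must be >= 1")
  for (p in c("psm_correct_score_sd", "psm_incorrect_score_sd",
              "expr_noise_sd", "baseline_hazard"))
    if (cfg[[p]] <= 0) stop("configuration error: ", p, " must be > 0")
  if (cfg$marker_hazard_ratio <= 0)
    stop("configuration error: marker_hazard_ratio must be > 0")
  invisible(cfg)
}

.AA20 <- names(.AVG_RESIDUE_MASS)

#' Generate a synthetic protein sequence database
#'
#' Random amino-acid sequences over the 20 standard residues with
#' log-normally distributed lengths, calibrated so the realized fraction
#' of entries with theoretical average mass < 15 kDa matches
#' `cfg$lmr_fraction` up to sampling error (proteome mass distributions
#' are heavy-tailed to the right, which the log-normal reproduces).
#' Ground-truth masses, LMr flags and secretion routes (drawn per
#' `route_fractions`) are recorded for every entry.
#'
#' @param cfg A [sim_config()].
#' @return List with `db` (named character vector of sequences) and
#'   `truth` (data frame: `accession`, `mass_da`, `is_lmr`, `route`).
#' @export
generate_protein_database <- function(cfg) {
  validate_sim_config(cfg)
  with_seed(cfg$seed, {
    n <- cfg$n_proteins
    # mean residue mass under uniform residue usage; length whose expected
    # mass sits at the 15 kDa cutoff
    mean_res <- mean(.AVG_RESIDUE_MASS)
    len15 <- (15000 - .WATER_AVG) / mean_res
    sdlog <- 0.55
    f <- min(max(cfg$lmr_fraction, 1e-6), 1 - 1e-6)
    meanlog <- log(len15) - sdlog * stats::qnorm(f)
    lens <- pmax(5L, round(stats::rlnorm(n, meanlog, sdlog)))
    seqs <- vapply(lens, function(L)
      paste(sample(.AA20, L, replace = TRUE), collapse = ""), character(1))
    names(seqs) <- sprintf("SP%05d", seq_len(n))
    mass <- compute_theoretical_mass(seqs)
    route <- sample(names(cfg$route_fractions), n, replace = TRUE,
                    prob = cfg$route_fractions)
    truth <- data.frame(accession = names(seqs), mass_da = mass,
                        is_lmr = classify_lmr(mass), route = route,
                        stringsAsFactors = FALSE)
    list(db = seqs, truth = truth)
  })
}

#' Generate per-cell-line peptide-spectrum-match tables
#'
#' For each cell line a random subset of database proteins is "detected";
#' each detected protein receives at least two unique correct peptides
#' whose scores follow the correct-match score distribution. Incorrect
#' matches (scores from the incorrect-match distribution) are added at
#' rate `psm_incorrect_rate`, split evenly between target and decoy
#' accessions. Peptide identification probabilities are a logistic
#' transform of the score, and protein probabilities combine the peptide
#' probabilities of each protein's peptides
#' (`1 - prod(1 - p)`). Ground-truth correctness and per-cell-line
#' detection are recorded separately from the target/decoy flag.
#'
#' @param db_truth Output of [generate_protein_database()].
#' @param cfg A [sim_config()].
#' @return List with `psms` (data frame: `cell_line`, `peptide`,
#'   `accession`, `score`, `peptide_prob`, `protein_prob`, `is_decoy`,
#'   `is_correct`) and `truth` (data frame: `cell_line`, `accession` of
#'   truly detected proteins).
#' @export
generate_psm_tables <- function(db_truth, cfg) {
  validate_sim_config(cfg)
  if (length(db_truth$db) == 0L) stop("empty protein database")
  with_seed(cfg$seed + 1L, {
    accs <- names(db_truth$db)
    # probability midpoint between the two score distributions
    mid <- (cfg$psm_correct_score_mean + cfg$psm_incorrect_score_mean) / 2
    scl <- max((cfg$psm_correct_score_mean - cfg$psm_incorrect_score_mean) / 10,
               1e-3)
    rand_pep <- function(k) vapply(seq_len(k), function(i) {
      L <- sample(7:18, 1L)
      paste0(paste(sample(.AA20, L, replace = TRUE), collapse = ""),
             sample(c("K", "R"), 1L))
    }, character(1))
    all_cl <- paste0("CL", seq_len(cfg$n_cell_lines))
    det_truth <- list(); tabs <- list()
    for (cl in all_cl) {
      det <- sort(sample(accs, max(1L, round(cfg$detect_fraction * length(accs)))))
      npep <- 2L + stats::rpois(length(det), 1.5)
      cor_acc <- rep(det, npep)
      n_cor <- length(cor_acc)
      cor_scores <- stats::rnorm(n_cor, cfg$psm_correct_score_mean,
                                 cfg$psm_correct_score_sd)
      n_inc <- if (cfg$psm_incorrect_rate >= 1) stop("psm_incorrect_rate must be < 1")
               else round(n_cor * cfg$psm_incorrect_rate / (1 - cfg$psm_incorrect_rate))
      inc_target <- sample(c(TRUE, FALSE), n_inc, replace = TRUE)
      inc_acc <- ifelse(inc_target, sample(accs, n_inc, replace = TRUE),
                        paste0("DECOY_", sample(accs, n_inc, replace = TRUE)))
      inc_scores <- stats::rnorm(n_inc, cfg$psm_incorrect_score_mean,
                                 cfg$psm_incorrect_score_sd)
      tab <- data.frame(
        cell_line = cl,
        peptide = rand_pep(n_cor + n_inc),
        accession = c(cor_acc, inc_acc),
        score = c(cor_scores, inc_scores),
        is_decoy = c(rep(FALSE, n_cor), !inc_target),
        is_correct = c(rep(TRUE, n_cor), rep(FALSE, n_inc)),
        stringsAsFactors = FALSE
      )
      tab$peptide_prob <- stats::plogis((tab$score - mid) / scl)
      pp <- tapply(tab$peptide_prob, tab$accession,
                   function(p) 1 - prod(1 - p))
      tab$protein_prob <- unname(pp[tab$accession])
      tabs[[cl]] <- tab
      det_truth[[cl]] <- data.frame(cell_line = cl, accession = det,
                                    stringsAsFactors = FALSE)
    }
    list(psms = do.call(rbind, c(tabs, list(make.row.names = FALSE))),
         truth = do.call(rbind, c(det_truth, list(make.row.names = FALSE))))
  })
}

#' Generate a secretion-predictor feature table
#'
#' Emits per-protein signal-peptide scores, non-classical-secretion
#' NN-scores and transmembrane-helix counts consistent with each protein's
#' ground-truth route: classical proteins score above the signal-peptide
#' threshold (and may additionally carry a high NN-score or transmembrane
#' helices, exercising the classification precedence), non-classical
#' proteins score at or above the NN threshold only, shedding proteins
#' carry helices only, and unassigned proteins are below threshold on all
#' three predictors.
#'
#' @param db_truth Output of [generate_protein_database()].
#' @param cfg A [sim_config()].
#' @return Data frame: `accession`, `signalp_score`, `secretomep_nn_score`,
#'   `tm_helix_count`, `route` (ground truth).
#' @export
generate_predictor_table <- function(db_truth, cfg) {
  validate_sim_config(cfg)
  with_seed(cfg$seed + 2L, {
    tr <- db_truth$truth
    n <- nrow(tr)
    sp <- stats::runif(n, 0, 0.45)
    nn <- stats::runif(n, 0, 0.45)
    tm <- integer(n)
    cls <- tr$route == "classical"
    sp[cls] <- stats::runif(sum(cls), 0.55, 1)
    # some classical proteins also look non-classical or membrane-bound,
    # exercising the classification precedence
    cls_nn <- cls & (stats::runif(n) < 0.5)
    nn[cls_nn] <- stats::runif(sum(cls_nn), 0.55, 1)
    nc <- tr$route == "nonclassical"
    nn[nc] <- stats::runif(sum(nc), 0.55, 1)
    shd <- tr$route == "shedding"
    tm[shd] <- sample(1:3, sum(shd), replace = TRUE)
    tm[cls] <- ifelse(stats::runif(sum(cls)) < 0.3,
                      sample(1:2, sum(cls), replace = TRUE), 0L)
    data.frame(accession = tr$accession,
               signalp_score = sp,
               secretomep_nn_score = nn,
               tm_helix_count = tm,
               route = tr$route,
               stringsAsFactors = FALSE)
  })
}

#' Generate tumor-versus-normal expression datasets
#'
#' Simulates log2-scale probe intensity matrices for `n_datasets`
#' datasets. Probes map (possibly many-to-one) onto the protein accession
#' universe; a fixed set of spiked genes (fraction `spiked_fraction`,
#' shared across datasets) has its tumor-group mean shifted upward by
#' `log2_effect`; all other genes have zero true shift.
#'
#' @param cfg A [sim_config()].
#' @param accession_universe Character vector of accessions to map probes
#'   onto (e.g., names of the generated protein database).
#' @return List with `datasets` (list of dataset objects as consumed by
#'   [select_top_upregulated()]) and `truth` (data frame: `accession`,
#'   `spiked`).
#' @export
generate_expression_datasets <- function(cfg, accession_universe) {
  validate_sim_config(cfg)
  if (cfg$n_tumor < 2L || cfg$n_normal < 2L)
    stop("configuration error: need >= 2 samples per group")
  accs <- unique(as.character(accession_universe))
  if (length(accs) < 2L) stop("accession universe too small")
  with_seed(cfg$seed + 3L, {
    n_spiked <- round(cfg$spiked_fraction * length(accs))
    spiked <- sort(sample(accs, n_spiked))
    truth <- data.frame(accession = accs, spiked = accs %in% spiked,
                        stringsAsFactors = FALSE)
    datasets <- lapply(seq_len(cfg$n_datasets), function(d) {
      # every gene gets >= 1 probe when the array is large enough; surplus
      # probes duplicate random genes (many-to-one probe map)
      probe_acc <- if (cfg$n_probes >= length(accs))
        sample(c(accs, sample(accs, cfg$n_probes - length(accs), replace = TRUE)))
      else sample(accs, cfg$n_probes)
      probes <- sprintf("D%d_P%05d", d, seq_len(cfg$n_probes))
      probe_map <- stats::setNames(probe_acc, probes)
      base <- stats::rnorm(cfg$n_probes, 8, 1)
      ns <- cfg$n_tumor + cfg$n_normal
      m <- matrix(stats::rnorm(cfg$n_probes * ns, 0, cfg$expr_noise_sd),
                  nrow = cfg$n_probes) + base
      groups <- c(rep("tumor", cfg$n_tumor), rep("normal", cfg$n_normal))
      is_spiked <- probe_acc %in% spiked
      m[is_spiked, groups == "tumor"] <-
        m[is_spiked, groups == "tumor"] + cfg$log2_effect
      rownames(m) <- probes
      colnames(m) <- sprintf("D%d_S%02d", d, seq_len(ns))
      list(dataset_id = sprintf("SIMD%02d", d), matrix = m, groups = groups,
           probe_map = probe_map, scale = "log2")
    })
    list(datasets = datasets, truth = truth)
  })
}

#' Generate a synthetic clinical cohort
#'
#' Per patient: tumor and adjacent-normal IHC intensity panels (four
#' percentages summing to 100, concentrated at high intensities for
#' marker-high tumors and at zero for normal epithelium), a binary marker
#' group, clinicopathological covariates, and survival under a
#' proportional-hazards model: exponential event times with the hazard of
#' the marker-high group multiplied by `marker_hazard_ratio`, and
#' administrative uniform censoring calibrated to the target censoring
#' proportion.
#'
#' @param cfg A [sim_config()].
#' @return List with `cohort` (one row per patient: `id`, `age`, `gender`,
#'   `stage_34`, `perineural`, tumor/normal panel columns `t_p0..t_p3`,
#'   `n_p0..n_p3`, `ihc_score_tumor`, `ihc_score_normal`, `marker_group`,
#'   `time`, `event`) and `truth` (list with `marker_group` and
#'   `hazard_ratio`).
#' @export
generate_clinical_cohort <- function(cfg) {
  validate_sim_config(cfg)
  with_seed(cfg$seed + 4L, {
    n <- cfg$n_patients
    high <- stats::runif(n) < cfg$marker_prevalence
    rdir <- function(alpha) {
      g <- stats::rgamma(length(alpha), alpha, 1)
      100 * g / sum(g)
    }
    tum <- t(vapply(high, function(h)
      if (h) rdir(c(0.5, 1, 4, 6)) else rdir(c(6, 4, 1, 0.5)),
      numeric(4)))
    nor <- t(vapply(seq_len(n), function(i) rdir(c(20, 2, 0.3, 0.1)),
                    numeric(4)))
    colnames(tum) <- paste0("t_p", 0:3)
    colnames(nor) <- paste0("n_p", 0:3)
    lam <- ifelse(high, cfg$baseline_hazard * cfg$marker_hazard_ratio,
                  cfg$baseline_hazard)
    tev <- stats::rexp(n, lam)
    # administrative uniform censoring C ~ U(0, tau); tau solved so that
    # P(C < T) matches the target censoring proportion for the hazard mix
    p_high <- cfg$marker_prevalence
    lam0 <- cfg$baseline_hazard
    lam1 <- lam0 * cfg$marker_hazard_ratio
    pcens <- function(tau) {
      s_int <- p_high * (1 - exp(-lam1 * tau)) / lam1 +
        (1 - p_high) * (1 - exp(-lam0 * tau)) / lam0
      s_int / tau
    }
    if (cfg$censor_rate > 0) {
      tau <- stats::uniroot(function(x) pcens(x) - cfg$censor_rate,
                            interval = c(1e-6, 1e6))$root
      cens <- stats::runif(n, 0, tau)
    } else {
      cens <- rep(Inf, n)
    }
    time <- pmin(tev, cens)
    event <- as.integer(tev <= cens)
    cohort <- data.frame(
      id = sprintf("PT%04d", seq_len(n)),
      age = round(stats::rnorm(n, 51.1, 11.8), 1),
      gender = sample(c("male", "female"), n, replace = TRUE,
                      prob = c(0.89, 0.11)),
      stage_34 = stats::runif(n) < 0.5,
      perineural = stats::runif(n) < 0.3,
      tum, nor,
      marker_group = factor(ifelse(high, "high", "low"),
                            levels = c("low", "high")),
      time = time, event = event,
      stringsAsFactors = FALSE
    )
    cohort$ihc_score_tumor <- combined_ihc_score(tum)
    cohort$ihc_score_normal <- combined_ihc_score(nor)
    list(cohort = cohort,
         truth = list(marker_group = cohort$marker_group,
                      hazard_ratio = cfg$marker_hazard_ratio))
  })
}
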
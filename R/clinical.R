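#' Combined immunohistochemistry score (H-score)
#'
#' The combined staining score is the sum over intensity levels of the
#' percentage of cells at that intensity multiplied by the intensity score
#' (0 = negative, 1 = weak, 2 = moderate, 3 = strong). Panels must account
#' for 100% of cells, so the score lies in \[0, 300\].
#'
#' @param panel Numeric vector `(p0, p1, p2, p3)` of percentages of cells
#'   at intensities 0-3, or a 4-column matrix/data frame (one panel per
#'   row).
#' @return Numeric score(s) in \[0, 300\].
#' @export
combined_ihc_score <- function(panel) {
  if (is.data.frame(panel)) panel <- as.matrix(panel)
  if (is.null(dim(panel))) panel <- matrix(panel, nrow = 1L)
  stopifnot(is.numeric(panel), ncol(panel) == 4L,
            all(panel >= 0), all(panel <= 100))
  if (any(abs(rowSums(panel) - 100) > 1e-6))
    stop("intensity percentages must sum to 100")
  drop(panel %*% 0:3)
}

#' Dichotomize a marker's IHC score
#'
#' Converts a combined IHC score into the binary patient group used for
#' survival stratification. MIF is split into high/low at a cutoff of 160
#' out of 300 (high iff score >= cutoff); HMGA2 nuclear staining is split
#' into present/absent (present iff score > 0, since normal epithelium
#' shows no staining at all).
#'
#' @param score Numeric score(s) in \[0, 300\].
#' @param marker `"MIF"` or `"HMGA2"`.
#' @param cutoff Cutoff for the high/low split; default 160 (MIF only).
#' @return Factor with levels `low`, `high` (MIF) or `absent`, `present`
#'   (HMGA2).
#' @export
dichotomize_marker <- function(score, marker = c("MIF", "HMGA2"),
                               cutoff = 160) {
  marker <- match.arg(marker)
  stopifnot(is.numeric(score), all(score >= 0 & score <= 300))
  if (marker == "MIF")
    factor(ifelse(score >= cutoff, "high", "low"), levels = c("low", "high"))
  else
    factor(ifelse(score > 0, "present", "absent"),
           levels = c("absent", "present"))
}

#' Transcript level relative to a reference gene
#'
#' Normalizes absolute transcript copy numbers to copies per `per` copies
#' of a reference housekeeping gene (conventionally GAPDH).
#'
#' @param target_copies Numeric vector of target-gene copy numbers.
#' @param reference_copies Numeric vector of reference-gene copy numbers
#'   (recycled); must be positive.
#' @param per Reporting denominator; default 1e5 (copies per 10^5
#'   reference copies).
#' @return Numeric vector of normalized copy numbers.
#' @export
relative_transcript_level <- function(target_copies, reference_copies,
                                      per = 1e5) {
  stopifnot(is.numeric(target_copies), is.numeric(reference_copies),
            all(target_copies >= 0))
  if (any(reference_copies <= 0))
    stop("reference copy numbers must be positive")
  target_copies / reference_copies * per
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Paired signed-rank test for tumor-versus-normal comparisons of the same
#' patients. Zero differences are dropped (the standard convention); if
#' all differences are zero the test is degenerate and `p = 1`. Exact
#' enumeration is used for small samples without ties, and the
#' continuity-corrected normal approximation otherwise.
#'
#' @param paired_a,paired_b Equal-length numeric vectors of paired values.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param exact_max Largest number of non-zero differences for which the
#'   exact test is attempted; default 25.
#' @return List with `statistic` (V, the sum of positive ranks) and
#'   `p.value`.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b,
                                 alternative = c("two.sided", "greater",
                                                 "less"),
                                 exact_max = 25L) {
  alternative <- match.arg(alternative)
  stopifnot(is.numeric(paired_a), is.numeric(paired_b),
            length(paired_a) == length(paired_b), length(paired_a) >= 1L)
  d <- paired_a - paired_b
  d <- d[d != 0]
  if (length(d) == 0L) return(list(statistic = NA_real_, p.value = 1))
  exact <- length(d) <= exact_max && !anyDuplicated(abs(d))
  ht <- suppressWarnings(stats::wilcox.test(
    d, alternative = alternative, exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sample rank test used for associating marker scores with binary
#' clinicopathological groups. Exact for small tie-free samples, normal
#' approximation with midranks and tie correction otherwise.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param exact_max Largest per-group size for which the exact test is
#'   attempted; default 50.
#' @return List with `statistic` (Mann-Whitney U for `group_a`) and
#'   `p.value`.
#' @export
wilcoxon_rank_sum <- function(group_a, group_b,
                              alternative = c("two.sided", "greater",
                                              "less"),
                              exact_max = 50L) {
  alternative <- match.arg(alternative)
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both groups must be nonempty")
  stopifnot(is.numeric(group_a), is.numeric(group_b))
  if (length(group_a) == 1L && length(group_b) == 1L &&
      group_a == group_b)
    return(list(statistic = 0.5, p.value = 1))
  exact <- max(length(group_a), length(group_b)) <= exact_max &&
    !anyDuplicated(c(group_a, group_b))
  ht <- suppressWarnings(stats::wilcox.test(
    group_a, group_b, alternative = alternative, exact = exact,
    correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Kaplan-Meier survival estimate per group
#'
#' Product-limit survival estimate per patient group, with the 5-year
#' (60-month) survival read from the step function (the value of S at the
#' last event time at or before 60 months).
#'
#' @param times Follow-up times (months), non-negative.
#' @param events Event indicators (1/TRUE = event, 0/FALSE = censored).
#' @param group_labels Group label per subject (any factor-able vector);
#'   if omitted, a single group is assumed.
#' @param horizon Time at which to read off survival; default 60 months.
#' @return Named list of per-group curves, each a list with `time`,
#'   `n_risk`, `n_event`, `surv` and `surv_horizon`.
#' @export
km_estimate <- function(times, events, group_labels = NULL, horizon = 60) {
  stopifnot(is.numeric(times), all(times >= 0), length(times) >= 1L)
  events <- as.integer(as.logical(events))
  if (is.null(group_labels)) group_labels <- rep("all", length(times))
  stopifnot(length(events) == length(times),
            length(group_labels) == length(times))
  g <- factor(group_labels)
  if (any(table(g) == 0L)) stop("empty group")
  out <- lapply(levels(g), function(lv) {
    i <- g == lv
    fit <- survival::survfit(survival::Surv(times[i], events[i]) ~ 1)
    sh <- summary(fit, times = horizon, extend = TRUE)
    list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
         surv = fit$surv, surv_horizon = sh$surv)
  })
  names(out) <- levels(g)
  out
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected chi-square log-rank test on one degree
#' of freedom, for binary patient stratifications.
#'
#' @param times,events,group_labels As in [km_estimate()]; exactly two
#'   groups required.
#' @return List with `chi2` and `p.value`.
#' @export
logrank_test <- function(times, events, group_labels) {
  g <- factor(group_labels)
  if (nlevels(g) != 2L) stop("log-rank test requires exactly 2 groups")
  if (any(table(g) == 0L)) stop("empty group")
  events <- as.integer(as.logical(events))
  fit_sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  list(chi2 = unname(fit_sd$chisq),
       p.value = stats::pchisq(fit_sd$chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards regression
#'
#' Partial-likelihood Cox model fit for univariate or multivariate risk
#' factor analysis. Breslow tie handling by default (Efron available);
#' Newton-type maximization with a tight convergence tolerance.
#'
#' @param times,events As in [km_estimate()].
#' @param covariates Numeric vector, matrix or data frame of covariates
#'   (one column per covariate; factors in data frames are expanded by the
#'   usual treatment coding).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return Data frame with one row per coefficient: `coef`, `hr`, `se`,
#'   `z`, `p`, `hr_lower95`, `hr_upper95`.
#' @export
cox_ph_fit <- function(times, events, covariates, ties = c("breslow",
                                                           "efron")) {
  ties <- match.arg(ties)
  events <- as.integer(as.logical(events))
  if (sum(events) < 1L) stop("at least one event is required")
  if (is.null(dim(covariates)))
    covariates <- data.frame(x = covariates)
  covariates <- as.data.frame(covariates)
  if (any(vapply(covariates, function(x) length(unique(x)) == 1L,
                 logical(1))))
    stop("covariate constant across all subjects")
  fit <- survival::coxph(
    survival::Surv(times, events) ~ ., data = covariates, ties = ties,
    control = survival::coxph.control(eps = 1e-9, iter.max = 50))
  if (any(!is.finite(stats::coef(fit))) ||
      any(sqrt(diag(stats::vcov(fit))) > 1e3))
    stop("Cox fit did not converge (possible monotone likelihood / separation)")
  s <- summary(fit)
  data.frame(
    term = rownames(s$coefficients),
    coef = s$coefficients[, "coef"],
    hr = s$coefficients[, "exp(coef)"],
    se = s$coefficients[, "se(coef)"],
    z = s$coefficients[, "z"],
    p = s$coefficients[, "Pr(>|z|)"],
    hr_lower95 = s$conf.int[, "lower .95"],
    hr_upper95 = s$conf.int[, "upper .95"],
    row.names = NULL, stringsAsFactors = FALSE
  )
}
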
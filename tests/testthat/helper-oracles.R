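# Independent brute-force oracles used across test files. These are kept
# deliberately naive (enumeration, grid search, hand formulas) and never
# share code with the implementation under test.

# exact signed-rank p-value by enumeration of all 2^n sign patterns
enumerate_signed_rank_p <- function(d, alternative = "greater") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  v_all <- apply(signs, 1L, function(s) sum(r[as.logical(s)]))
  switch(alternative,
         greater = mean(v_all >= v_obs),
         less = mean(v_all <= v_obs),
         two.sided = min(1, 2 * min(mean(v_all >= v_obs),
                                    mean(v_all <= v_obs))))
}

# exact rank-sum p-value by enumeration of all group-a rank assignments
enumerate_rank_sum_p <- function(a, b) {
  n <- length(a) + length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_along(a)])
  combs <- utils::combn(n, length(a))
  w_all <- apply(combs, 2L, function(i) sum(r[i]))
  min(1, 2 * min(mean(w_all >= w_obs), mean(w_all <= w_obs)))
}

# hand product-limit estimator (no grouping, right censoring)
hand_km <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  s <- 1
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    at_risk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events == 1)
    s <- s * (1 - d / at_risk)
    out[i] <- s
  }
  list(time = ut, surv = out)
}

# hand log-rank chi-square from per-event-time hypergeometric terms
hand_logrank_chi2 <- function(times, events, group) {
  g <- as.integer(factor(group)) == 1L
  ut <- sort(unique(times[events == 1]))
  o_minus_e <- 0; v <- 0
  for (t in ut) {
    at_risk <- times >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g)
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Breslow log partial likelihood for a single covariate, brute force
hand_cox_loglik <- function(beta, times, events, x) {
  ll <- 0
  for (i in which(events == 1)) {
    risk <- times >= times[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# minimal PSM data frame builder
make_psms <- function(score, is_decoy, cell_line = "CL1",
                      accession = paste0("P", seq_along(score)),
                      peptide = paste0("PEP", seq_along(score), "K"),
                      peptide_prob = rep(0.99, length(score)),
                      protein_prob = rep(0.99, length(score))) {
  data.frame(cell_line = cell_line, peptide = peptide,
             accession = accession, score = score,
             peptide_prob = peptide_prob, protein_prob = protein_prob,
             is_decoy = is_decoy, stringsAsFactors = FALSE)
}
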
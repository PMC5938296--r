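# Shared fixtures and independent oracles for the test suite.

# hand-built grading records
make_records <- function(n = 10, seed = 1) {
  set.seed(seed)
  d <- default_design()
  i <- sample.int(nrow(d), n, replace = TRUE)
  data.frame(
    patient_id = sprintf("P%02d", sample.int(5, n, replace = TRUE)),
    observer_id = sample(c("A", "B"), n, replace = TRUE),
    criterion = sample.int(6, n, replace = TRUE),
    left_mAs = d$left_mAs[i], left_algo = d$left_algo[i],
    right_mAs = d$right_mAs[i], right_algo = d$right_algo[i],
    score = sample(-2:2, n, replace = TRUE),
    replicate_index = rep(0L, n))
}

# independent cumulative-logit log-likelihood: probabilities written directly
# as logistic CDF differences, no code shared with the fitted path
oracle_cl_loglik <- function(theta, a, dlog, y) {
  if (any(diff(theta) <= 0)) return(-Inf)
  th <- c(-Inf, theta, Inf)
  eta <- a * dlog
  sum(log(plogis(th[y + 1L] - eta) - plogis(th[y] - eta)))
}

# brute-force weighted kappa straight from the formula, double loop
oracle_weighted_kappa <- function(tab, scheme = "linear") {
  K <- nrow(tab)
  n <- sum(tab)
  num <- 0; den <- 0
  for (i in seq_len(K)) for (j in seq_len(K)) {
    w <- abs(i - j) / (K - 1)
    if (scheme == "quadratic") w <- w^2
    num <- num + w * tab[i, j] / n
    den <- den + w * (sum(tab[i, ]) / n) * (sum(tab[, j]) / n)
  }
  1 - num / den
}

# mirror every pair and negate every score
flip_records <- function(records) {
  out <- records
  out$left_mAs <- records$right_mAs
  out$left_algo <- records$right_algo
  out$right_mAs <- records$left_mAs
  out$right_algo <- records$left_algo
  out$score <- -records$score
  out
}
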
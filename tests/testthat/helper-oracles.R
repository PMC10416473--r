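# Independent re-implementations of the closed-form statistics, written
# against the cellwise/definitional forms rather than the package's
# vectorised algebra, for dual-route checks.

oracle_ror <- function(a, b, c, d) {
  or <- (a / c) / (b / d)                      # ratio-of-ratios form
  se <- sqrt(sum(1 / c(a, b, c, d)))
  list(est = or, lo = or * exp(-1.96 * se), hi = or * exp(1.96 * se))
}

oracle_prr <- function(a, b, c, d) {
  (a / (a + b)) / (c / (c + d))
}

# chi-squared via the cellwise sum of (O - E)^2 / E
oracle_chi2 <- function(a, b, c, d) {
  obs <- matrix(as.numeric(c(a, b, c, d)), 2, 2, byrow = TRUE)
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  sum((obs - expd)^2 / expd)
}

oracle_ic <- function(a, b, c, d) {
  n <- a + b + c + d
  e <- (a + b) * (a + c) / n
  ic <- (log(a + 0.5) - log(e + 0.5)) / log(2)
  list(ic = ic,
       ic025 = ic - 3.3 / sqrt(a + 0.5) - 2 / sqrt(a + 0.5)^3)
}

oracle_ebgm_simple <- function(a, b, c, d) {
  n <- a + b + c + d
  est <- (a / ((a + b) * (a + c))) * n
  se <- sqrt(sum(1 / c(a, b, c, d)))
  list(est = est, lo05 = est * exp(-1.645 * se))
}

# Random strictly-positive 2x2 tables for property sweeps.
random_tables <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    a = sample(1:500, n, replace = TRUE),
    b = sample(1:5000, n, replace = TRUE),
    c = sample(1:5000, n, replace = TRUE),
    d = sample(100:100000, n, replace = TRUE))
}

# Small deterministic cohort shared across io tests.
tiny_sim <- function(n_cases = 400, seed = 11, ...) {
  simulate_reports(sim_config(n_cases = n_cases, seed = seed, ...))
}
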
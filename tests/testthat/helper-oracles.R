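# Independent oracles: deliberately naive implementations (explicit loops,
# direct formulas, exhaustive enumeration) used only to check the package's
# fast paths on small inputs.

# Efron partial log-likelihood, written directly from its definition with
# loops over death times.
oracle_cox_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    deaths <- which(time == t & event == 1)
    risk <- which(time >= t)
    d <- length(deaths)
    s_risk <- sum(exp(beta * x[risk]))
    s_death <- sum(exp(beta * x[deaths]))
    ll <- ll + sum(beta * x[deaths])
    for (l in seq_len(d) - 1) ll <- ll - log(s_risk - (l / d) * s_death)
  }
  ll
}

oracle_cox_fit <- function(x, time, event, lower = -30, upper = 30) {
  stats::optimize(function(b) oracle_cox_loglik(b, x, time, event),
                  c(lower, upper), maximum = TRUE, tol = 1e-10)$maximum
}

# Two-group log-rank chi-square from the observed-minus-expected table,
# assembled by hand at each death time.
oracle_logrank <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(c(0, 1), c(length(time_a), length(time_b)))
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi <- o_minus_e^2 / v
  list(chi_square = chi, p_value = stats::pchisq(chi, 1, lower.tail = FALSE))
}

# Product-limit estimator by direct recursion over event times.
oracle_km <- function(time, event) {
  s <- 1
  out <- data.frame(time = 0, survival = 1)
  for (t in sort(unique(time[event == 1]))) {
    n <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n)
    out <- rbind(out, data.frame(time = t, survival = s))
  }
  out
}

# Hypergeometric upper-tail by direct choose() products (exact for small M).
oracle_hyper_direct <- function(x, K, N, M) {
  if (x == 0) return(1)
  i <- 0:(x - 1)
  1 - sum(choose(K, i) * choose(M - K, N - i)) / choose(M, N)
}

# ... and by literal enumeration of every size-N draw from the universe.
oracle_hyper_enum <- function(x, K, N, M) {
  draws <- utils::combn(M, N)
  mean(colSums(draws <= K) >= x)
}

# Two-sided exact Wilcoxon rank-sum p by enumerating all group assignments.
oracle_wilcoxon <- function(a, b) {
  m <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  center <- m * length(b) / 2
  assignments <- utils::combn(length(pooled), m)
  u_all <- apply(assignments, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  mean(abs(u_all - center) >= abs(u_obs - center) - 1e-9)
}

# Minimal stand-ins for fitted objects, for unit tests of downstream steps.
make_signature <- function(sites, coefficients, p_values = rep(0.01, length(sites))) {
  entries <- data.frame(site = sites, coefficient = coefficients,
                        p_value = p_values, stringsAsFactors = FALSE)
  structure(list(entries = entries,
                 positive_sites = sites[coefficients >= 0],
                 negative_sites = sites[coefficients < 0],
                 alpha = 0.05, training_samples = character(0), source = "test"),
            class = "prognostic_signature")
}

make_net <- function(degrees) {
  structure(list(degree = degrees), class = "methnet")
}

# A tiny deterministic beta-value matrix.
toy_matrix <- function(n_sites = 6, n_samples = 8, seed = 42) {
  m <- methnetprog:::with_seed(seed,
    matrix(stats::runif(n_sites * n_samples), nrow = n_sites))
  dimnames(m) <- list(sprintf("cg%02d", seq_len(n_sites)),
                      sprintf("S%02d", seq_len(n_samples)))
  m
}

toy_clinical <- function(samples, seed = 99, event_rate = 0.7) {
  methnetprog:::with_seed(seed, data.frame(
    sample = samples,
    time_days = stats::rexp(length(samples), 1 / 1000),
    event = stats::rbinom(length(samples), 1, event_rate),
    stringsAsFactors = FALSE))
}
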
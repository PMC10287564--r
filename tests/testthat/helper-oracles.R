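# Independent oracles, written before the implementations they check.

# Efron-approximation Cox partial log-likelihood for one stratum with
# delayed entry, hand-written from the definition: for each distinct event
# time t with tied event set D (|D| = d), the risk set is
# {i : entry_i < t <= exit_i} and the contribution is
# beta * sum(x_D) - sum_{j=0}^{d-1} log(sum_R e^{bx} - (j/d) sum_D e^{bx}).
efron_loglik <- function(beta, entry, exit, event, x) {
  ll <- 0
  for (t in sort(unique(exit[event == 1]))) {
    D <- which(event == 1 & exit == t)
    R <- which(entry < t & exit >= t)
    d <- length(D)
    rs <- sum(exp(beta * x[R]))
    ds <- sum(exp(beta * x[D]))
    ll <- ll + beta * sum(x[D]) -
      sum(log(rs - ((seq_len(d) - 1) / d) * ds))
  }
  ll
}

# brute-force maximizer of the Efron partial likelihood
efron_mle <- function(entry, exit, event, x, lower = -8, upper = 8) {
  stats::optimize(function(b) efron_loglik(b, entry, exit, event, x),
                  c(lower, upper), maximum = TRUE, tol = 1e-10)$maximum
}

# brute-force Benjamini-Hochberg adjusted p-values from the definition:
# adj_i = min(1, min over j with p_j >= p_i of m * p_j / rank(p_j)),
# rank(p_j) = number of p-values <= p_j
bh_brute <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    cand <- p[p >= pi]
    min(1, min(m * cand / vapply(cand, function(pj) sum(p <= pj),
                                 numeric(1))))
  }, numeric(1))
}

# random tiny survival dataset (one stratum) with ties and both exposure
# groups represented among events; returns NULL when degenerate
tiny_cox_data <- function(n = 8) {
  entry <- runif(n, 35, 45)
  exit <- round(entry + runif(n, 1, 10))
  entry <- pmin(entry, exit - 0.5)
  event <- rbinom(n, 1, 0.7)
  x <- rbinom(n, 1, 0.5)
  if (sum(event[x == 1]) == 0 || sum(event[x == 0]) == 0) return(NULL)
  data.frame(entry = entry, exit = exit, event = event, x = x,
             age_band = "all")
}
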
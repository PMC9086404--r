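# shared fixtures and small independent reference implementations

random_trend <- function(m, states = c(-1L, 0L, 1L)) {
  sample(states, m, replace = TRUE)
}

# textbook Benjamini-Hochberg step-up, written independently of p.adjust
bh_reference <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# truncated autocovariance series for the product-chain variance
sigma2_series <- function(px, py, K = 200) {
  e2 <- function(p) if (inherits(p, "two_state_params")) 1 else 2 * p$phi1
  acov <- function(p, k) {
    if (inherits(p, "two_state_params")) (2 * p$a - 1)^k
    else 2 * p$phi1 * (p$b - p$c)^k
  }
  s <- e2(px) * e2(py)
  for (k in seq_len(K)) s <- s + 2 * acov(px, k) * acov(py, k)
  s
}

# tolerance for comparing an observed rate against a published rate, both
# Monte Carlo: three combined binomial standard errors
rate_tol <- function(p_ref, n_ours, n_ref = 10000) {
  3 * sqrt(p_ref * (1 - p_ref) / n_ours + p_ref * (1 - p_ref) / n_ref)
}
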
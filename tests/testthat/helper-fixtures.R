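# Small configurations reused across tests. Panels are deliberately tiny;
# statistical checks state their own Monte-Carlo tolerances.

tiny_config <- function(fst = 0, het_grr = 1, n_null_snps = 500, ...) {
  sim_config(
    n_cases = 25, n_controls = 25, external_sizes = c(25, 25),
    fst = fst, n_null_snps = n_null_snps,
    disease = disease_model(het_grr = het_grr), ...
  )
}

study_config <- function(fst = 0, het_grr = 1, n_null_snps = 10000, ...) {
  sim_config(fst = fst, n_null_snps = n_null_snps,
             disease = disease_model(het_grr = het_grr), ...)
}

# plain double-loop IBS oracle, independent of the BLAS kernel
ibs_oracle <- function(G) {
  n <- nrow(G)
  S <- diag(1, n)
  N <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    N[i, i] <- sum(!is.na(G[i, ]))
    for (j in seq_len(n)) {
      if (i == j) next
      ok <- !is.na(G[i, ]) & !is.na(G[j, ])
      N[i, j] <- sum(ok)
      S[i, j] <- 1 - sum(abs(G[i, ok] - G[j, ok])) / (2 * sum(ok))
    }
  }
  list(ibs = S, pair_counts = N)
}

# negative Bernoulli log-likelihood for the independent-optimizer oracle
neg_loglik_logistic <- function(beta, y, X) {
  eta <- drop(X %*% beta)
  -sum(y * eta - log1p(exp(eta)))
}

# three-sigma binomial tolerance helper
binom_tol3 <- function(p, n) 3 * sqrt(p * (1 - p) / n)
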
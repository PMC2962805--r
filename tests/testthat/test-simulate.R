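test_that("Balding-Nichols divergence has the stated moments", {
  expect_identical(diverge_frequency(0.37, 0), 0.37)
  expect_identical(diverge_frequency(c(0.1, 0.4), 0), c(0.1, 0.4))

  set.seed(101)
  p <- diverge_frequency(rep(0.2, 1e5), 0.01)
  expect_lt(abs(mean(p) - 0.2), 2e-3)
  expect_lt(abs(var(p) - 0.01 * 0.2 * 0.8), 0.05 * 0.0016)

  # fst = 0.5, q = 0.5 gives the arcsine-shaped Beta(0.5, 0.5)
  set.seed(102)
  p2 <- diverge_frequency(rep(0.5, 1e5), 0.5)
  expect_true(all(p2 > 0 & p2 < 1))
  expect_equal(mean(p2), 0.5, tolerance = 5e-3)
})

test_that("empirical F_ST recovers the configured divergence", {
  # variance-standardized estimator over the simulated cohort frequencies
  for (fst in c(0.01, 0.05)) {
    set.seed(300 + round(1000 * fst))
    q <- runif(2e4, 0.05, 0.5)
    p <- diverge_frequency(q, fst)
    fst_hat <- mean((p - q)^2 / (q * (1 - q)))
    expect_lt(abs(fst_hat - fst), 0.10 * fst)
  }
})

test_that("HWE genotype sampling matches expected proportions", {
  expect_identical(sample_hwe_genotypes(0, 50), rep(0L, 50))
  expect_identical(sample_hwe_genotypes(1, 50), rep(2L, 50))

  set.seed(103)
  g <- sample_hwe_genotypes(0.3, 1e5)
  exp_p <- c(0.49, 0.42, 0.09)
  obs <- tabulate(g + 1L, 3) / 1e5
  for (k in 1:3) {
    expect_lt(abs(obs[k] - exp_p[k]), binom_tol3(exp_p[k], 1e5))
  }
})

test_that("case/control sampling follows the ascertained distributions", {
  # null effect: cases are plain HWE
  m0 <- disease_model(het_grr = 1, risk_allele_freq = 0.3)
  set.seed(104)
  cc <- sample_case_control_genotypes(m0, 2e4, 100)
  hwe <- c(0.49, 0.42, 0.09)
  obs <- tabulate(cc$case + 1L, 3) / 2e4
  for (k in 1:3) expect_lt(abs(obs[k] - hwe[k]), binom_tol3(hwe[k], 2e4))

  # risk model: P(G = 1 | case) from the normalized HWE x risk weights
  m1 <- disease_model(prevalence = 0.001, het_grr = 1.5,
                      risk_allele_freq = 0.2)
  set.seed(105)
  cc1 <- sample_case_control_genotypes(m1, 2e4, 2e4)
  p1 <- 2 * 0.2 * 0.8 * 1.5 / 1.21
  expect_lt(abs(mean(cc1$case == 1) - p1), binom_tol3(p1, 2e4))
  # controls near HWE at K = 0.001
  p_ctrl <- genotype_probs(m1)$p_control
  obs_ctrl <- tabulate(cc1$control + 1L, 3) / 2e4
  for (k in 1:3) {
    expect_lt(abs(obs_ctrl[k] - p_ctrl[k]), binom_tol3(p_ctrl[k], 2e4))
  }
})

test_that("a replicate has consistent shape, labels and phenotype", {
  cfg <- tiny_config(fst = c(0.02, 0.1))
  d <- simulate_replicate(cfg, seed = 1)
  n <- 25 * 4
  expect_equal(dim(d$null_genotypes), c(n, 500))
  expect_length(d$test_dosage, n)
  expect_length(d$phenotype, n)
  expect_identical(d$phenotype, as.integer(d$samples$cohort == "case"))
  expect_setequal(unique(d$samples$cohort),
                  c("case", "control", "external-1", "external-2"))
  expect_true(all(d$null_genotypes %in% 0:2))
  expect_true(all(d$test_dosage %in% 0:2))
})

test_that("replicates are bit-reproducible from a seed", {
  cfg <- tiny_config(fst = 0.05, het_grr = 1.5)
  d1 <- simulate_replicate(cfg, seed = 99)
  d2 <- simulate_replicate(cfg, seed = 99)
  expect_identical(d1$null_genotypes, d2$null_genotypes)
  expect_identical(d1$test_dosage, d2$test_dosage)
  d3 <- simulate_replicate(cfg, seed = 100)
  expect_false(identical(d1$null_genotypes, d3$null_genotypes))
})

test_that("the panel-free fast path keeps the test SNP machinery", {
  cfg <- tiny_config()
  d <- simulate_replicate(cfg, seed = 5, panel = FALSE)
  expect_null(d$null_genotypes)
  expect_length(d$test_dosage, 100)
})

test_that("undiverged cohorts share the source frequencies exactly", {
  # at fst = 0 the generating frequency of every cohort is the source draw,
  # so cohort genotype frequencies differ only by sampling noise
  cfg <- tiny_config(fst = 0, n_null_snps = 2000)
  d <- simulate_replicate(cfg, seed = 7)
  freq_by_cohort <- vapply(
    split(seq_len(nrow(d$null_genotypes)), d$samples$cohort),
    function(i) colMeans(d$null_genotypes[i, ]) / 2,
    numeric(2000)
  )
  # per-SNP spread across cohorts consistent with binomial noise at n = 50
  spread <- apply(freq_by_cohort, 1, var)
  p_bar <- rowMeans(freq_by_cohort)
  expect_lt(mean(spread) / mean(p_bar * (1 - p_bar) / 50), 1.15)
})
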
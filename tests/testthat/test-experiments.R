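test_that("the adjusted test reduces to the unadjusted one when no axis is
           selected", {
  cfg <- tiny_config(fst = 0)
  d <- simulate_replicate(cfg, seed = 60)
  mds <- classical_mds(ibs_matrix(d$null_genotypes), t_max = 3)
  # an impossibly strict retention threshold forces an empty selection
  res <- run_three_tests(d, mds = mds, alpha_select = 1e-12)
  tf <- res[res$test == "T_F", ]
  tfm <- res[res$test == "T_Fmds", ]
  expect_identical(tfm$statistic, tf$statistic)
  expect_identical(tfm$beta, tf$beta)
  expect_identical(tfm$p_value, tf$p_value)
})

test_that("replicate summaries are bit-reproducible and order-free", {
  cfg <- tiny_config(fst = 0.05)
  s1 <- estimate_error_rate(cfg, n_reps = 6, base_seed = 61)
  s2 <- estimate_error_rate(cfg, n_reps = 6, base_seed = 61)
  expect_identical(tibble::as_tibble(s1), tibble::as_tibble(s2))

  # a single replicate rerun in isolation reproduces its row
  r_all <- attr(s1, "replicates")
  d4 <- simulate_replicate(cfg, seed = expandctrl:::replicate_seed(61, 4))
  r4 <- run_three_tests(d4)
  expect_equal(r4$p_value, r_all$p_value[r_all$rep == 4], tolerance = 1e-12)
})

test_that("mode guards distinguish null from power configurations", {
  expect_error(estimate_power(tiny_config(het_grr = 1), 2, 1), "het_grr")
  expect_error(estimate_error_rate(tiny_config(het_grr = 1.5), 2, 1),
               "null")
})

test_that("degenerate test SNPs are counted, not dropped", {
  # a rare test allele at small n yields occasional monomorphic replicates
  cfg <- sim_config(n_cases = 8, n_controls = 8, external_sizes = c(4, 4),
                    fst = 0, n_null_snps = 50,
                    disease = disease_model(het_grr = 1,
                                            risk_allele_freq = 0.03))
  s <- estimate_error_rate(cfg, n_reps = 60, base_seed = 62,
                           tests = "T_CC")
  expect_gt(s$n_degenerate, 0)
  expect_equal(s$n_reps, 60)
  r <- attr(s, "replicates")
  expect_true(all(r$p_value[r$status == "degenerate"] == 1))
})

test_that("sensitivity strategies run and differ where they should", {
  cfg <- tiny_config(fst = 0.1)
  s05 <- sensitivity_analysis(cfg, n_reps = 5, base_seed = 63,
                              strategy = "select@0.05")
  s10 <- sensitivity_analysis(cfg, n_reps = 5, base_seed = 63,
                              strategy = "select@0.10")
  all3 <- sensitivity_analysis(cfg, n_reps = 5, base_seed = 63,
                               strategy = "all-axes")
  t10 <- sensitivity_analysis(cfg, n_reps = 5, base_seed = 63,
                              strategy = "t_max=10")
  expect_identical(s05$strategy[1], "select@0.05")
  # all-axes always adjusts for every leading axis
  r <- attr(all3, "replicates")
  expect_true(all(r$n_axes[r$test == "T_Fmds"] == 3))
  expect_true(is.finite(t10$prop_gt3_axes[t10$test == "T_Fmds"]))
  expect_error(sensitivity_analysis(cfg, 2, 1, strategy = "bogus"))
  # identical seeds, identical strategy: bit-reproducible
  s05b <- sensitivity_analysis(cfg, n_reps = 5, base_seed = 63,
                               strategy = "select@0.05")
  expect_identical(tibble::as_tibble(s05), tibble::as_tibble(s05b))
})

test_that("fst_grid stacks one summary per divergence value", {
  cfg <- tiny_config(fst = 0)
  g <- fst_grid(cfg, fst_values = c(0, 0.1), n_reps = 4, base_seed = 64,
                tests = c("T_CC", "T_F"))
  expect_equal(nrow(g), 4)
  expect_setequal(unique(g$fst), c(0, 0.1))
})

test_that("grr_grid traces rejection rate from size to power", {
  cfg <- tiny_config(fst = 0)
  g <- grr_grid(cfg, grr_values = c(1, 2.5), n_reps = 30, base_seed = 65,
                tests = "T_CC")
  expect_equal(nrow(g), 2)
  # a strong effect at the test SNP rejects far more often than the null
  expect_gt(g$rejection_rate[g$het_grr == 2.5],
            g$rejection_rate[g$het_grr == 1])
})
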
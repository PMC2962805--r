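test_that("classical MDS reproduces exactly Euclidean configurations", {
  # unit square in the plane
  xy <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  D <- as.matrix(dist(xy))
  r <- classical_mds(D, t_max = 3, is_distance = TRUE)
  expect_lte(ncol(r$scores), 2) # planar configuration has rank 2
  Dhat <- as.matrix(dist(r$scores))
  expect_equal(Dhat, D, tolerance = 1e-8, ignore_attr = TRUE)

  # random 3-d configuration
  set.seed(30)
  pts <- matrix(rnorm(15 * 3), 15, 3)
  D3 <- as.matrix(dist(pts))
  r3 <- classical_mds(D3, t_max = 5, is_distance = TRUE)
  expect_equal(ncol(r3$scores), 3)
  expect_equal(as.matrix(dist(r3$scores)), D3, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("classical MDS agrees with the cmdscale oracle", {
  set.seed(31)
  pts <- matrix(rnorm(12 * 4), 12, 4)
  D <- as.matrix(dist(pts))
  r <- classical_mds(D, t_max = 4, is_distance = TRUE)
  o <- stats::cmdscale(D, k = 4, eig = TRUE)
  expect_equal(r$eigenvalues, o$eig[1:4], tolerance = 1e-9)
  # scores agree column-by-column up to sign under distinct eigenvalues
  for (t in 1:4) {
    expect_equal(min(max(abs(r$scores[, t] - o$points[, t])),
                     max(abs(r$scores[, t] + o$points[, t]))),
                 0, tolerance = 1e-8)
  }
})

test_that("axes are ordered, centered, and non-positive axes dropped", {
  set.seed(32)
  G <- matrix(sample(0:2, 40 * 300, replace = TRUE), 40, 300)
  r <- classical_mds(ibs_matrix(G), t_max = 6)
  expect_true(all(diff(r$eigenvalues) <= 1e-12))
  expect_true(all(r$eigenvalues > 0))
  expect_lt(max(abs(colMeans(r$scores))), 1e-10)

  # zero-distance degenerate case: no positive eigenvalues survive
  S <- matrix(1, 5, 5)
  r0 <- classical_mds(S, t_max = 3)
  expect_equal(ncol(r0$scores), 0)
})

test_that("input validation catches bad matrices and t_max", {
  S <- matrix(runif(16), 4, 4)
  expect_error(classical_mds(S, t_max = 2), "symmetric")
  D <- as.matrix(dist(matrix(rnorm(8), 4, 2)))
  expect_error(classical_mds(D, t_max = 4, is_distance = TRUE), "t_max")
})

test_that("axis 1 separates two diverged populations", {
  cfg <- sim_config(n_cases = 25, n_controls = 25, external_sizes = 50,
                    fst = 0.1, n_null_snps = 2000,
                    disease = disease_model(het_grr = 1))
  d <- simulate_replicate(cfg, seed = 33)
  r <- classical_mds(ibs_matrix(d$null_genotypes), t_max = 3)
  lab <- as.integer(d$samples$cohort == "external-1")
  expect_gt(abs(cor(r$scores[, 1], lab)), 0.9)
})

test_that("a homogeneous sample has no dominant axis and no phenotype link", {
  cfg <- sim_config(n_cases = 100, n_controls = 100,
                    external_sizes = c(1, 1), fst = 0,
                    n_null_snps = 10000,
                    disease = disease_model(het_grr = 1))
  d <- simulate_replicate(cfg, seed = 34)
  keep <- d$samples$cohort %in% c("case", "control")
  r <- classical_mds(ibs_matrix(d$null_genotypes[keep, ]), t_max = 10)
  expect_lt(r$eigenvalues[1] / sum(r$eigenvalues), 0.25)
  expect_lt(abs(cor(r$scores[, 1], d$phenotype[keep])), 0.3)
})
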
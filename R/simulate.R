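#' Diverge an allele frequency under the Balding-Nichols model
#'
#' Draws the allele frequency of a cohort that has drifted from a source
#' population with frequency `q` by divergence `fst`, from
#' `Beta(a, b)` with `a = q (1 - fst) / fst` and `b = (1 - q)(1 - fst) / fst`.
#' The draw has mean `q` and variance `fst * q * (1 - q)`. `fst = 0` is the
#' degenerate point mass and returns `q` exactly. Draws arbitrarily close to
#' 0 or 1 are returned as-is: near-monomorphic external cohorts are a real
#' feature of strongly diverged populations and downstream code tolerates
#' them.
#'
#' @param q Source allele frequency, each in (0, 1). Vectorized.
#' @param fst Divergence in `[0, 1)` (scalar).
#' @return Diverged frequencies, same length as `q`.
#' @export
diverge_frequency <- function(q, fst) {
  stopifnot(all(q > 0), all(q < 1), length(fst) == 1, fst >= 0, fst < 1)
  if (fst == 0) return(q)
  rbeta(length(q), q * (1 - fst) / fst, (1 - q) * (1 - fst) / fst)
}

#' Sample Hardy-Weinberg genotypes
#'
#' Independent dosage draws with `P(0, 1, 2) = ((1-q)^2, 2q(1-q), q^2)`.
#'
#' @param q Allele frequency in `[0, 1]`.
#' @param n Number of samples.
#' @return Integer dosage vector of length `n`.
#' @export
sample_hwe_genotypes <- function(q, n) {
  stopifnot(length(q) == 1, q >= 0, q <= 1, n >= 0)
  u <- runif(n)
  c1 <- (1 - q)^2
  c2 <- c1 + 2 * q * (1 - q)
  as.integer(u > c1) + as.integer(u > c2)
}

#' Sample test-SNP genotypes for cases and unaffected controls
#'
#' Cases are drawn from `P(G | D) = HWE(G) f_G / K` and controls from
#' `P(G | not D) = HWE(G) (1 - f_G) / (1 - K)`, with penetrances
#' `f_G = f0 * grr^G` from the multiplicative model. Controls are explicitly
#' ascertained as unaffected; at low prevalence this is nearly the
#' population distribution but the ascertainment is kept exact.
#'
#' @param model A [disease_model()].
#' @param n_cases,n_controls Numbers of cases and controls to draw.
#' @return A list with integer dosage vectors `case` and `control`.
#' @export
sample_case_control_genotypes <- function(model, n_cases, n_controls) {
  probs <- genotype_probs(model)
  list(
    case = sample.int(3, n_cases, replace = TRUE, prob = probs$p_case) - 1L,
    control = sample.int(3, n_controls, replace = TRUE,
                         prob = probs$p_control) - 1L
  )
}

#' Simulate one replicate of an expanded-control study
#'
#' Generates a full replicate of the design in a [sim_config()]: a panel of
#' uncorrelated null SNPs with source minor allele frequencies drawn
#' uniformly on `maf_range`, per-SNP external-cohort frequencies drawn
#' independently by [diverge_frequency()], HWE genotypes in every cohort,
#' plus a single test SNP whose source case/control genotypes follow the
#' disease model and whose external-cohort genotypes are HWE at the diverged
#' frequency (external samples are unphenotyped for the disease, so their
#' genotypes ignore the disease model). The test SNP is not part of the null
#' panel, so IBS relationships are never contaminated by the tested marker.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed set before any draw; with a seed the
#'   returned replicate is bit-reproducible.
#' @param panel If `FALSE`, the null structure panel is not generated
#'   (`null_genotypes` is `NULL`) - a fast path for replicate loops that
#'   only run unadjusted tests, which never look at the panel. The RNG
#'   stream differs from a `panel = TRUE` run at the same seed.
#' @return An object of class `study_data`: a list with
#'   `null_genotypes` (n x n_null_snps dosage matrix), `test_dosage`
#'   (length-n integer vector), `phenotype` (1 = case), and `samples`
#'   (a tibble with `id`, `cohort`, `phenotype`).
#' @export
simulate_replicate <- function(config, seed = NULL, panel = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  J <- length(config$external_sizes)
  sizes <- c(config$n_cases, config$n_controls, config$external_sizes)
  n <- sum(sizes)
  m <- config$n_null_snps

  G <- NULL
  if (panel) {
    # null structure panel: columns are cohorts (cases and controls both
    # draw from the source frequency)
    q_null <- runif(m, config$maf_range[1], config$maf_range[2])
    freq <- matrix(0, m, 2 + J)
    freq[, 1] <- q_null
    freq[, 2] <- q_null
    for (j in seq_len(J)) {
      freq[, 2 + j] <- diverge_frequency(q_null, config$fst[j])
    }
    G <- cpp_hwe_genotypes(freq, as.integer(sizes))
  }

  # test SNP
  cc <- sample_case_control_genotypes(config$disease, config$n_cases,
                                      config$n_controls)
  q0 <- config$disease$risk_allele_freq
  ext <- vector("list", J)
  for (j in seq_len(J)) {
    qj <- diverge_frequency(q0, config$fst[j])
    ext[[j]] <- sample_hwe_genotypes(qj, config$external_sizes[j])
  }
  test_dosage <- c(cc$case, cc$control, unlist(ext))

  cohort <- rep(c("case", "control", paste0("external-", seq_len(J))), sizes)
  phenotype <- as.integer(cohort == "case")
  ids <- sprintf("S%04d", seq_len(n))
  if (panel) {
    rownames(G) <- ids
    colnames(G) <- paste0("snp", seq_len(m))
  }

  structure(
    list(null_genotypes = G,
         test_dosage = as.integer(test_dosage),
         phenotype = phenotype,
         samples = tibble::tibble(id = ids, cohort = cohort,
                                  phenotype = phenotype),
         config = config),
    class = "study_data"
  )
}

#' @method print study_data
#' @export
print.study_data <- function(x, ...) {
  cat("Simulated expanded-control replicate\n")
  if (is.null(x$null_genotypes)) {
    cat("  ", nrow(x$samples), "samples, test SNP only (no null panel)\n")
  } else {
    cat("  ", nrow(x$null_genotypes), "samples x", ncol(x$null_genotypes),
        "null SNPs + 1 test SNP\n")
  }
  print(dplyr::count(x$samples, .data$cohort))
  invisible(x)
}
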
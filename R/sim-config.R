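#' Simulation configuration for an expanded-control study design
#'
#' Bundles the generative parameters for one replicate of the study design:
#' a source population contributing cases and within-study controls, plus
#' external reference cohorts diverged from the source by per-cohort
#' `F_ST` under the Balding-Nichols model. Each replicate carries a panel of
#' uncorrelated null SNPs (used only to measure IBS relationships) and a
#' single test SNP under the disease model.
#'
#' @param n_cases,n_controls Source-population sample sizes. Default 100/100.
#' @param external_sizes Integer vector of external cohort sizes; its length
#'   sets the number of external cohorts. Default `c(100, 100, 100)`.
#' @param fst Per-cohort divergence from the source population, each in
#'   `[0, 1)`; recycled to `length(external_sizes)` if scalar.
#' @param n_null_snps Size of the null structure panel. Default 10000.
#' @param maf_range Range from which source-population minor allele
#'   frequencies of null SNPs are drawn uniformly. Default `c(0.05, 0.5)`.
#' @param disease A [disease_model()] for the test SNP.
#' @param t_max_axes Maximum number of MDS axes considered for adjustment.
#' @param alpha_select Per-axis significance threshold in forward selection.
#' @param alpha_test Significance level of the trend tests.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cases = 100, n_controls = 100,
                       external_sizes = c(100, 100, 100),
                       fst = 0, n_null_snps = 10000,
                       maf_range = c(0.05, 0.5),
                       disease = disease_model(),
                       t_max_axes = 3, alpha_select = 0.05,
                       alpha_test = 0.05) {
  if (length(fst) == 1) fst <- rep(fst, length(external_sizes))
  stopifnot(n_cases >= 1, n_controls >= 1, n_null_snps >= 1,
            length(external_sizes) >= 1, all(external_sizes >= 1),
            length(fst) == length(external_sizes),
            all(fst >= 0), all(fst < 1),
            length(maf_range) == 2, maf_range[1] > 0,
            maf_range[1] < maf_range[2], maf_range[2] <= 0.5,
            inherits(disease, "disease_model"),
            t_max_axes >= 0,
            alpha_select > 0, alpha_select < 1,
            alpha_test > 0, alpha_test < 1)
  structure(
    list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         external_sizes = as.integer(external_sizes), fst = as.double(fst),
         n_null_snps = as.integer(n_null_snps),
         maf_range = as.double(maf_range), disease = disease,
         t_max_axes = as.integer(t_max_axes),
         alpha_select = alpha_select, alpha_test = alpha_test),
    class = "sim_config"
  )
}

#' @method print sim_config
#' @export
print.sim_config <- function(x, ...) {
  cat("Expanded-control simulation design\n")
  cat("  source population:  ", x$n_cases, "cases +", x$n_controls,
      "controls\n")
  cat("  external cohorts:   ", paste(x$external_sizes, collapse = ", "),
      "samples at F_ST", paste(format(x$fst), collapse = ", "), "\n")
  cat("  null SNP panel:     ", x$n_null_snps, "SNPs, source MAF in [",
      x$maf_range[1], ",", x$maf_range[2], "]\n")
  cat("  test SNP:            q =", x$disease$risk_allele_freq,
      ", het GRR =", x$disease$het_grr, ", K =", x$disease$prevalence, "\n")
  cat("  axis selection:      up to", x$t_max_axes, "axes at P <",
      x$alpha_select, "; tests at alpha =", x$alpha_test, "\n")
  invisible(x)
}
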
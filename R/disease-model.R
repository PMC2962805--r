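#' Multiplicative disease model at a single SNP
#'
#' Defines the penetrance model used throughout the simulator: genotype
#' penetrances `f0`, `f0 * grr`, `f0 * grr^2` for 0, 1, 2 copies of the risk
#' allele, where `grr` is the heterozygous genotype relative risk. The
#' baseline penetrance `f0` is derived from the population prevalence `K` by
#' averaging the penetrances over Hardy-Weinberg genotype frequencies at the
#' risk-allele frequency `q`:
#' `K = f0 * ((1-q)^2 + 2q(1-q) grr + q^2 grr^2)`.
#'
#' @param prevalence Disease prevalence `K`, in (0, 1). Default 0.001 (0.1%).
#' @param het_grr Heterozygous genotype relative risk, > 0. 1 means no
#'   genetic effect.
#' @param risk_allele_freq Risk-allele frequency `q` at the disease SNP,
#'   in (0, 1). Default 0.2.
#' @return An object of class `disease_model`: a list with the inputs plus
#'   the derived baseline penetrance `f0`.
#' @examples
#' disease_model(prevalence = 0.001, het_grr = 1.5, risk_allele_freq = 0.2)
#' @export
disease_model <- function(prevalence = 0.001, het_grr = 1,
                          risk_allele_freq = 0.2) {
  stopifnot(is.numeric(prevalence), length(prevalence) == 1,
            prevalence > 0, prevalence < 1,
            is.numeric(het_grr), length(het_grr) == 1, het_grr > 0,
            is.numeric(risk_allele_freq), length(risk_allele_freq) == 1,
            risk_allele_freq > 0, risk_allele_freq < 1)
  model <- structure(
    list(prevalence = prevalence, het_grr = het_grr,
         risk_allele_freq = risk_allele_freq),
    class = "disease_model"
  )
  model$f0 <- baseline_penetrance(model)
  model
}

#' Baseline penetrance of a multiplicative disease model
#'
#' Solves `K = f0 * ((1-q)^2 + 2q(1-q) grr + q^2 grr^2)` for `f0`, the
#' penetrance of the non-risk homozygote. Errors when the implied penetrance
#' of the risk homozygote, `f0 * grr^2`, exceeds 1 (an infeasible model).
#'
#' @param model A [disease_model()].
#' @return The baseline penetrance `f0`, a probability.
#' @export
baseline_penetrance <- function(model) {
  stopifnot(inherits(model, "disease_model"))
  q <- model$risk_allele_freq
  g <- model$het_grr
  mean_rr <- (1 - q)^2 + 2 * q * (1 - q) * g + q^2 * g^2
  f0 <- model$prevalence / mean_rr
  if (f0 * g^2 > 1) {
    stop("infeasible disease model: implied risk-homozygote penetrance ",
         "f0 * grr^2 = ", format(f0 * g^2), " exceeds 1", call. = FALSE)
  }
  f0
}

#' Genotype distributions implied by a disease model
#'
#' Tabulates, for dosages 0/1/2 of the risk allele: the Hardy-Weinberg
#' population frequency, the penetrance, and the genotype distributions
#' conditional on being a case (`P(G | D) = HWE(G) f_G / K`) and on being
#' unaffected (`P(G | not D) = HWE(G) (1 - f_G) / (1 - K)`).
#'
#' @param model A [disease_model()].
#' @return A tibble with columns `genotype`, `hwe`, `penetrance`,
#'   `p_case`, `p_control`; each probability column sums to 1.
#' @export
genotype_probs <- function(model) {
  stopifnot(inherits(model, "disease_model"))
  q <- model$risk_allele_freq
  hwe <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  f <- model$f0 * model$het_grr^(0:2)
  K <- sum(hwe * f) # equals model$prevalence by construction
  tibble::tibble(
    genotype = 0:2,
    hwe = hwe,
    penetrance = f,
    p_case = hwe * f / K,
    p_control = hwe * (1 - f) / (1 - K)
  )
}

#' @method print disease_model
#' @export
print.disease_model <- function(x, ...) {
  cat("Multiplicative disease model\n")
  cat("  prevalence K:        ", format(x$prevalence), "\n")
  cat("  het. relative risk:  ", format(x$het_grr),
      " (penetrances f0, f0*g, f0*g^2)\n")
  cat("  risk allele freq q:  ", format(x$risk_allele_freq), "\n")
  cat("  baseline penetrance: ", format(x$f0), "\n")
  invisible(x)
}
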
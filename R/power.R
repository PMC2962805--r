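#' Analytic power of the 1-df trend test
#'
#' Closed-form normal-approximation power for the additive-dosage trend
#' test under the multiplicative disease model. The expected genotype
#' distributions `P(G | case)` and `P(G | unaffected)` give the case and
#' control mean dosages; the test's non-centrality is the squared
#' standardized mean difference,
#' `ncp = (mu_case - mu_control)^2 / (sigma^2 (1/n_cases + 1/n_controls))`,
#' with `sigma^2` the dosage variance under the case/control mixture in
#' sample proportions. Power is the probability that a non-central
#' chi-square with 1 df and that non-centrality exceeds the central
#' `1 - alpha` quantile. With `het_grr = 1` the non-centrality is zero and
#' power equals `alpha` exactly.
#'
#' @param n_cases,n_controls Sample sizes.
#' @param risk_allele_freq Risk-allele frequency `q` in (0, 1).
#' @param het_grr Heterozygous genotype relative risk, > 0.
#' @param prevalence Disease prevalence `K`.
#' @param alpha Significance level. Default 0.05.
#' @return Power, a value in `[alpha, 1)`.
#' @examples
#' analytic_trend_power(500, 2000, risk_allele_freq = 0.2, het_grr = 1.3)
#' @export
analytic_trend_power <- function(n_cases, n_controls,
                                 risk_allele_freq = 0.2, het_grr = 1.5,
                                 prevalence = 0.001, alpha = 0.05) {
  stopifnot(n_cases >= 1, n_controls >= 1, alpha > 0, alpha < 1)
  model <- disease_model(prevalence = prevalence, het_grr = het_grr,
                         risk_allele_freq = risk_allele_freq)
  probs <- genotype_probs(model)
  g <- 0:2
  mu1 <- sum(g * probs$p_case)
  mu0 <- sum(g * probs$p_control)
  w1 <- n_cases / (n_cases + n_controls)
  pmix <- w1 * probs$p_case + (1 - w1) * probs$p_control
  sigma2 <- sum(g^2 * pmix) - sum(g * pmix)^2
  ncp <- (mu1 - mu0)^2 / (sigma2 * (1 / n_cases + 1 / n_controls))
  pchisq(qchisq(1 - alpha, df = 1), df = 1, ncp = ncp, lower.tail = FALSE)
}

#' Power curve over control count and genotype relative risk
#'
#' Evaluates [analytic_trend_power()] over a grid of control-group sizes
#' and heterozygous genotype relative risks for a fixed number of cases -
#' the design question behind expanding a control group with external
#' samples: how much power is bought by each additional block of controls.
#'
#' @param n_cases Number of cases.
#' @param n_controls Vector of control-group sizes.
#' @param het_grr Vector of heterozygous genotype relative risks.
#' @param risk_allele_freq,prevalence,alpha Passed to
#'   [analytic_trend_power()].
#' @return A tibble of class `power_curve` with columns `n_controls`,
#'   `het_grr`, `power`.
#' @export
power_curve <- function(n_cases = 500,
                        n_controls = seq(500, 5000, by = 500),
                        het_grr = seq(1.05, 2, by = 0.05),
                        risk_allele_freq = 0.2, prevalence = 0.001,
                        alpha = 0.05) {
  grid <- tidyr::expand_grid(n_controls = n_controls, het_grr = het_grr)
  pw <- purrr::map2_dbl(
    grid$n_controls, grid$het_grr,
    function(n0, g) analytic_trend_power(n_cases, n0, risk_allele_freq,
                                         g, prevalence, alpha)
  )
  out <- tibble::tibble(n_cases = n_cases, n_controls = grid$n_controls,
                        het_grr = grid$het_grr, power = pw)
  class(out) <- c("power_curve", class(tibble::tibble()))
  out
}

#' Plot a power curve
#'
#' @param object A [power_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot object: power against relative risk, one line per
#'   control-group size.
#' @export
autoplot.power_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$het_grr, .data$power,
                               colour = factor(.data$n_controls),
                               group = .data$n_controls)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "heterozygous genotype relative risk", y = "power",
                  colour = "controls") +
    ggplot2::theme_minimal()
}
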
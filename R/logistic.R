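#' Maximum-likelihood logistic regression fit
#'
#' Fits `logit P(y = 1) = X b` by iteratively reweighted least squares
#' (via [stats::glm.fit()]) to a tight tolerance (`|delta deviance| < 1e-10`
#' relative, at most 100 iterations). The first column of `X` is taken to be
#' the intercept. Quasi-separation is flagged when any non-intercept
#' coefficient exceeds 15 on the standardized-covariate scale
#' (`|b_j| * sd(x_j) > 15`); the standardized scale keeps the flag invariant
#' to rescaling of a covariate column, which matters because MDS axis scores
#' have arbitrary scale. Flagged fits are marked not converged.
#'
#' @param y Binary response vector (0/1) containing both classes.
#' @param X Model matrix including an intercept column first; must have full
#'   column rank.
#' @return An object of class `logistic_fit`: coefficients, `loglik`
#'   (maximized Bernoulli log-likelihood, always <= 0), `converged`,
#'   `separation`, `iter`, `n`, `df` (number of columns of `X`).
#' @export
fit_logistic <- function(y, X) {
  y <- as.numeric(y)
  if (!is.matrix(X)) X <- cbind(intercept = X)
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  if (min(y) == max(y)) {
    stop("response has a single class; logistic model is undefined",
         call. = FALSE)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    cols <- colnames(X)
    if (is.null(cols)) cols <- paste0("V", seq_len(ncol(X)))
    dropped <- cols[qx$pivot[-seq_len(qx$rank)]]
    stop("model matrix is rank deficient; aliased column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(epsilon = 1e-10, maxit = 100))
  )
  beta <- fit$coefficients
  sds <- if (ncol(X) > 1) apply(X[, -1, drop = FALSE], 2, sd) else numeric(0)
  separation <- any(abs(beta[-1]) * sds > 15)
  structure(
    list(coefficients = beta,
         loglik = -fit$deviance / 2,
         converged = fit$converged && !separation,
         separation = separation,
         iter = fit$iter, n = length(y), df = ncol(X)),
    class = "logistic_fit"
  )
}

#' @method print logistic_fit
#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic fit: logLik", format(x$loglik), "on", x$df,
      "parameters (", x$iter, "IRLS iterations,",
      if (x$converged) "converged" else "NOT converged", ")\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.logistic_fit <- function(x, ...) {
  nm <- names(x$coefficients)
  if (is.null(nm)) nm <- paste0("b", seq_along(x$coefficients) - 1L)
  tibble::tibble(term = nm, estimate = unname(x$coefficients))
}

#' @export
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, df = x$df, n = x$n,
                 iter = x$iter, converged = x$converged,
                 separation = x$separation)
}

#' Likelihood-ratio test of nested logistic fits
#'
#' `statistic = 2 (logLik_alt - logLik_null)` floored at zero, compared to
#' the chi-square upper tail with `df` degrees of freedom. A maximized
#' alternative log-likelihood below the null (beyond numerical tolerance)
#' signals an optimizer failure and errors.
#'
#' @param fit_null,fit_alt Nested [fit_logistic()] results.
#' @param df Difference in parameter count, >= 1.
#' @return A list with `statistic` and `p_value`.
#' @export
likelihood_ratio_test <- function(fit_null, fit_alt, df = 1) {
  stopifnot(inherits(fit_null, "logistic_fit"),
            inherits(fit_alt, "logistic_fit"), df >= 1)
  delta <- fit_alt$loglik - fit_null$loglik
  if (delta < -1e-6) {
    stop("alternative log-likelihood below the null (", format(2 * delta),
         "); optimizer failure in the larger model", call. = FALSE)
  }
  stat <- max(0, 2 * delta)
  list(statistic = stat, p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Forward selection of disease-associated MDS axes
#'
#' Tests axes of genetic variation for association with phenotype in order
#' of decreasing eigenvalue. In the default conditional mode, the null model
#' at step `t` contains the intercept plus all previously retained axes, and
#' axis `t` is retained when its 1-df likelihood-ratio P-value is below
#' `alpha_select`; in `marginal` mode every axis is tested against the
#' intercept-only model. A non-converged axis fit is never retained. In a
#' genetically homogeneous sample no axis is expected to survive selection.
#'
#' @param y Binary phenotype over all samples (external samples count as
#'   controls).
#' @param mds An [classical_mds()] result aligned with `y`.
#' @param t_max Number of leading axes eligible for selection; 0 gives an
#'   empty selection.
#' @param alpha_select Retention threshold on the per-axis P-value.
#' @param method `"forward"` (conditional, default) or `"marginal"`.
#' @return An object of class `axis_selection`: a tibble with one row per
#'   examined axis (`axis`, `eigenvalue`, `p_value`, `converged`,
#'   `retained`), with the threshold and method as attributes.
#' @export
select_axes <- function(y, mds, t_max = 3, alpha_select = 0.05,
                        method = c("forward", "marginal")) {
  method <- match.arg(method)
  stopifnot(inherits(mds, "mds_result"), t_max >= 0)
  n_avail <- ncol(mds$scores)
  t_use <- min(t_max, n_avail)
  empty <- tibble::tibble(axis = integer(0), eigenvalue = double(0),
                          p_value = double(0), converged = logical(0),
                          retained = logical(0))
  if (t_use == 0) {
    return(structure(empty, alpha_select = alpha_select, method = method,
                     class = c("axis_selection", class(empty))))
  }
  stopifnot(length(y) == nrow(mds$scores))
  intercept <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  retained <- integer(0)
  rows <- vector("list", t_use)
  fit_null <- fit_logistic(y, intercept)
  for (t in seq_len(t_use)) {
    X_null <- cbind(intercept, mds$scores[, retained, drop = FALSE])
    null_t <- if (method == "forward" && length(retained)) {
      fit_logistic(y, X_null)
    } else {
      fit_null
    }
    alt_t <- fit_logistic(y, cbind(X_null, mds$scores[, t, drop = FALSE]))
    lrt <- likelihood_ratio_test(null_t, alt_t, df = 1)
    keep <- alt_t$converged && lrt$p_value < alpha_select
    if (keep && method == "forward") retained <- c(retained, t)
    if (keep && method == "marginal") retained <- c(retained, t)
    rows[[t]] <- tibble::tibble(axis = t, eigenvalue = mds$eigenvalues[t],
                                p_value = lrt$p_value,
                                converged = alt_t$converged,
                                retained = keep)
  }
  out <- dplyr::bind_rows(rows)
  structure(out, alpha_select = alpha_select, method = method,
            class = c("axis_selection", class(out)))
}

#' Structure-adjusted likelihood-ratio trend test of a SNP
#'
#' Tests the SNP term in `logit P(D) = a + b g + sum_t c_t x_t`, where `g`
#' is the allele dosage (0/1/2 by default) and the `x_t` are optional
#' covariate columns (typically selected MDS axes). The statistic is the
#' 1-df likelihood ratio against the covariate-only null; `exp(b)` estimates
#' the allelic odds ratio. A monomorphic SNP carries no information and is
#' reported as degenerate with `P = 1` rather than an error, so replicate
#' loops never abort.
#'
#' @param y Binary phenotype.
#' @param g Genotype dosage vector in `{0, 1, 2}`.
#' @param covariates Optional numeric matrix of covariate columns (no
#'   intercept), row-aligned with `y`.
#' @param test Label recorded in the output (e.g. `"T_CC"`).
#' @param coding Genetic coding of `g`: `"additive"` (dosage, default),
#'   `"dominant"`, `"recessive"` or `"heterozygote"`.
#' @return A one-row tibble of class `assoc_result`: `test`, `beta`,
#'   `odds_ratio`, `statistic`, `df`, `p_value`, `n`, `axes`, `n_axes`,
#'   `converged`, `status` (`"ok"` or `"degenerate"`).
#' @export
trend_test <- function(y, g, covariates = NULL, test = "trend",
                       coding = c("additive", "dominant", "recessive",
                                  "heterozygote")) {
  coding <- match.arg(coding)
  stopifnot(length(y) == length(g))
  g <- switch(coding,
              additive = as.numeric(g),
              dominant = as.numeric(g > 0),
              recessive = as.numeric(g == 2),
              heterozygote = as.numeric(g == 1))
  axes <- if (is.null(covariates) || ncol(covariates) == 0) {
    character(0)
  } else {
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
    }
    colnames(covariates)
  }
  if (min(g) == max(g)) {
    return(new_assoc_result(test, NA_real_, NA_real_, 0, 1, length(y),
                            axes, converged = TRUE, status = "degenerate"))
  }
  intercept <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  X_null <- if (length(axes)) cbind(intercept, covariates) else intercept
  fit0 <- fit_logistic(y, X_null)
  fit1 <- fit_logistic(y, cbind(X_null, g = g))
  lrt <- likelihood_ratio_test(fit0, fit1, df = 1)
  beta <- unname(fit1$coefficients["g"])
  new_assoc_result(test, beta, exp(beta), lrt$statistic, lrt$p_value,
                   length(y), axes, converged = fit1$converged,
                   status = "ok")
}

new_assoc_result <- function(test, beta, or, stat, p, n, axes, converged,
                             status) {
  k_axes <- length(axes)
  out <- tibble::tibble(
    test = test, beta = beta, odds_ratio = or, statistic = stat, df = 1L,
    p_value = p, n = n, axes = paste(axes, collapse = "+"),
    n_axes = k_axes, converged = converged, status = status
  )
  class(out) <- c("assoc_result", class(out))
  out
}

#' Run the three trend tests on one replicate
#'
#' Computes, for a [simulate_replicate()] dataset (or any `study_data`-shaped
#' object):
#' * `T_CC` - cases against within-study controls only, unadjusted;
#' * `T_F` - cases against the expanded control group (within-study controls
#'   plus all external samples), unadjusted;
#' * `T_Fmds` - the expanded-control contrast adjusted for the MDS axes of
#'   genetic variation retained by [select_axes()] over the full sample.
#'
#' When no axis is selected the adjusted model is identical to the
#' unadjusted one, and `T_Fmds` reproduces `T_F` exactly. The test-SNP
#' dosage is recoded to count the minor allele of the combined sample before
#' testing.
#'
#' @param data A `study_data` object.
#' @param mds A [classical_mds()] result over all samples, or `NULL` to
#'   compute it from `data$null_genotypes` (required only when `"T_Fmds"`
#'   is requested).
#' @param t_max,alpha_select,select_method Forward-selection controls passed
#'   to [select_axes()]; defaults come from `data$config` when present.
#' @param tests Character subset of `c("T_CC", "T_F", "T_Fmds")` to compute.
#' @return A tibble of class `assoc_result` with one row per requested
#'   test, and the `axis_selection` attached as attribute `selection` when
#'   `T_Fmds` was computed.
#' @export
run_three_tests <- function(data, mds = NULL, t_max = NULL,
                            alpha_select = NULL,
                            select_method = c("forward", "marginal"),
                            tests = c("T_CC", "T_F", "T_Fmds")) {
  select_method <- match.arg(select_method)
  stopifnot(inherits(data, "study_data"),
            all(tests %in% c("T_CC", "T_F", "T_Fmds")), length(tests) >= 1)
  cfg <- data$config
  if (is.null(t_max)) t_max <- if (!is.null(cfg)) cfg$t_max_axes else 3L
  if (is.null(alpha_select)) {
    alpha_select <- if (!is.null(cfg)) cfg$alpha_select else 0.05
  }
  y <- data$phenotype
  g <- as.numeric(data$test_dosage)
  # minor-allele coding in the combined sample
  if (mean(g) > 1) g <- 2 - g
  src <- data$samples$cohort %in% c("case", "control")

  out <- list()
  selection <- NULL
  if ("T_CC" %in% tests) {
    out$T_CC <- trend_test(y[src], g[src], test = "T_CC")
  }
  tf <- if (any(c("T_F", "T_Fmds") %in% tests)) {
    trend_test(y, g, test = "T_F")
  }
  if ("T_F" %in% tests) out$T_F <- tf
  if ("T_Fmds" %in% tests) {
    if (is.null(mds)) {
      mds <- classical_mds(ibs_matrix(data$null_genotypes),
                           t_max = max(t_max, 1))
    }
    selection <- select_axes(y, mds, t_max = t_max,
                             alpha_select = alpha_select,
                             method = select_method)
    sel <- selection$axis[selection$retained]
    if (length(sel) == 0) {
      out$T_Fmds <- dplyr::mutate(tf, test = "T_Fmds")
    } else {
      out$T_Fmds <- trend_test(y, g,
                               covariates = mds$scores[, sel, drop = FALSE],
                               test = "T_Fmds")
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("assoc_result", class(tibble::tibble()))
  attr(res, "selection") <- selection
  res
}
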
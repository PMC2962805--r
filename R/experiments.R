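# Replicate engine shared by the error-rate, power and sensitivity drivers.
# Each replicate gets its own derived seed, so any execution order (or a
# rerun of a single replicate) reproduces the same summary.
replicate_results <- function(config, n_reps, base_seed,
                              tests = c("T_CC", "T_F", "T_Fmds"),
                              t_max = NULL, alpha_select = NULL,
                              all_axes = FALSE,
                              select_method = "forward") {
  stopifnot(inherits(config, "sim_config"), n_reps >= 1)
  if (is.null(t_max)) t_max <- config$t_max_axes
  if (is.null(alpha_select)) alpha_select <- config$alpha_select
  need_panel <- "T_Fmds" %in% tests
  rows <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    d <- simulate_replicate(config, seed = replicate_seed(base_seed, i),
                            panel = need_panel)
    if (need_panel && all_axes) {
      mds <- classical_mds(ibs_matrix(d$null_genotypes), t_max = t_max)
      y <- d$phenotype
      g <- as.numeric(d$test_dosage)
      if (mean(g) > 1) g <- 2 - g
      src <- d$samples$cohort %in% c("case", "control")
      res <- dplyr::bind_rows(
        if ("T_CC" %in% tests) trend_test(y[src], g[src], test = "T_CC"),
        if ("T_F" %in% tests) trend_test(y, g, test = "T_F"),
        trend_test(y, g, covariates = mds$scores, test = "T_Fmds")
      )
      n_sel <- ncol(mds$scores)
      max_sel <- n_sel
    } else {
      res <- run_three_tests(d, t_max = t_max, alpha_select = alpha_select,
                             select_method = select_method, tests = tests)
      sel <- attr(res, "selection")
      n_sel <- if (is.null(sel)) NA_integer_ else sum(sel$retained)
      max_sel <- if (is.null(sel) || n_sel == 0) {
        0L
      } else {
        max(sel$axis[sel$retained])
      }
    }
    res$rep <- i
    res$n_axes_selected <- n_sel
    res$max_axis_selected <- max_sel
    rows[[i]] <- res
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "config") <- config
  out
}

summarize_replicates <- function(results, alpha_test, config) {
  safe_mean <- function(x) if (length(x)) mean(x) else NA_real_
  safe_q <- function(x, p) {
    if (length(x)) quantile(x, p, names = FALSE) else NA_real_
  }
  out <- results |>
    dplyr::group_by(.data$test) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      rejection_rate = mean(.data$p_value < alpha_test),
      mean_or = safe_mean(.data$odds_ratio[.data$converged &
                                             .data$status == "ok"]),
      or_q05 = safe_q(.data$odds_ratio[.data$converged &
                                         .data$status == "ok"], 0.05),
      or_q95 = safe_q(.data$odds_ratio[.data$converged &
                                         .data$status == "ok"], 0.95),
      n_degenerate = sum(.data$status == "degenerate"),
      n_nonconverged = sum(!.data$converged),
      prop_gt3_axes = mean(.data$max_axis_selected > 3),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      fst = max(config$fst), alpha = alpha_test,
      .before = 1
    )
  class(out) <- c("experiment_summary", class(tibble::tibble()))
  attr(out, "config") <- config
  attr(out, "replicates") <- results
  out
}

#' Estimate the false-positive error rate of the three trend tests
#'
#' Runs `n_reps` independent replicates of the design under the null
#' (heterozygous genotype relative risk 1): each replicate is simulated,
#' IBS and MDS are computed from the null panel when the adjusted test is
#' requested, and the requested trend tests are performed. The rejection
#' fraction at `config$alpha_test` estimates the false-positive error rate;
#' under a well-calibrated test it should match the nominal level.
#' Degenerate (monomorphic test SNP) replicates count as non-rejections and
#' are tallied, never silently redrawn.
#'
#' @param config A [sim_config()] with `disease$het_grr == 1`.
#' @param n_reps Number of replicates.
#' @param base_seed Integer base seed; replicate `i` uses a seed derived
#'   deterministically from `(base_seed, i)`.
#' @param tests Which of `c("T_CC", "T_F", "T_Fmds")` to run; the null
#'   panel is only simulated when `"T_Fmds"` is included.
#' @return A tibble of class `experiment_summary` with one row per test:
#'   rejection rate, mean and 5-/95-percentile allelic odds-ratio estimates
#'   over converged replicates, degenerate and non-converged counts, and the
#'   proportion of replicates selecting an axis beyond the third. Per-
#'   replicate results are attached as attribute `"replicates"`.
#' @export
estimate_error_rate <- function(config, n_reps, base_seed,
                                tests = c("T_CC", "T_F", "T_Fmds")) {
  if (config$disease$het_grr != 1) {
    stop("error-rate estimation requires het_grr = 1 (null model); use ",
         "estimate_power() under the alternative", call. = FALSE)
  }
  res <- replicate_results(config, n_reps, base_seed, tests = tests)
  summarize_replicates(res, config$alpha_test, config)
}

#' Estimate the power of the three trend tests
#'
#' As [estimate_error_rate()] but under the alternative
#' (`disease$het_grr > 1`); the rejection fraction estimates power, and the
#' mean allelic odds-ratio estimate across replicates can be compared with
#' the generating relative risk.
#'
#' @inheritParams estimate_error_rate
#' @param config A [sim_config()] with `disease$het_grr > 1`.
#' @return A tibble of class `experiment_summary`; see
#'   [estimate_error_rate()].
#' @export
estimate_power <- function(config, n_reps, base_seed,
                           tests = c("T_CC", "T_F", "T_Fmds")) {
  if (config$disease$het_grr <= 1) {
    stop("power estimation requires het_grr > 1; use estimate_error_rate()",
         " under the null", call. = FALSE)
  }
  res <- replicate_results(config, n_reps, base_seed, tests = tests)
  summarize_replicates(res, config$alpha_test, config)
}

#' Error rate or power over a grid of divergence values
#'
#' Maps [estimate_error_rate()] (when `het_grr == 1`) or [estimate_power()]
#' over a grid of `F_ST` values, applying each value to every external
#' cohort, and stacks the summaries - the layout of the published
#' error-rate and power tables.
#'
#' @param config Template [sim_config()]; its `fst` is replaced by each
#'   grid value in turn.
#' @param fst_values Numeric vector of divergence values.
#' @param n_reps,base_seed As in [estimate_error_rate()]; each grid cell
#'   uses an independent seed block derived from `base_seed`.
#' @param tests Tests to run in each cell.
#' @return An `experiment_summary` tibble with one row per (fst, test).
#' @export
fst_grid <- function(config, fst_values, n_reps, base_seed,
                     tests = c("T_CC", "T_F", "T_Fmds")) {
  stopifnot(length(fst_values) >= 1)
  fun <- if (config$disease$het_grr == 1) estimate_error_rate else
    estimate_power
  out <- purrr::imap(fst_values, function(f, idx) {
    cfg <- config
    cfg$fst <- rep(f, length(cfg$external_sizes))
    s <- fun(cfg, n_reps, replicate_seed(base_seed, 100000 + idx),
             tests = tests)
    s$fst <- f
    s
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("experiment_summary", class(tibble::tibble()))
  out
}

#' Power over a grid of genotype relative risks
#'
#' Maps the replicate drivers over a grid of heterozygous genotype relative
#' risks at fixed divergence - the simulated analogue of a power curve,
#' with one summary row per (relative risk, test). Values of 1 estimate the
#' false-positive error rate, so a grid spanning 1 traces the whole curve
#' with one code path.
#'
#' @param config Template [sim_config()]; its disease model's `het_grr` is
#'   replaced by each grid value in turn.
#' @param grr_values Numeric vector of heterozygous genotype relative
#'   risks, each > 0.
#' @param n_reps,base_seed As in [estimate_error_rate()].
#' @param tests Tests to run in each cell.
#' @return An `experiment_summary` tibble with a `het_grr` column.
#' @export
grr_grid <- function(config, grr_values, n_reps, base_seed,
                     tests = c("T_CC", "T_F", "T_Fmds")) {
  stopifnot(length(grr_values) >= 1, all(grr_values > 0))
  out <- purrr::imap(grr_values, function(g, idx) {
    cfg <- config
    cfg$disease <- disease_model(
      prevalence = config$disease$prevalence, het_grr = g,
      risk_allele_freq = config$disease$risk_allele_freq
    )
    res <- replicate_results(cfg, n_reps,
                             replicate_seed(base_seed, 200000 + idx),
                             tests = tests)
    s <- summarize_replicates(res, cfg$alpha_test, cfg)
    s$het_grr <- g
    s
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("experiment_summary", class(tibble::tibble()))
  out
}

#' Sensitivity of the adjusted test to the axis-selection strategy
#'
#' Re-runs the replicate pipeline with an alternative strategy for choosing
#' which axes of genetic variation enter the adjusted test:
#' `"select@0.05"` (the default forward selection), `"select@0.10"` (laxer
#' retention threshold), `"all-axes"` (always adjust for all leading axes,
#' no selection), or `"t_max=10"` (forward selection among the first ten
#' axes, also reporting how often any axis beyond the third is used).
#'
#' @param config A [sim_config()].
#' @param n_reps,base_seed As in [estimate_error_rate()].
#' @param strategy One of `"select@0.05"`, `"select@0.10"`, `"all-axes"`,
#'   `"t_max=10"`.
#' @return An `experiment_summary` tibble with a `strategy` column.
#' @export
sensitivity_analysis <- function(config, n_reps, base_seed,
                                 strategy = c("select@0.05", "select@0.10",
                                              "all-axes", "t_max=10")) {
  strategy <- match.arg(strategy)
  args <- switch(strategy,
    "select@0.05" = list(alpha_select = 0.05, t_max = config$t_max_axes,
                         all_axes = FALSE),
    "select@0.10" = list(alpha_select = 0.10, t_max = config$t_max_axes,
                         all_axes = FALSE),
    "all-axes" = list(alpha_select = config$alpha_select,
                      t_max = config$t_max_axes, all_axes = TRUE),
    "t_max=10" = list(alpha_select = 0.05, t_max = 10L, all_axes = FALSE)
  )
  res <- replicate_results(config, n_reps, base_seed,
                           tests = c("T_F", "T_Fmds"),
                           t_max = args$t_max,
                           alpha_select = args$alpha_select,
                           all_axes = args$all_axes)
  out <- summarize_replicates(res, config$alpha_test, config)
  out$strategy <- strategy
  out
}

#' Plot rejection rates from an experiment summary
#'
#' @param object An `experiment_summary`.
#' @param ... Unused.
#' @return A ggplot object: rejection rate per test, against `F_ST` when
#'   the summary spans a grid.
#' @export
autoplot.experiment_summary <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if (length(unique(df$fst)) > 1) {
    ggplot2::ggplot(df, ggplot2::aes(.data$fst, .data$rejection_rate,
                                     colour = .data$test)) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::geom_hline(yintercept = unique(df$alpha), linetype = 2) +
      ggplot2::labs(x = expression(F[ST]), y = "rejection rate",
                    colour = NULL) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$test, .data$rejection_rate)) +
      ggplot2::geom_col(width = 0.6) +
      ggplot2::geom_hline(yintercept = unique(df$alpha), linetype = 2) +
      ggplot2::labs(x = NULL, y = "rejection rate") +
      ggplot2::theme_minimal()
  }
}
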
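#' Axes of genetic variation by classical multidimensional scaling
#'
#' Applies classical (Torgerson) multidimensional scaling to the distance
#' matrix `D = 1 - IBS`: the squared distances are double-centered,
#' `B = -1/2 J (D o D) J` with `J` the centering projector, and the top
#' eigenpairs of `B` give principal-coordinate scores
#' `x_t = v_t * sqrt(lambda_t)`, ordered by decreasing eigenvalue. Axes with
#' non-positive (or numerically negligible) eigenvalues carry no Euclidean
#' signal and are dropped, so the result may have fewer than `t_max`
#' columns. Score columns are mean-centered by construction.
#'
#' The sqrt-eigenvalue scaling is the usual principal-coordinate convention;
#' any monotone rescaling of a single axis leaves downstream logistic
#' likelihood-ratio tests unchanged, so the choice is cosmetic but fixed.
#' Exact eigenvalue ties are broken by the eigensolver's deterministic
#' output order.
#'
#' @param S An [ibs_matrix()], or a symmetric similarity matrix with unit
#'   diagonal, or (with `is_distance = TRUE`) a symmetric distance matrix.
#' @param t_max Maximum number of axes to return; must be less than the
#'   number of samples.
#' @param is_distance If `TRUE`, `S` is already a distance matrix and is
#'   used as-is rather than as `1 - S`.
#' @return An object of class `mds_result`: a list with `scores`
#'   (n x T matrix, T <= t_max, columns `axis1`, `axis2`, ...),
#'   `eigenvalues` (length T, non-increasing), and `sample_ids`.
#' @export
classical_mds <- function(S, t_max, is_distance = FALSE) {
  if (inherits(S, "ibs_matrix")) {
    ids <- S$sample_ids
    D <- 1 - S$ibs
  } else {
    stopifnot(is.matrix(S), nrow(S) == ncol(S))
    if (max(abs(S - t(S))) > 1e-8) {
      stop("input matrix must be symmetric", call. = FALSE)
    }
    ids <- rownames(S)
    if (is.null(ids)) ids <- sprintf("S%04d", seq_len(nrow(S)))
    D <- if (is_distance) S else 1 - S
  }
  n <- nrow(D)
  stopifnot(t_max >= 1)
  if (t_max >= n) stop("t_max must be less than the number of samples",
                       call. = FALSE)

  D2 <- D * D
  rm_ <- rowMeans(D2)
  B <- -0.5 * (D2 - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(D2))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  lambda <- e$values[seq_len(t_max)]
  tol <- max(abs(e$values[1]), 1) * 1e-12
  keep <- which(lambda > tol)
  lambda <- lambda[keep]
  scores <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(lambda),
                                                    length(keep))
  if (length(keep)) {
    colnames(scores) <- paste0("axis", seq_along(keep))
    rownames(scores) <- ids
  }
  structure(list(scores = scores, eigenvalues = lambda, sample_ids = ids),
            class = "mds_result")
}

#' @method print mds_result
#' @export
print.mds_result <- function(x, ...) {
  cat("Classical MDS axes of genetic variation\n")
  cat("  ", length(x$sample_ids), "samples,", length(x$eigenvalues),
      "positive axes\n")
  if (length(x$eigenvalues)) {
    cat("  eigenvalues:", paste(format(x$eigenvalues, digits = 4),
                                collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy MDS scores into a sample-per-row tibble
#'
#' @param x An `mds_result`.
#' @param ... Unused.
#' @return A tibble with `id` and one column per axis.
#' @export
tidy.mds_result <- function(x, ...) {
  out <- tibble::as_tibble(x$scores)
  dplyr::bind_cols(tibble::tibble(id = x$sample_ids), out)
}

#' Plot samples on two MDS axes
#'
#' @param object An `mds_result`.
#' @param axes Which two axes to display.
#' @param labels Optional per-sample grouping (e.g. cohort) used for colour.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mds_result <- function(object, axes = c(1, 2), labels = NULL, ...) {
  stopifnot(length(axes) == 2, max(axes) <= ncol(object$scores))
  df <- tibble::tibble(
    x = object$scores[, axes[1]],
    y = object$scores[, axes[2]],
    group = if (is.null(labels)) "sample" else as.character(labels)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = paste0("axis ", axes[1]),
                  y = paste0("axis ", axes[2]), colour = NULL) +
    ggplot2::theme_minimal()
}
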
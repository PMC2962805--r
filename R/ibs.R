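#' Pairwise identity-by-state matrix
#'
#' Computes the mean allele-sharing identity by state between every pair of
#' samples: `IBS_ij = 1 - sum_k |G_ik - G_jk| / (2 N_ij)`, where the sum
#' runs over the `N_ij` SNPs with genotype data available for both samples.
#' IBS is 1 for identical genotype vectors, 0 for opposite homozygotes at
#' every SNP, and lies in `[0, 1]` in general. SNPs missing in either member
#' of a pair are excluded from that pair's numerator and from `N_ij`.
#'
#' Complete matrices take a fast BLAS path; matrices with missing genotypes
#' use a per-pair masked computation.
#'
#' @param G Numeric samples x SNPs dosage matrix with entries in
#'   `{0, 1, 2}` or `NA`; at least 2 samples, and every pair of samples must
#'   share at least one non-missing SNP.
#' @return An object of class `ibs_matrix`: a list with `ibs` (n x n,
#'   unit diagonal), `pair_counts` (n x n integer `N_ij`), and `sample_ids`.
#' @examples
#' G <- rbind(a = c(0, 1, 2), b = c(0, 2, 2))
#' ibs_matrix(G)$ibs
#' @export
ibs_matrix <- function(G) {
  stopifnot(is.matrix(G), nrow(G) >= 2, ncol(G) >= 1)
  if (!is.double(G)) storage.mode(G) <- "double"
  ids <- rownames(G)
  if (is.null(ids)) ids <- sprintf("S%04d", seq_len(nrow(G)))
  if (anyNA(G)) {
    res <- cpp_ibs_missing(G)
    S <- res$ibs
    N <- res$pair_counts
    if (any(N[upper.tri(N)] == 0)) {
      bad <- which(N == 0 & upper.tri(N), arr.ind = TRUE)[1, ]
      stop("samples ", ids[bad[1]], " and ", ids[bad[2]],
           " share no non-missing SNPs", call. = FALSE)
    }
  } else {
    S <- cpp_ibs_complete(G)
    N <- matrix(ncol(G), nrow(G), nrow(G))
    storage.mode(N) <- "integer"
  }
  dimnames(S) <- list(ids, ids)
  dimnames(N) <- list(ids, ids)
  structure(list(ibs = S, pair_counts = N, sample_ids = ids),
            class = "ibs_matrix")
}

#' @method print ibs_matrix
#' @export
print.ibs_matrix <- function(x, ...) {
  n <- length(x$sample_ids)
  off <- x$ibs[upper.tri(x$ibs)]
  cat("Pairwise IBS matrix:", n, "samples\n")
  cat("  off-diagonal IBS in [", format(min(off), digits = 4), ",",
      format(max(off), digits = 4), "], median pair count",
      stats::median(x$pair_counts[upper.tri(x$pair_counts)]), "\n")
  invisible(x)
}

#' Greedy LD thinning of a genotype matrix
#'
#' Scans SNPs left to right inside a sliding window and drops the later SNP
#' of any pair whose squared genotype correlation exceeds `r2_max`, as is
#' standard before IBS/MDS on dense genotyping arrays where local linkage
#' disequilibrium would otherwise dominate the leading axes. Column order of
#' retained SNPs is preserved. Intended for real data; the simulator's SNPs
#' are generated uncorrelated.
#'
#' @param G Samples x SNPs dosage matrix.
#' @param r2_max Maximum allowed squared correlation between retained SNPs,
#'   in (0, 1]. Default 0.2.
#' @param window Number of preceding retained SNPs each candidate is
#'   compared against. Default 50.
#' @return The thinned genotype matrix (possibly all columns).
#' @export
ld_thin <- function(G, r2_max = 0.2, window = 50) {
  stopifnot(is.matrix(G), r2_max > 0, r2_max <= 1, window >= 1)
  m <- ncol(G)
  keep <- integer(0)
  for (j in seq_len(m)) {
    recent <- keep[max(1, length(keep) - window + 1):length(keep)]
    if (length(keep) == 0) {
      keep <- j
      next
    }
    r <- suppressWarnings(cor(G[, j], G[, recent, drop = FALSE],
                              use = "pairwise.complete.obs"))
    r[is.na(r)] <- 0
    if (all(r^2 <= r2_max)) keep <- c(keep, j)
  }
  G[, keep, drop = FALSE]
}
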
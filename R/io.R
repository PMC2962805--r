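#' Read a genotype dosage matrix
#'
#' Two formats are supported. Plain TSV: a header row of SNP ids, first
#' column the sample id, entries in `{0, 1, 2, NA}` (samples in rows, SNPs
#' in columns). VCF: each biallelic SNP record contributes one column of
#' ALT-allele counts parsed from the GT field (`./.` and half-calls become
#' `NA`); multi-allelic and non-SNP records are skipped with one counted
#' warning, so no data is lost silently.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return A samples x SNPs numeric matrix with row and column names.
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
      "vcf"
    } else {
      "tsv"
    }
  }
  if (format == "tsv") read_genotypes_tsv(path) else read_genotypes_vcf(path)
}

read_genotypes_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2) {
    stop("empty genotype matrix in ", path, call. = FALSE)
  }
  ids <- as.character(df[[1]])
  G <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(G) <- "double"
  bad <- which(!(is.na(G) | G == 0 | G == 1 | G == 2), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("malformed genotype at data line ", bad[1, 1], ", SNP column ",
         bad[1, 2], " of ", path, ": entries must be 0, 1, 2 or NA",
         call. = FALSE)
  }
  rownames(G) <- ids
  G
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@fix) == 0) stop("empty VCF: ", path, call. = FALSE)
  ref <- vcf@fix[, "REF"]
  alt <- vcf@fix[, "ALT"]
  keep <- !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    !grepl(",", alt, fixed = TRUE)
  n_skip <- sum(!keep)
  if (n_skip > 0) {
    warning(n_skip, " multi-allelic or non-SNP record(s) skipped",
            call. = FALSE)
  }
  if (!any(keep)) stop("no biallelic SNP records in ", path, call. = FALSE)
  vcf <- vcf[keep, ]
  gt <- vcfR::extract.gt(vcf, element = "GT")
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  dos <- (a1 == "1") + (a2 == "1")
  dos[is.na(gt) | a1 == "." | a2 == "."] <- NA
  ids <- vcf@fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(vcf@fix[, "CHROM"], ":",
                                         vcf@fix[, "POS"])[is.na(ids) |
                                                             ids == "."]
  G <- t(dos)
  colnames(G) <- ids
  storage.mode(G) <- "double"
  G
}

#' Write a genotype dosage matrix as plain TSV
#'
#' Inverse of the TSV reader: header of SNP ids, first column `id`,
#' entries `{0, 1, 2, NA}`. A written matrix reads back identically.
#'
#' @param G Samples x SNPs matrix with row and column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path) {
  stopifnot(is.matrix(G))
  if (is.null(rownames(G))) rownames(G) <- sprintf("S%04d", seq_len(nrow(G)))
  if (is.null(colnames(G))) colnames(G) <- paste0("snp", seq_len(ncol(G)))
  df <- data.frame(id = rownames(G), G, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' A manifest is a TSV with header columns `id` and `role` (plus optional
#' covariate columns): `role` is `case`, `control`, or the name of an
#' external cohort. Sample ids must be unique, roles must be non-missing,
#' and at least one case and one control must be present.
#'
#' @param path Path to the manifest TSV.
#' @return A tibble with `id`, `role` and any extra columns.
#' @export
read_manifest <- function(path) {
  df <- tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
  if (!all(c("id", "role") %in% names(df))) {
    stop("manifest must have 'id' and 'role' columns", call. = FALSE)
  }
  df$id <- as.character(df$id)
  dup <- df$id[duplicated(df$id)]
  if (length(dup)) {
    stop("duplicate sample id in manifest: ", dup[1], call. = FALSE)
  }
  if (any(is.na(df$role) | df$role == "")) {
    stop("missing role for sample ",
         df$id[which(is.na(df$role) | df$role == "")[1]], call. = FALSE)
  }
  if (!any(df$role == "case") || !any(df$role == "control")) {
    stop("manifest needs at least one case and one control", call. = FALSE)
  }
  df
}

#' Write an experiment summary as TSV
#'
#' Emits a display table shaped like the published error-rate/power tables
#' (rejection rates as 1-decimal percentages, odds-ratio mean and 5-95%
#' interval), plus a full-precision sidecar (`<path>.full.tsv`) carrying
#' every column unrounded for downstream use.
#'
#' @param summary An `experiment_summary` tibble.
#' @param path Output path for the display table.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  stopifnot(inherits(summary, "experiment_summary") ||
              is.data.frame(summary))
  disp <- tibble::as_tibble(summary) |>
    dplyr::mutate(
      rejection_rate = sprintf("%.1f%%", 100 * .data$rejection_rate),
      mean_or = sprintf("%.2f", .data$mean_or),
      or_5_95 = sprintf("%.2f-%.2f", .data$or_q05, .data$or_q95)
    ) |>
    dplyr::select(dplyr::any_of(c("fst", "strategy", "test", "n_reps",
                                  "rejection_rate", "mean_or", "or_5_95")))
  write.table(disp, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(tibble::as_tibble(summary), paste0(path, ".full.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a miniature deterministic test dataset
#'
#' Generates a small on-disk dataset (genotype TSV + manifest TSV) used by
#' the test suite and as CLI demo input: `"two-pop"` is 10 cases + 10
#' controls from one population plus 10 external samples strongly diverged
#' (F_ST 0.1) at 200 SNPs, so the leading MDS axis separates the external
#' cohort; `"homogeneous"` is the same design with no divergence. A fixed
#' seed gives identical bytes.
#'
#' @param kind `"two-pop"` or `"homogeneous"`.
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @return Named character vector with paths `genotypes` and `manifest`.
#' @export
make_fixture <- function(kind = c("two-pop", "homogeneous"), seed = 1,
                         dir = tempdir()) {
  kind <- match.arg(kind)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- sim_config(
    n_cases = 10, n_controls = 10, external_sizes = 10,
    fst = if (kind == "two-pop") 0.1 else 0,
    n_null_snps = 200,
    disease = disease_model(het_grr = 1)
  )
  d <- simulate_replicate(cfg, seed = seed)
  gpath <- file.path(dir, paste0("fixture-", kind, "-genotypes.tsv"))
  mpath <- file.path(dir, paste0("fixture-", kind, "-manifest.tsv"))
  write_genotypes(d$null_genotypes, gpath)
  manifest <- d$samples |>
    dplyr::transmute(id = .data$id, role = .data$cohort)
  write.table(manifest, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  c(genotypes = gpath, manifest = mpath)
}
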
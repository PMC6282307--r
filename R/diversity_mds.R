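# Post-VCF genetic-diversity stage: variant filtering by missingness and
# minor allele frequency, identity-by-state distances, classical
# multidimensional scaling, and k-medoids group assignment.

#' Construct a genotype matrix
#'
#' @param calls Integer matrix, samples x variants, alternate-allele
#'   dosages in `{0, 1, 2}` with `NA` for missing calls.
#' @param chrom,pos Optional per-variant chromosome and position.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, chrom = NULL, pos = NULL) {
  calls <- as.matrix(calls)
  stopifnot(all(calls %in% c(0L, 1L, 2L, NA)))
  if (nrow(calls) && is.null(rownames(calls)))
    rownames(calls) <- paste0("S", seq_len(nrow(calls)))
  if (ncol(calls) && is.null(colnames(calls)))
    colnames(calls) <- paste0("V", seq_len(ncol(calls)))
  structure(list(calls = calls, chrom = chrom, pos = pos),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$calls), " samples x ", ncol(x$calls),
      " variants; ", sprintf("%.1f%%", 100 * mean(is.na(x$calls))),
      " missing\n", sep = "")
  invisible(x)
}

#' Read biallelic genotypes from a VCF file
#'
#' Extracts GT fields as alternate-allele dosages.  Multiallelic records
#' are skipped (their count is reported with a message); `./.` becomes
#' missing.
#'
#' @param path Path to a VCF file (uncompressed or gzipped).
#' @return A [genotype_matrix()] (samples in rows).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (ncol(v@gt) < 2L ||
      !all(vapply(strsplit(v@gt[, "FORMAT"], ":"),
                  function(f) "GT" %in% f, logical(1))))
    stop("VCF has no GT format field", call. = FALSE)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    message("skipping ", sum(multi), " multiallelic record(s)")
  gt <- vcfR::extract.gt(v, element = "GT")[!multi, , drop = FALSE]
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt),
                dimnames = dimnames(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  dos[clean %in% c("0/0", "0")] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean %in% c("1/1", "1")] <- 2L
  keep_fix <- fix[!multi, , drop = FALSE]
  genotype_matrix(t(dos), chrom = keep_fix[, "CHROM"],
                  pos = as.integer(keep_fix[, "POS"]))
}

per_variant_missing <- function(G) colMeans(is.na(G$calls))

per_variant_maf <- function(G) {
  alt <- colMeans(G$calls, na.rm = TRUE) / 2   # alt-allele frequency
  pmin(alt, 1 - alt)
}

#' Filter variants by missingness and minor allele frequency
#'
#' Keeps variants whose missing-call fraction is at most `max_missing` and
#' whose minor allele frequency (computed on non-missing calls) is at
#' least `min_maf`; variant order is preserved.  The removal counts are
#' attached as the `"filter_report"` attribute.
#'
#' @param G A [genotype_matrix()].
#' @param max_missing Maximum tolerated missing fraction (default 0.10).
#' @param min_maf Minimum minor allele frequency (default 0.01).
#' @return A filtered `genotype_matrix`.
#' @export
filter_variants <- function(G, max_missing = 0.10, min_maf = 0.01) {
  stopifnot(inherits(G, "genotype_matrix"))
  miss <- per_variant_missing(G)
  maf <- per_variant_maf(G)
  maf[is.nan(maf)] <- 0                    # all-missing variant
  keep <- miss <= max_missing & maf >= min_maf
  if (!any(keep)) warning("no variant passes the filters", call. = FALSE)
  out <- genotype_matrix(G$calls[, keep, drop = FALSE],
                         chrom = G$chrom[keep], pos = G$pos[keep])
  attr(out, "filter_report") <- tibble::tibble(
    n_input = length(keep),
    n_removed_missing = sum(miss > max_missing),
    n_removed_maf = sum(maf < min_maf),
    n_retained = sum(keep))
  out
}

#' Identity-by-state distance matrix
#'
#' `D(i, j) = 1 - mean allele-sharing`, where the allele-sharing of a pair
#' at one variant is `1 - |dosage_i - dosage_j| / 2` and the mean runs over
#' variants non-missing in both samples (pairwise-complete; no
#' imputation).  A pair with no shared non-missing variant is an error.
#'
#' @param G A [genotype_matrix()] with >= 2 samples.
#' @return A symmetric matrix of distances in `[0, 1]` with zero diagonal.
#' @export
ibs_distance <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  X <- G$calls
  n <- nrow(X)
  if (n < 2L) stop("need >= 2 samples", call. = FALSE)
  D <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(X[i, ]) & !is.na(X[j, ])
      if (!any(ok))
        stop("samples ", rownames(X)[i], " and ", rownames(X)[j],
             " share no non-missing variant", call. = FALSE)
      d <- mean(abs(X[i, ok] - X[j, ok]) / 2)
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Classical (metric) multidimensional scaling
#'
#' Double-centers the squared distance matrix, eigendecomposes, and scales
#' the top-`k` eigenvectors by the square roots of their (positive)
#' eigenvalues, via [stats::cmdscale()].
#'
#' @param D A symmetric distance matrix (e.g. from [ibs_distance()]).
#' @param k Number of axes to return (`k < nrow(D)`).
#' @return An `mds_result`: list with `coordinates` (tibble: sample, C1,
#'   C2, ...) and `eigenvalues`.
#' @export
classical_mds <- function(D, k = 2) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (k >= n) stop("k must be smaller than the number of samples",
                   call. = FALSE)
  fit <- stats::cmdscale(D, k = k, eig = TRUE)
  coords <- fit$points
  colnames(coords) <- paste0("C", seq_len(ncol(coords)))
  samples <- rownames(D)
  if (is.null(samples)) samples <- paste0("S", seq_len(n))
  structure(list(
    coordinates = dplyr::bind_cols(tibble::tibble(sample = samples),
                                   tibble::as_tibble(coords)),
    eigenvalues = fit$eig),
    class = "mds_result")
}

#' @export
print.mds_result <- function(x, ...) {
  pos <- x$eigenvalues[x$eigenvalues > 0]
  cat("<mds_result> ", nrow(x$coordinates), " samples, ",
      ncol(x$coordinates) - 1L, " axes; first-axis variance fraction ",
      sprintf("%.2f", pos[1] / sum(pos)), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.mds_result <- function(x, ...) x$coordinates

#' @export
glance.mds_result <- function(x, ...) {
  pos <- x$eigenvalues[x$eigenvalues > 0]
  tibble::tibble(n_samples = nrow(x$coordinates),
                 n_axes = ncol(x$coordinates) - 1L,
                 var_frac_axis1 = pos[1] / sum(pos))
}

#' Plot MDS coordinates
#'
#' @param x An `mds_result`.
#' @param groups Optional group labels (tibble from [assign_groups()] or a
#'   vector aligned with the samples).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mds_result <- function(x, groups = NULL, ...) {
  df <- x$coordinates
  if (!is.null(groups)) {
    df$group <- if (is.data.frame(groups))
      factor(groups$group[match(df$sample, groups$sample)]) else
        factor(groups)
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$C1, y = .data$C2)) +
    ggplot2::labs(x = "C1", y = "C2") + ggplot2::theme_minimal()
  if (is.null(df$group)) p + ggplot2::geom_point() else
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
}

#' Assign samples to groups by k-medoids on MDS coordinates
#'
#' Partitions the samples into `k_groups` by k-medoids (PAM) on the
#' coordinate matrix.  PAM's build/swap search is deterministic; the seed
#' argument is accepted for interface uniformity and recorded.
#'
#' @param coords An `mds_result` or a tibble with a `sample` column and
#'   coordinate columns.
#' @param k_groups Number of groups (`1 <= k_groups <= n`).
#' @param seed Optional integer seed.
#' @return A tibble with columns `sample`, `group`.
#' @export
assign_groups <- function(coords, k_groups, seed = NULL) {
  if (inherits(coords, "mds_result")) coords <- coords$coordinates
  stopifnot(is.data.frame(coords), "sample" %in% names(coords))
  X <- as.matrix(coords[, setdiff(names(coords), "sample"), drop = FALSE])
  n <- nrow(X)
  if (k_groups < 1 || k_groups > n)
    stop("k_groups must be between 1 and the number of samples",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  grp <- if (k_groups == 1L) rep(1L, n) else if (k_groups == n) seq_len(n)
    else cluster::pam(X, k = k_groups, cluster.only = TRUE)
  tibble::tibble(sample = coords$sample, group = as.integer(grp))
}
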
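#' Convert raw counts to TPM
#'
#' tpm[g,s] = (count[g,s] / length_kb[g]) / sum_g'(count[g',s] /
#' length_kb[g']) * 1e6, so every column sums to one million.
#'
#' @param counts Gene x sample matrix of raw counts.
#' @param gene_lengths Named numeric vector of gene lengths in bp (> 0),
#'   covering all rows of `counts`.
#' @return TPM matrix with a `unit` attribute of `"TPM"`.
#' @export
counts_to_tpm <- function(counts, gene_lengths) {
  stopifnot(is.matrix(counts))
  lens <- gene_lengths[rownames(counts)]
  if (anyNA(lens)) stop("gene_lengths missing for some genes")
  if (any(lens <= 0)) stop("gene lengths must be > 0")
  rpk <- counts / (lens / 1000)
  tot <- colSums(rpk)
  if (any(tot == 0)) {
    stop(sprintf("sample '%s' has zero total counts",
                 colnames(counts)[which(tot == 0)[1]]))
  }
  tpm <- sweep(rpk, 2, tot, "/") * 1e6
  attr(tpm, "unit") <- "TPM"
  tpm
}

#' Unit flag of an expression matrix
#'
#' @param expr Expression matrix.
#' @return `"log2"` or `"TPM"` (the default when no flag is set).
#' @export
expr_unit <- function(expr) {
  u <- attr(expr, "unit")
  if (is.null(u)) "TPM" else u
}

#' Filter and log-transform expression features
#'
#' Drops features with a missing fraction above `missing_max`, transforms
#' TPM to log2(TPM + 1) (skipped when the input already carries a log2 unit
#' flag, which makes the filter idempotent on its own output), then drops
#' features whose population SD across non-missing tumor values is below
#' `sd_min`.
#'
#' @param expr Gene x sample matrix, TPM scale unless flagged log2.
#' @param sd_min Minimum population SD on the log2 scale (default 1.0).
#' @param missing_max Maximum tolerated missing fraction (default 0.75,
#'   strict >).
#' @return Filtered log2-scale matrix (unit attribute `"log2"`).
#' @export
filter_expression_features <- function(expr, sd_min = 1, missing_max = 0.75) {
  stopifnot(is.matrix(expr))
  unit <- expr_unit(expr)  # subsetting would drop the attribute
  miss <- rowMeans(is.na(expr))
  expr <- expr[miss <= missing_max, , drop = FALSE]
  if (unit != "log2") {
    expr <- log2(expr + 1)
  }
  pop_sd <- apply(expr, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(0)
    sqrt(mean((x - mean(x))^2))
  })
  out <- expr[pop_sd >= sd_min, , drop = FALSE]
  if (nrow(out) == 0) warning("no features survive the SD filter")
  attr(out, "unit") <- "log2"
  out
}

#' K-nearest-neighbor imputation over rows of a matrix
#'
#' Distances between rows are root-mean-square differences over the samples
#' observed in both profiles (a per-coordinate normalization of Euclidean
#' distance, so rows with different overlap sizes are comparable). Each
#' missing entry is replaced by the mean of the k nearest rows that are
#' observed at that column; observed entries are never altered.
#'
#' @param mat Numeric matrix with missing entries.
#' @param k Number of neighbors (default 5).
#' @return Completed matrix.
#' @export
knn_impute_rows <- function(mat, k = 5) {
  need <- which(rowSums(is.na(mat)) > 0)
  if (length(need) == 0) return(mat)
  out <- mat
  for (i in need) {
    d <- vapply(seq_len(nrow(mat)), function(j) {
      if (j == i) return(Inf)
      shared <- !is.na(mat[i, ]) & !is.na(mat[j, ])
      if (!any(shared)) return(Inf)
      sqrt(mean((mat[i, shared] - mat[j, shared])^2))
    }, 0)
    for (s in which(is.na(mat[i, ]))) {
      donors <- which(!is.na(mat[, s]) & is.finite(d))
      if (length(donors) == 0) {
        stop(sprintf("row '%s' has no neighbor observed at column '%s'",
                     rownames(mat)[i], colnames(mat)[s]))
      }
      donors <- donors[order(d[donors])][seq_len(min(k, length(donors)))]
      out[i, s] <- mean(mat[donors, s])
    }
  }
  out
}

#' Select clustering-ready methylation features
#'
#' Applies the array-level feature rules: drop probes with a missing
#' fraction above `missing_max` (strict >), SNP-associated probes and
#' sex-chromosome probes; impute remaining missing beta-values by
#' probe-space KNN; rank probes by raw median absolute deviation
#' (median |x - median(x)|, no consistency constant) and keep the `k_top`
#' largest. Ties and ranking are resolved deterministically by probe order.
#'
#' @param betas Probe x sample beta-value matrix.
#' @param manifest Probe manifest data.frame (`probe_id`, `chromosome`,
#'   `tss_distance`, `gene`, `snp_associated`) covering all probes.
#' @param k_top Number of top-MAD probes to keep (default 1000).
#' @param knn_k Neighbors for imputation (default 5).
#' @param missing_max Maximum tolerated missing fraction (default 0.2).
#' @return Filtered, complete beta matrix of at most `k_top` probes.
#' @export
prepare_methylation_features <- function(betas, manifest, k_top = 1000,
                                         knn_k = 5, missing_max = 0.2) {
  stopifnot(is.matrix(betas))
  m <- manifest[match(rownames(betas), manifest$probe_id), ]
  if (anyNA(m$probe_id)) stop("manifest does not cover all probes")
  keep <- rowMeans(is.na(betas)) <= missing_max &
    !m$snp_associated & !(m$chromosome %in% c("X", "Y"))
  betas <- betas[keep, , drop = FALSE]
  betas <- knn_impute_rows(betas, k = knn_k)
  mads <- apply(betas, 1, function(x) stats::median(abs(x - stats::median(x))))
  if (k_top > nrow(betas)) {
    warning(sprintf("k_top (%d) exceeds surviving probes (%d); keeping all",
                    k_top, nrow(betas)))
    k_top <- nrow(betas)
  }
  ord <- order(-mads, seq_along(mads))
  betas[sort(ord[seq_len(k_top)]), , drop = FALSE]
}

#' Binarize discrete GISTIC lesion calls
#'
#' Converts discrete copy-number calls (0 = no alteration, >= 1 = altered at
#' increasing amplitude thresholds) into a binary altered/not matrix; lesion
#' metadata passes through untouched.
#'
#' @param lesions List with `values` (lesion x sample integer calls) and
#'   `meta` as returned by [read_gistic_lesions()].
#' @return List with binary `values` and the original `meta`.
#' @export
binarize_lesions <- function(lesions) {
  v <- lesions$values
  if (any(v < 0, na.rm = TRUE)) {
    stop("negative lesion calls: expected discrete 0/1/2 dialect")
  }
  b <- (v >= 1) * 1
  list(values = b, meta = lesions$meta)
}
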
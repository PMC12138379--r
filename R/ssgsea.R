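#' Single-sample gene-set enrichment (ssGSEA) scores
#'
#' For each sample, genes are ranked by expression (descending, average
#' ranks on ties: the top gene carries rank N). Walking down the ranked
#' list, the score of a set is the sum over all positions of the difference
#' between the weighted in-set cumulative distribution (weights = rank^alpha
#' of in-set genes, normalized to 1) and the unweighted out-of-set
#' cumulative distribution -- the standard ssGSEA running-sum integral.
#' Because the statistic is rank-based, any strictly increasing transform of
#' a sample's expression leaves its scores unchanged. Genes absent from the
#' expression matrix are dropped from each set; sets left empty are skipped
#' with a warning.
#'
#' @param expr Gene x sample expression matrix (any monotone scale;
#'   log2(TPM+1) conventionally).
#' @param sets List of gene sets as returned by [read_gmt()].
#' @param alpha Rank-weighting exponent (default 0.25, the ssGSEA
#'   convention).
#' @return Set x sample score matrix with attribute `normalized = FALSE`.
#' @export
ssgsea_scores <- function(expr, sets, alpha = 0.25) {
  stopifnot(is.matrix(expr), nrow(expr) >= 2, length(sets) >= 1)
  genes <- rownames(expr)
  kept <- lapply(sets, function(s) intersect(s$genes, genes))
  empty <- vapply(kept, length, 0L) < 1
  if (any(empty)) {
    warning(sprintf("skipping %d set(s) with no genes in the matrix: %s",
                    sum(empty),
                    paste(names(sets)[empty], collapse = ", ")))
    kept <- kept[!empty]
  }
  if (length(kept) == 0) stop("no scorable gene sets")
  n <- length(genes)
  scores <- matrix(NA_real_, length(kept), ncol(expr),
                   dimnames = list(names(kept), colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    r <- rank(expr[, j], ties.method = "average")  # top gene has rank n
    ord <- order(r, decreasing = TRUE)
    r_ord <- r[ord]
    genes_ord <- genes[ord]
    for (k in seq_along(kept)) {
      inset <- genes_ord %in% kept[[k]]
      w <- r_ord^alpha * inset
      cdf_in <- cumsum(w) / sum(w)
      n_out <- n - sum(inset)
      cdf_out <- if (n_out > 0) cumsum(!inset) / n_out else rep(0, n)
      scores[k, j] <- sum(cdf_in - cdf_out)
    }
  }
  attr(scores, "normalized") <- FALSE
  scores
}

#' Normalize ssGSEA scores by the global score range
#'
#' Divides every score by (max - min) over the whole matrix, the
#' conventional ssGSEA normalization; within-sample ordering of sets is
#' preserved.
#'
#' @param scores A score matrix from [ssgsea_scores()].
#' @return Normalized score matrix with attribute `normalized = TRUE`.
#' @export
normalize_scores <- function(scores) {
  rng <- range(scores[is.finite(scores)])
  if (diff(rng) == 0) stop("degenerate score range: max equals min")
  out <- scores / diff(rng)
  attr(out, "normalized") <- TRUE
  out
}
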
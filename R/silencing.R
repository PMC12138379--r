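#' Select candidate probes for epigenetic-silencing testing
#'
#' Candidate CpG probes are (a) non-SNP and autosomal, (b) within the
#' promoter window (|TSS distance| <= `promoter_bp`), (c) unmethylated in
#' normal tissue (mean normal beta <= `normal_max`; probes exceeding it are
#' constitutively methylated and removed), and (d) methylated (beta >=
#' `meth_thresh`) in at least `min_meth_frac` of all tumor samples.
#' Alongside the probe list the function returns the methylated /
#' unmethylated call matrix for the kept probes.
#'
#' @param manifest Probe manifest covering all probes.
#' @param normal_betas,tumor_betas Probe x sample beta matrices.
#' @param promoter_bp Promoter half-width in bp (default 1500).
#' @param normal_max Maximum mean normal beta (default 0.2).
#' @param meth_thresh Beta threshold defining "methylated" (default 0.3,
#'   inclusive: beta >= 0.3 is methylated).
#' @param min_meth_frac Minimum fraction of tumors methylated (default 0.05).
#' @return List with `probes` (character) and `calls` (logical probe x tumor
#'   matrix, TRUE = methylated).
#' @export
select_candidate_probes <- function(manifest, normal_betas, tumor_betas,
                                    promoter_bp = 1500, normal_max = 0.2,
                                    meth_thresh = 0.3, min_meth_frac = 0.05) {
  if (is.null(normal_betas) || ncol(normal_betas) == 0) {
    stop("no normal samples: the normal-reference filter cannot run")
  }
  m <- manifest[match(rownames(tumor_betas), manifest$probe_id), ]
  if (anyNA(m$probe_id)) stop("manifest does not cover all tumor probes")
  ok_annot <- !m$snp_associated & !(m$chromosome %in% c("X", "Y")) &
    abs(m$tss_distance) <= promoter_bp
  norm_mean <- rowMeans(normal_betas[rownames(tumor_betas), , drop = FALSE],
                        na.rm = TRUE)
  ok_normal <- norm_mean <= normal_max
  meth_frac <- rowMeans(tumor_betas >= meth_thresh, na.rm = TRUE)
  ok_meth <- meth_frac >= min_meth_frac
  keep <- ok_annot & ok_normal & ok_meth
  if (!any(keep)) warning("no candidate probes survive the filters")
  probes <- rownames(tumor_betas)[keep]
  calls <- tumor_betas[probes, , drop = FALSE] >= meth_thresh
  list(probes = probes, calls = calls)
}

#' Test candidate probes for expression suppression in methylated tumors
#'
#' For each probe/gene pair, tumors are split into methylated and
#' unmethylated groups by the call matrix; the probe is selected when the
#' mean (log2) expression of the gene in the methylated group is at least
#' `z` unmethylated-group standard deviations below the unmethylated-group
#' mean (inclusive: equality counts as selected). The SD is the sample SD
#' (n - 1); probes whose unmethylated or methylated group has too few
#' samples, or whose gene is absent from the expression matrix, are
#' reported as untestable (`selected = NA`) rather than dropped silently.
#'
#' @param expr Gene x tumor expression matrix on the log2 scale.
#' @param calls Logical probe x tumor methylation call matrix.
#' @param manifest Probe manifest (for the probe -> gene map).
#' @param z Suppression threshold in SD units (default 1.64).
#' @return Data frame with one row per probe: `probe_id`, `gene`,
#'   `mean_meth_expr`, `mean_unmeth_expr`, `sd_unmeth_expr`, `selected`.
#' @export
test_probe_silencing <- function(expr, calls, manifest, z = 1.64) {
  if (nrow(calls) == 0) {
    return(data.frame(probe_id = character(), gene = character(),
                      mean_meth_expr = numeric(),
                      mean_unmeth_expr = numeric(),
                      sd_unmeth_expr = numeric(), selected = logical(),
                      stringsAsFactors = FALSE))
  }
  m <- manifest[match(rownames(calls), manifest$probe_id), ]
  res <- data.frame(
    probe_id = rownames(calls), gene = m$gene,
    mean_meth_expr = NA_real_, mean_unmeth_expr = NA_real_,
    sd_unmeth_expr = NA_real_, selected = NA,
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(calls))) {
    g <- res$gene[i]
    if (!(g %in% rownames(expr))) next
    meth <- calls[i, ]
    x <- expr[g, colnames(calls)]
    e_meth <- x[meth]; e_unmeth <- x[!meth]
    if (length(e_unmeth) < 2 || length(e_meth) < 1) next
    mm <- mean(e_meth); mu <- mean(e_unmeth); s <- stats::sd(e_unmeth)
    res$mean_meth_expr[i] <- mm
    res$mean_unmeth_expr[i] <- mu
    res$sd_unmeth_expr[i] <- s
    res$selected[i] <- (mm <= mu - z * s)
  }
  res
}

#' Call epigenetically silenced genes per sample
#'
#' A tumor is silenced at a selected probe when it is methylated there and
#' the gene's expression in that tumor is strictly below the probe's
#' unmethylated-group mean. A gene is silenced in a sample when more than
#' half of its selected probes call that sample silenced (a single-probe
#' gene inherits the probe call).
#'
#' @param expr Gene x tumor log2 expression matrix.
#' @param calls Logical probe x tumor methylation call matrix.
#' @param probe_results Output of [test_probe_silencing()].
#' @return List with `probe_calls` (logical selected-probe x tumor),
#'   `gene_calls` (logical gene x tumor) and `burden` (per-sample count of
#'   silenced genes).
#' @export
call_silenced <- function(expr, calls, probe_results) {
  sel <- probe_results[!is.na(probe_results$selected) &
                         probe_results$selected, , drop = FALSE]
  samples <- colnames(calls)
  if (nrow(sel) == 0) {
    gene_calls <- matrix(FALSE, 0, length(samples),
                         dimnames = list(character(), samples))
    return(list(probe_calls = gene_calls, gene_calls = gene_calls,
                burden = stats::setNames(rep(0L, length(samples)), samples)))
  }
  probe_calls <- matrix(FALSE, nrow(sel), length(samples),
                        dimnames = list(sel$probe_id, samples))
  for (i in seq_len(nrow(sel))) {
    probe_calls[i, ] <- calls[sel$probe_id[i], ] &
      (expr[sel$gene[i], samples] < sel$mean_unmeth_expr[i])
  }
  genes <- sort(unique(sel$gene))
  gene_calls <- matrix(FALSE, length(genes), length(samples),
                       dimnames = list(genes, samples))
  for (g in genes) {
    idx <- which(sel$gene == g)
    n_sil <- colSums(probe_calls[idx, , drop = FALSE])
    gene_calls[g, ] <- n_sil > length(idx) / 2
  }
  list(probe_calls = probe_calls, gene_calls = gene_calls,
       burden = silencing_burden(gene_calls))
}

#' Per-sample methylation-silencing burden
#'
#' @param gene_calls Logical gene x sample silencing matrix.
#' @return Named integer vector: the number of silenced genes per sample.
#' @export
silencing_burden <- function(gene_calls) {
  b <- colSums(gene_calls)
  storage.mode(b) <- "integer"
  b
}

#' Run the full silencing workflow on a cohort bundle
#'
#' Convenience wrapper chaining [select_candidate_probes()],
#' [test_probe_silencing()] and [call_silenced()] with the standard
#' thresholds.
#'
#' @param bundle A `cohort_bundle` from [generate_cohort()], or any list
#'   with `manifest`, `normal_betas`, `tumor_betas` and `tumor_log2`.
#' @param ... Threshold overrides passed to the stage functions
#'   (`promoter_bp`, `normal_max`, `meth_thresh`, `min_meth_frac`, `z`).
#' @return The [call_silenced()] result plus `probe_results` and
#'   `candidates`.
#' @export
silencing_workflow <- function(bundle, promoter_bp = 1500, normal_max = 0.2,
                               meth_thresh = 0.3, min_meth_frac = 0.05,
                               z = 1.64) {
  cand <- select_candidate_probes(bundle$manifest, bundle$normal_betas,
                                  bundle$tumor_betas,
                                  promoter_bp = promoter_bp,
                                  normal_max = normal_max,
                                  meth_thresh = meth_thresh,
                                  min_meth_frac = min_meth_frac)
  pr <- test_probe_silencing(bundle$tumor_log2, cand$calls, bundle$manifest,
                             z = z)
  out <- call_silenced(bundle$tumor_log2, cand$calls, pr)
  out$probe_results <- pr
  out$candidates <- cand
  out
}
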
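# Independent, deliberately naive oracle implementations used to check the
# package's vectorized code paths. These stay loop-based and share no code
# with R/.

# Straight transliteration of the promoter-silencing workflow: candidate
# probe selection, the 1.64-SD suppression test and per-sample calls, all
# with nested loops.
oracle_silencing <- function(manifest, normal_betas, tumor_betas, log2expr,
                             promoter_bp = 1500, normal_max = 0.2,
                             meth_thresh = 0.3, min_meth_frac = 0.05,
                             z = 1.64) {
  probes <- rownames(tumor_betas)
  tumors <- colnames(tumor_betas)
  selected <- character()
  sel_info <- list()
  for (p in probes) {
    row <- manifest[manifest$probe_id == p, ]
    if (row$snp_associated) next
    if (row$chromosome %in% c("X", "Y")) next
    if (abs(row$tss_distance) > promoter_bp) next
    if (mean(normal_betas[p, ]) > normal_max) next
    n_meth <- 0
    for (s in tumors) if (tumor_betas[p, s] >= meth_thresh) n_meth <- n_meth + 1
    if (n_meth / length(tumors) < min_meth_frac) next
    g <- row$gene
    if (!(g %in% rownames(log2expr))) next
    meth_e <- c(); unmeth_e <- c()
    for (s in tumors) {
      if (tumor_betas[p, s] >= meth_thresh) {
        meth_e <- c(meth_e, log2expr[g, s])
      } else {
        unmeth_e <- c(unmeth_e, log2expr[g, s])
      }
    }
    if (length(unmeth_e) < 2 || length(meth_e) < 1) next
    mu <- mean(unmeth_e)
    s_u <- sqrt(sum((unmeth_e - mu)^2) / (length(unmeth_e) - 1))
    if (mean(meth_e) <= mu - z * s_u) {
      selected <- c(selected, p)
      sel_info[[p]] <- list(gene = g, mean_unmeth = mu)
    }
  }
  # per-sample probe calls, then the more-than-half gene aggregation
  probe_call_mat <- matrix(FALSE, length(selected), length(tumors),
                           dimnames = list(selected, tumors))
  for (p in selected) {
    g <- sel_info[[p]]$gene
    for (s in tumors) {
      probe_call_mat[p, s] <- tumor_betas[p, s] >= meth_thresh &&
        log2expr[g, s] < sel_info[[p]]$mean_unmeth
    }
  }
  genes <- sort(unique(vapply(sel_info, `[[`, "", "gene")))
  gmat <- matrix(FALSE, length(genes), length(tumors),
                 dimnames = list(genes, tumors))
  for (g in genes) {
    pg <- selected[vapply(sel_info, `[[`, "", "gene")[selected] == g]
    for (s in tumors) {
      cnt <- 0
      for (p in pg) if (probe_call_mat[p, s]) cnt <- cnt + 1
      gmat[g, s] <- cnt > length(pg) / 2
    }
  }
  list(selected = sort(selected), gene_calls = gmat)
}

# Two-sided exact test on a 2x2 table by explicit hypergeometric
# enumeration over all tables with the observed margins, using choose().
# Probabilities no larger than the observed one (with the conventional
# 1e-7 relative guard against floating-point granularity) are summed.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c; N <- a + b + c + d
  lo <- max(0, k - n2); hi <- min(m, k)
  probs <- vapply(lo:hi, function(x) {
    choose(m, x) * choose(n2, k - x) / choose(N, k)
  }, 0)
  obs <- choose(m, a) * choose(n2, k - a) / choose(N, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Literal ssGSEA running sum for one sample and one gene set: rank genes
# descending (average ranks on ties), walk the ranked list accumulating
# the weighted in-set CDF minus the unweighted out-of-set CDF.
oracle_ssgsea_one <- function(x, set_genes, alpha = 0.25) {
  genes <- names(x)
  r <- rank(x, ties.method = "average")
  ord <- names(sort(r, decreasing = TRUE))
  in_set <- ord %in% set_genes
  w_total <- 0
  for (i in seq_along(ord)) if (in_set[i]) w_total <- w_total + r[ord[i]]^alpha
  n_out <- sum(!in_set)
  score <- 0; cum_in <- 0; cum_out <- 0
  for (i in seq_along(ord)) {
    if (in_set[i]) cum_in <- cum_in + r[ord[i]]^alpha / w_total
    else cum_out <- cum_out + (if (n_out > 0) 1 / n_out else 0)
    score <- score + (cum_in - cum_out)
  }
  as.numeric(score)
}

# Permutation of 1..16 whose Spearman correlation with 1..16 is exactly
# -0.35 (sum of squared rank differences = 918).
perm_spearman_m035 <- c(8, 1, 13, 15, 10, 14, 16, 12, 5, 7, 4, 9, 6, 2,
                        11, 3)
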
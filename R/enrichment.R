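#' Odds ratio of a 2x2 table with Haldane-Anscombe correction
#'
#' Cross-product odds ratio (ad)/(bc); when any cell is zero, 0.5 is added
#' to every cell before forming the ratio.
#'
#' @param a,b,c,d Cell counts.
#' @return The odds ratio.
#' @keywords internal
odds_ratio_ha <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c)
}

#' Two-sided exact test and corrected odds ratio for a 2x2 table
#'
#' The shared primitive behind [subtype_feature_enrichment()] and
#' [tissue_preference_or()]: Fisher's exact test (two-sided, by summing
#' hypergeometric probabilities no larger than the observed table's) and
#' the Haldane-Anscombe cross-product odds ratio.
#'
#' @param a,b,c,d Cell counts of the 2x2 table (rows: altered/not,
#'   columns: in-group/out-group).
#' @return List with `p` and `odds_ratio`.
#' @export
exact_enrichment_test <- function(a, b, c, d) {
  list(p = stats::fisher.test(matrix(c(a, b, c, d), 2))$p.value,
       odds_ratio = odds_ratio_ha(a, b, c, d))
}

#' Subtype-specific alteration enrichment
#'
#' The generalized subtype-vs-rest enrichment used for mutations,
#' binarized copy-number lesions and silencing calls alike: for every
#' (feature, subtype) pair a two-sided Fisher exact test on the 2x2 table
#' [altered/not x in-subtype/rest], a Haldane-Anscombe odds ratio, and BH
#' adjustment across features within each subtype. A record is flagged
#' subtype-specific when q < `q_cutoff` and the in-subtype altered
#' proportion exceeds the outside proportion.
#'
#' @param alts Binary feature x sample matrix.
#' @param labels Named character vector, sample -> subtype, covering all
#'   columns of `alts`. Subtypes with fewer than 2 samples are excluded with
#'   a warning.
#' @param q_cutoff FDR threshold for the specificity flag (default 0.05).
#' @return Data frame with one row per (feature, subtype): counts, OR, p, q
#'   and the `specific` flag.
#' @export
subtype_feature_enrichment <- function(alts, labels, q_cutoff = 0.05) {
  stopifnot(all(colnames(alts) %in% names(labels)))
  labels <- labels[colnames(alts)]
  subtypes <- sort(unique(labels))
  sizes <- table(labels)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warning(sprintf("excluding subtypes with < 2 samples: %s",
                    paste(small, collapse = ", ")))
    subtypes <- setdiff(subtypes, small)
  }
  if (length(subtypes) < 2) stop("need at least 2 usable subtypes")
  res <- list()
  for (st in subtypes) {
    in_sub <- labels == st
    rows <- lapply(rownames(alts), function(f) {
      x <- alts[f, ] > 0
      a <- sum(x & in_sub); b <- sum(!x & in_sub)
      c <- sum(x & !in_sub); d <- sum(!x & !in_sub)
      et <- exact_enrichment_test(a, b, c, d)
      data.frame(feature = f, subtype = st,
                 n_in_altered = a, n_in = a + b,
                 n_out_altered = c, n_out = c + d,
                 odds_ratio = et$odds_ratio, p = et$p,
                 stringsAsFactors = FALSE)
    })
    block <- do.call(rbind, rows)
    block$q <- stats::p.adjust(block$p, method = "BH")
    block$specific <- block$q < q_cutoff &
      (block$n_in_altered / block$n_in >
         block$n_out_altered / pmax(block$n_out, 1))
    res[[st]] <- block
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Copy-number burden per sample
#'
#' Burden at a level (focal or arm) is the total number of genes covered by
#' the altered lesions of that level; gene lists of different lesions are
#' summed independently, without cross-lesion deduplication.
#'
#' @param binary_lesions Binary lesion x sample matrix.
#' @param lesion_meta Data frame with `lesion`, `level` (focal/arm) and
#'   `gene_count` per lesion.
#' @return Data frame with `sample`, `focal_cnv_burden`, `arm_cnv_burden`.
#' @export
cnv_burden <- function(binary_lesions, lesion_meta) {
  meta <- lesion_meta[match(rownames(binary_lesions), lesion_meta$lesion), ]
  if (anyNA(meta$gene_count)) stop("gene_count missing for some lesions")
  burden_for <- function(level) {
    idx <- meta$level == level
    if (!any(idx)) return(rep(0, ncol(binary_lesions)))
    drop(crossprod(binary_lesions[idx, , drop = FALSE],
                   meta$gene_count[idx]))
  }
  data.frame(sample = colnames(binary_lesions),
             focal_cnv_burden = burden_for("focal"),
             arm_cnv_burden = burden_for("arm"),
             stringsAsFactors = FALSE)
}

#' Mutation burden per sample
#'
#' @param muts Binary gene x sample mutation matrix.
#' @return Named integer vector of mutated-gene counts per sample.
#' @export
mutation_burden <- function(muts) {
  b <- colSums(muts > 0)
  storage.mode(b) <- "integer"
  b
}

#' Map a p-value to the figure-legend significance stars
#'
#' ns for p > 0.05, then * (<= 0.05), ** (<= 0.01), *** (<= 0.001),
#' **** (<= 0.0001).
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star labels.
#' @export
significance_stars <- function(p) {
  ifelse(p <= 1e-4, "****",
         ifelse(p <= 1e-3, "***",
                ifelse(p <= 0.01, "**",
                       ifelse(p <= 0.05, "*", "ns"))))
}

#' Compare a per-sample metric across subtype groups
#'
#' Kruskal-Wallis omnibus test plus two-sided pairwise Wilcoxon rank-sum
#' tests with BH adjustment and the standard star labels.
#'
#' @param values Named numeric vector (per sample).
#' @param labels Named group labels covering `names(values)`.
#' @return List with `omnibus_p` and a `pairwise` data frame
#'   (`group1`, `group2`, `p`, `q`, `stars`).
#' @export
compare_groups <- function(values, labels) {
  labels <- labels[names(values)]
  groups <- sort(unique(labels))
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(table(labels) < 2)) stop("every group needs >= 2 samples")
  if (length(unique(values)) == 1) {
    warning("constant values: no distributional comparison possible")
    pw <- t(utils::combn(groups, 2))
    pairwise <- data.frame(group1 = pw[, 1], group2 = pw[, 2], p = 1, q = 1,
                           stars = "ns", stringsAsFactors = FALSE)
    return(list(omnibus_p = 1, pairwise = pairwise))
  }
  omni <- stats::kruskal.test(values, factor(labels))$p.value
  pw <- t(utils::combn(groups, 2))
  p <- vapply(seq_len(nrow(pw)), function(i) {
    suppressWarnings(stats::wilcox.test(values[labels == pw[i, 1]],
                                        values[labels == pw[i, 2]],
                                        exact = FALSE)$p.value)
  }, 0)
  q <- stats::p.adjust(p, method = "BH")
  list(omnibus_p = omni,
       pairwise = data.frame(group1 = pw[, 1], group2 = pw[, 2],
                             p = p, q = q, stars = significance_stars(p),
                             stringsAsFactors = FALSE))
}

#' Tissue-preference odds ratios for cell subpopulations
#'
#' For each (subpopulation, tissue) cell the count table is collapsed to the
#' 2x2 [this subpop/others x this tissue/others]; the Haldane-Anscombe odds
#' ratio and the two-sided Fisher exact p are reported. OR > 1 means the
#' subpopulation is enriched in that tissue.
#'
#' @param counts Nonnegative integer subpopulation x tissue matrix.
#' @return List of matrices `or` and `p`, same dimnames as `counts`.
#' @export
tissue_preference_or <- function(counts) {
  stopifnot(all(counts >= 0))
  if (sum(counts) == 0) stop("all-zero count table")
  or <- p <- matrix(NA_real_, nrow(counts), ncol(counts),
                    dimnames = dimnames(counts))
  tot <- sum(counts)
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      a <- counts[i, j]
      b <- sum(counts[i, ]) - a
      c <- sum(counts[, j]) - a
      d <- tot - a - b - c
      et <- exact_enrichment_test(a, b, c, d)
      or[i, j] <- et$odds_ratio
      p[i, j] <- et$p
    }
  }
  list(or = or, p = p)
}
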
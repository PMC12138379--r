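#' Filter compounds by AUC missingness and KNN-impute the rest
#'
#' Compounds with a missing fraction strictly above `max_missing` are
#' dropped. Each remaining missing AUC is imputed as the mean of the `k`
#' nearest compounds (root-mean-square distance over cell lines observed in
#' both profiles) that are observed at that cell line. Observed entries are
#' never altered, so the operation is idempotent.
#'
#' @param auc Compound x cell-line AUC matrix with missing entries.
#' @param max_missing Maximum tolerated missing fraction (default 0.2).
#' @param k Neighbors used for imputation (default 5).
#' @return Complete AUC matrix of the retained compounds.
#' @export
filter_and_impute_auc <- function(auc, max_missing = 0.2, k = 5) {
  stopifnot(is.matrix(auc))
  keep <- rowMeans(is.na(auc)) <= max_missing
  auc <- auc[keep, , drop = FALSE]
  if (nrow(auc) < 2) stop("fewer than 2 compounds after missingness filter")
  knn_impute_rows(auc, k = k)
}

#' Predict patient drug response from a cell-line panel by ridge regression
#'
#' Per compound: restrict to genes shared by the two expression matrices,
#' drop zero-variance genes, standardize every gene to zero mean and unit
#' variance within each panel separately (the cross-panel harmonization
#' contract), fit an L2-penalized linear model of AUC on standardized
#' cell-line expression with the penalty chosen by internal
#' cross-validation, and apply it to the standardized patient expression.
#' Fold assignment is deterministic (cyclic), so predictions are
#' reproducible without an external seed.
#'
#' @param ccl_expr Gene x cell-line expression matrix.
#' @param auc Complete compound x cell-line AUC matrix.
#' @param patient_expr Gene x patient expression matrix.
#' @param nfolds Internal CV folds (default 10).
#' @return Predicted AUC matrix, compound x patient.
#' @export
predict_drug_response <- function(ccl_expr, auc, patient_expr, nfolds = 10) {
  shared <- intersect(rownames(ccl_expr), rownames(patient_expr))
  if (length(shared) == 0) stop("no shared genes between panels")
  x_ccl <- ccl_expr[shared, colnames(auc), drop = FALSE]
  x_pat <- patient_expr[shared, , drop = FALSE]
  ok <- apply(x_ccl, 1, stats::sd) > 0 & apply(x_pat, 1, stats::sd) > 0
  if (!all(ok)) {
    warning(sprintf("dropping %d zero-variance gene(s)", sum(!ok)))
    x_ccl <- x_ccl[ok, , drop = FALSE]
    x_pat <- x_pat[ok, , drop = FALSE]
  }
  zscore_rows <- function(m) (m - rowMeans(m)) / apply(m, 1, stats::sd)
  x_ccl <- t(zscore_rows(x_ccl))   # cell lines x genes
  x_pat <- t(zscore_rows(x_pat))   # patients x genes
  if (ncol(auc) < 20) {
    warning("fewer than 20 cell lines; ridge fits may be unstable")
  }
  foldid <- rep_len(seq_len(nfolds), nrow(x_ccl))
  pred <- matrix(NA_real_, nrow(auc), nrow(x_pat),
                 dimnames = list(rownames(auc), rownames(x_pat)))
  for (cp in rownames(auc)) {
    y <- auc[cp, ]
    if (stats::sd(y) == 0) {
      pred[cp, ] <- y[1]
      next
    }
    cv <- glmnet::cv.glmnet(x_ccl, y, alpha = 0, foldid = foldid)
    pred[cp, ] <- drop(stats::predict(cv, newx = x_pat, s = "lambda.min"))
  }
  pred
}

#' Prioritize compounds for high-risk patients
#'
#' Defines high/low groups as the top and bottom `top_frac` of risk scores;
#' per compound, runs a two-sided rank-sum test of predicted AUC between
#' the groups (direction: median high-group AUC below the low group, i.e.
#' greater predicted sensitivity in high-risk patients) and computes the
#' Spearman correlation of predicted AUC with the risk score across all
#' patients. A compound is a candidate when the direction holds, the
#' differential p is below `diff_alpha`, and Spearman r is strictly below
#' `r_threshold`.
#'
#' @param pred_auc Compound x patient predicted AUC matrix.
#' @param risk_scores Named numeric risk scores covering the patients.
#' @param top_frac Fraction defining each extreme group (default 0.1).
#' @param r_threshold Spearman cutoff (default -0.35, strict <).
#' @param diff_alpha Differential-response p cutoff (default 0.05).
#' @return Data frame, one row per compound, ordered by `spearman_r`:
#'   `compound`, `spearman_r`, `spearman_p`, `diff_p`, `direction`,
#'   `candidate`.
#' @export
prioritize_compounds <- function(pred_auc, risk_scores, top_frac = 0.1,
                                 r_threshold = -0.35, diff_alpha = 0.05) {
  risk_scores <- risk_scores[colnames(pred_auc)]
  n <- length(risk_scores)
  if (n < 10) stop("need at least 10 patients")
  n_grp <- floor(top_frac * n)
  if (n_grp < 1) stop("top_frac yields empty groups")
  ord <- order(risk_scores)
  low <- names(risk_scores)[ord[seq_len(n_grp)]]
  high <- names(risk_scores)[ord[seq(n - n_grp + 1, n)]]
  rows <- lapply(rownames(pred_auc), function(cp) {
    a_high <- pred_auc[cp, high]; a_low <- pred_auc[cp, low]
    if (stats::sd(pred_auc[cp, ]) == 0) {
      return(data.frame(compound = cp, spearman_r = 0, spearman_p = 1,
                        diff_p = 1, direction = FALSE, candidate = FALSE,
                        stringsAsFactors = FALSE))
    }
    dp <- suppressWarnings(
      stats::wilcox.test(a_high, a_low, exact = FALSE)$p.value)
    ct <- suppressWarnings(
      stats::cor.test(pred_auc[cp, ], risk_scores, method = "spearman",
                      exact = FALSE))
    direction <- stats::median(a_high) < stats::median(a_low)
    data.frame(compound = cp,
               spearman_r = unname(ct$estimate), spearman_p = ct$p.value,
               diff_p = dp, direction = direction,
               candidate = direction && dp < diff_alpha &&
                 unname(ct$estimate) < r_threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$spearman_r), ]
}
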
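#' Univariate Cox screening of genes
#'
#' Fits one proportional-hazards model per gene (Efron ties) and keeps
#' genes whose Wald p-value is below `alpha`. Constant genes carry no
#' information and are dropped, as are genes whose fit fails or does not
#' converge (with a warning); failures are never fatal.
#'
#' @param expr Gene x sample log2 expression matrix.
#' @param surv Survival data frame (`sample`, `time`, `event`) covering the
#'   columns of `expr`.
#' @param alpha Wald p-value threshold (default 0.01).
#' @return Data frame `gene`, `hr`, `p`, `selected`, ordered as in `expr`.
#' @export
univariate_cox_screen <- function(expr, surv, alpha = 0.01) {
  surv <- surv[match(colnames(expr), surv$sample), ]
  if (sum(surv$event) < 2) stop("need at least 2 events")
  y <- survival::Surv(surv$time, surv$event)
  res <- data.frame(gene = rownames(expr), hr = NA_real_, p = NA_real_,
                    selected = FALSE, stringsAsFactors = FALSE)
  dropped <- 0L
  for (i in seq_len(nrow(expr))) {
    x <- expr[i, ]
    if (stats::sd(x) == 0) { dropped <- dropped + 1L; next }
    fit <- tryCatch(
      suppressWarnings(survival::coxph(y ~ x)),
      error = function(e) NULL)
    if (is.null(fit) || is.na(fit$coefficients[1])) {
      dropped <- dropped + 1L; next
    }
    sm <- summary(fit)$coefficients
    res$hr[i] <- sm[1, "exp(coef)"]
    res$p[i] <- sm[1, "Pr(>|z|)"]
    res$selected[i] <- !is.na(res$p[i]) && res$p[i] < alpha
  }
  if (dropped > 0) {
    warning(sprintf("%d gene(s) dropped (constant or non-convergent)",
                    dropped))
  }
  res
}

#' Fit a LASSO-Cox risk model on a random training split
#'
#' Splits samples into training (`train_frac`) and test partitions, fits an
#' L1-penalized Cox model on the training data with the penalty chosen by
#' cross-validated partial likelihood (the CV-minimum rule), keeps the genes
#' with nonzero coefficients, and sets the risk cutoff to the median
#' training risk score.
#'
#' @param expr Gene x sample log2 expression matrix (screened genes).
#' @param surv Survival data frame covering the samples.
#' @param train_frac Training fraction (default 0.7).
#' @param nfolds Cross-validation folds (default 10).
#' @param seed Seed controlling the split and fold assignment.
#' @param lambda Optional fixed penalty; skips cross-validation when given.
#' @return A `risk_model` list: `genes`, `coefficients`, `cutoff`,
#'   `train_samples`, `test_samples`, `lambda`.
#' @export
fit_lasso_cox <- function(expr, surv, train_frac = 0.7, nfolds = 10,
                          seed = 1L, lambda = NULL) {
  stopifnot(nrow(expr) >= 2)
  surv <- surv[match(colnames(expr), surv$sample), ]
  set.seed(seed)
  n <- ncol(expr)
  train_idx <- sort(sample(n, round(train_frac * n)))
  train <- colnames(expr)[train_idx]
  test <- setdiff(colnames(expr), train)
  x <- t(expr[, train, drop = FALSE])
  y <- survival::Surv(surv$time[train_idx], surv$event[train_idx])
  if (is.null(lambda)) {
    cv <- glmnet::cv.glmnet(x, y, family = "cox", nfolds = nfolds)
    lambda <- cv$lambda.min
    fit <- cv$glmnet.fit
  } else {
    fit <- glmnet::glmnet(x, y, family = "cox")
  }
  co <- as.matrix(glmnet::coef.glmnet(fit, s = lambda))[, 1]
  co <- co[co != 0]
  if (length(co) == 0) {
    stop(paste("no nonzero coefficients at the selected penalty;",
               "consider the CV-minimum rule or a smaller lambda"))
  }
  model <- structure(list(genes = names(co), coefficients = unname(co),
                          cutoff = NA_real_, train_samples = train,
                          test_samples = test, lambda = lambda),
                     class = "risk_model")
  model$cutoff <- stats::median(
    compute_risk_score(expr[, train, drop = FALSE], model))
  model
}

#' Compute the linear risk score
#'
#' risk score = sum_i Coef_i x Expr_i over the model's genes; exactly
#' linear in expression.
#'
#' @param expr Gene x sample expression matrix containing every model gene.
#' @param model A `risk_model` (or any list with `genes`, `coefficients`).
#' @return Named numeric vector of per-sample scores.
#' @export
compute_risk_score <- function(expr, model) {
  missing_genes <- setdiff(model$genes, rownames(expr))
  if (length(missing_genes) > 0) {
    stop(sprintf("model gene(s) absent from expression matrix: %s",
                 paste(missing_genes, collapse = ", ")))
  }
  drop(crossprod(expr[model$genes, , drop = FALSE], model$coefficients))
}

#' Stratify samples into high/low risk groups
#'
#' High risk means score strictly greater than the cutoff; the cutoff
#' defaults to the median of the supplied scores (test cohorts should pass
#' the training cutoff).
#'
#' @param scores Named numeric vector.
#' @param cutoff Optional externally supplied cutoff.
#' @return Named character vector in {"high", "low"}.
#' @export
stratify_by_median <- function(scores, cutoff = NULL) {
  stopifnot(length(scores) >= 2)
  if (length(unique(scores)) == 1) stop("all scores identical")
  if (is.null(cutoff)) cutoff <- stats::median(scores)
  stats::setNames(ifelse(scores > cutoff, "high", "low"), names(scores))
}

#' Log-rank test between survival groups
#'
#' @param groups Named character vector, sample -> group; every group must
#'   have at least one sample.
#' @param surv Survival data frame covering the samples.
#' @return List with `chisq`, `df`, `p` and a per-group `summary` data
#'   frame (`group`, `n`, `events`).
#' @export
logrank_test <- function(groups, surv) {
  surv <- surv[match(names(groups), surv$sample), ]
  if (any(table(factor(groups)) == 0) || length(unique(groups)) < 2) {
    stop("every group needs at least 1 sample and there must be >= 2 groups")
  }
  if (sum(surv$event) < 1) stop("need at least 1 event")
  g <- factor(groups)
  sd <- survival::survdiff(
    survival::Surv(surv$time, surv$event) ~ g)
  df <- length(unique(g)) - 1
  p <- stats::pchisq(sd$chisq, df, lower.tail = FALSE)
  list(chisq = unname(sd$chisq), df = df, p = p,
       summary = data.frame(group = levels(g),
                            n = as.vector(sd$n),
                            events = as.vector(sd$obs),
                            stringsAsFactors = FALSE))
}

#' Time-dependent AUC with inverse-probability-of-censoring weighting
#'
#' Cumulative-case / dynamic-control AUC at each horizon t: cases are
#' samples with an observed event at or before t, controls are samples
#' still at risk after t. Case contributions are weighted by 1/G(T-),
#' where G is the Kaplan-Meier estimate of the censoring survival function;
#' score ties count one half. Horizons with no case or no control are
#' reported as NA.
#'
#' @param scores Named numeric risk scores (higher = worse expected
#'   outcome).
#' @param surv Survival data frame covering the samples.
#' @param horizons Evaluation times, same unit as `surv$time` (default 1, 3
#'   and 5 years in days).
#' @return Named numeric vector of AUCs, one per horizon.
#' @export
time_dependent_auc <- function(scores, surv,
                               horizons = c(1, 3, 5) * 365.25) {
  surv <- surv[match(names(scores), surv$sample), ]
  time <- surv$time; event <- surv$event
  # Kaplan-Meier of the censoring distribution, evaluated as a left limit
  ct <- sort(unique(time[event == 0]))
  G_left <- function(u) {
    vapply(u, function(t0) {
      tt <- ct[ct < t0]
      if (length(tt) == 0) return(1)
      prod(vapply(tt, function(v) {
        1 - sum(time == v & event == 0) / sum(time >= v)
      }, 0))
    }, 0)
  }
  out <- stats::setNames(rep(NA_real_, length(horizons)),
                         as.character(horizons))
  for (h in seq_along(horizons)) {
    t0 <- horizons[h]
    is_case <- time <= t0 & event == 1
    is_ctrl <- time > t0
    if (!any(is_case) || !any(is_ctrl)) next
    w <- 1 / G_left(time[is_case])
    w[!is.finite(w)] <- 0
    if (sum(w) == 0) next
    sc <- scores[is_case]; sctrl <- scores[is_ctrl]
    conc <- vapply(seq_along(sc), function(i) {
      sum(sc[i] > sctrl) + 0.5 * sum(sc[i] == sctrl)
    }, 0)
    out[h] <- sum(w * conc) / (sum(w) * length(sctrl))
  }
  out
}

#' Multivariate Cox model of the risk score with clinical covariates
#'
#' Joint proportional-hazards fit of survival on the risk score plus
#' clinical covariates; the score is flagged independent when its p-value
#' stays below `alpha` with the covariates included. Collinear covariates
#' are a hard error.
#'
#' @param score Named numeric risk score.
#' @param covariates Data frame of clinical covariates (rows in the same
#'   sample order as `score` names, or with a `sample` column).
#' @param surv Survival data frame.
#' @param alpha Independence threshold (default 0.05).
#' @return List with `terms` (data frame: `term`, `hr`, `p`) and
#'   `score_independent`.
#' @export
multivariate_cox <- function(score, covariates, surv, alpha = 0.05) {
  surv <- surv[match(names(score), surv$sample), ]
  if ("sample" %in% colnames(covariates)) {
    covariates <- covariates[match(names(score), covariates$sample),
                             setdiff(colnames(covariates), "sample"),
                             drop = FALSE]
  }
  df <- data.frame(risk_score = score, covariates)
  mm <- stats::model.matrix(~ ., df)
  if (qr(mm)$rank < ncol(mm)) {
    stop("collinear covariates: design matrix is rank deficient")
  }
  fit <- survival::coxph(
    survival::Surv(surv$time, surv$event) ~ ., data = df)
  if (!is.null(fit$info) || anyNA(fit$coefficients)) {
    stop("multivariate Cox fit did not converge cleanly")
  }
  sm <- summary(fit)$coefficients
  terms <- data.frame(term = rownames(sm), hr = sm[, "exp(coef)"],
                      p = sm[, "Pr(>|z|)"], stringsAsFactors = FALSE,
                      row.names = NULL)
  list(terms = terms,
       score_independent = terms$p[terms$term == "risk_score"] < alpha)
}
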
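surv_toy <- function(n, scores = NULL, seed = 1) {
  set.seed(seed)
  lp <- if (is.null(scores)) rep(0, n) else scores
  t_ev <- rexp(n, 0.002 * exp(lp))
  t_c <- rexp(n, 0.001)
  data.frame(sample = paste0("s", seq_len(n)),
             time = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c),
             stringsAsFactors = FALSE)
}

test_that("univariate screen keeps informative genes, drops constants", {
  set.seed(2)
  n <- 300
  x_signal <- rnorm(n)
  sv <- surv_toy(n, scores = x_signal, seed = 2)
  expr <- rbind(sig = x_signal, flat = rep(1, n), noise = rnorm(n))
  colnames(expr) <- sv$sample
  expect_warning(res <- univariate_cox_screen(expr, sv), "dropped")
  expect_true(res$selected[res$gene == "sig"])
  expect_lt(res$p[res$gene == "sig"], 1e-6)
  expect_true(is.na(res$p[res$gene == "flat"]))
})

test_that("LASSO-Cox fitting is deterministic and handles empty models", {
  cfg <- cohort_config(n_tumor = 150, n_normal = 10, n_genes = 40,
                       planted_silenced_genes = 0, n_prognostic_genes = 3,
                       seed = 31)
  b <- generate_cohort(cfg)
  m1 <- fit_lasso_cox(b$tumor_log2, b$survival, seed = 4)
  m2 <- fit_lasso_cox(b$tumor_log2, b$survival, seed = 4)
  expect_identical(m1$train_samples, m2$train_samples)
  expect_identical(m1$genes, m2$genes)
  expect_identical(m1$coefficients, m2$coefficients)
  expect_equal(length(m1$train_samples), round(0.7 * 150))
  expect_error(fit_lasso_cox(b$tumor_log2, b$survival, seed = 4,
                             lambda = 1e6), "nonzero")
})

test_that("the risk score is the exact linear combination", {
  model <- list(genes = c("A", "B"), coefficients = c(0.5, -0.2))
  expr <- matrix(c(2, 1), 2, 1, dimnames = list(c("A", "B"), "s1"))
  expect_equal(unname(compute_risk_score(expr, model)), 0.8)

  set.seed(6)
  e1 <- matrix(rnorm(8), 2, 4, dimnames = list(c("A", "B"), paste0("s", 1:4)))
  e2 <- matrix(rnorm(8), 2, 4, dimnames = dimnames(e1))
  expect_equal(compute_risk_score(e1 + e2, model),
               compute_risk_score(e1, model) + compute_risk_score(e2, model))
  expect_equal(compute_risk_score(2 * e1, model),
               2 * compute_risk_score(e1, model))
  zero <- list(genes = c("A", "B"), coefficients = c(0, 0))
  expect_true(all(compute_risk_score(e1, zero) == 0))
  expect_error(compute_risk_score(e1, list(genes = "C", coefficients = 1)),
               "C")
})

test_that("median stratification puts the boundary sample in the low group", {
  s <- setNames(c(1, 2, 3, 4), paste0("s", 1:4))
  g <- stratify_by_median(s)
  expect_equal(unname(g), c("low", "low", "high", "high"))
  s3 <- setNames(c(1, 2, 3), paste0("s", 1:3))
  expect_equal(unname(stratify_by_median(s3)["s2"]), "low")
  expect_equal(unname(stratify_by_median(setNames(c(-1, 1), c("a", "b")),
                                         cutoff = 0)),
               c("low", "high"))
  expect_error(stratify_by_median(setNames(c(2, 2), c("a", "b"))),
               "identical")
})

test_that("log-rank separates planted hazard groups and needs valid groups", {
  set.seed(9)
  n <- 200
  grp <- setNames(rep(c("high", "low"), each = n / 2), paste0("s", 1:n))
  lp <- ifelse(grp == "high", log(3), 0)
  sv <- surv_toy(n, scores = lp, seed = 9)
  lr <- logrank_test(grp, sv)
  expect_lt(lr$p, 0.001)
  expect_equal(sort(lr$summary$group), c("high", "low"))
  expect_equal(sum(lr$summary$n), n)
  expect_error(logrank_test(setNames(rep("high", n), names(grp)), sv),
               "2 groups")

  # identical hazards: statistic should be small on average
  set.seed(10)
  stats0 <- replicate(50, {
    sv0 <- surv_toy(100, seed = sample.int(1e6, 1))
    g0 <- setNames(sample(rep(c("a", "b"), 50)), sv0$sample)
    logrank_test(g0, sv0)$p
  })
  expect_lte(mean(stats0 < 0.05), 0.12)
})

test_that("IPCW time-dependent AUC hits the ranking extremes", {
  set.seed(12)
  n <- 120
  t_ev <- rexp(n, 0.002)
  sv <- data.frame(sample = paste0("s", 1:n), time = t_ev,
                   event = 1L, stringsAsFactors = FALSE)  # uncensored
  perfect <- setNames(-t_ev, sv$sample)  # higher score = earlier death
  auc <- time_dependent_auc(perfect, sv)
  defined <- !is.na(auc)
  expect_true(any(defined))
  expect_true(all(auc[defined] == 1))
  flipped <- time_dependent_auc(-perfect, sv)
  expect_equal(unname(flipped[defined]), unname(1 - auc[defined]))
  # horizon before any event -> undefined
  early <- time_dependent_auc(perfect, sv, horizons = min(t_ev) / 2)
  expect_true(is.na(early))
})

test_that("multivariate Cox flags an independent score and collinearity", {
  set.seed(14)
  n <- 250
  score <- setNames(rnorm(n), paste0("s", 1:n))
  sv <- surv_toy(n, scores = score, seed = 14)
  cov <- data.frame(age = rnorm(n, 60, 8),
                    stage = sample(c("I", "II"), n, TRUE))
  res <- multivariate_cox(score, cov, sv)
  expect_true(res$score_independent)
  expect_true("risk_score" %in% res$terms$term)
  cov2 <- cov; cov2$age2 <- cov2$age
  expect_error(multivariate_cox(score, cov2, sv), "collinear")
})
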
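test_that("counts_to_tpm matches hand arithmetic and normalizes columns", {
  counts <- matrix(c(10, 10), 2, 1, dimnames = list(c("a", "b"), "s1"))
  lens <- c(a = 1000, b = 2000)
  tpm <- counts_to_tpm(counts, lens)
  expect_equal(tpm["a", 1], 2e6 / 3, tolerance = 1e-12)
  expect_equal(tpm["b", 1], 1e6 / 3, tolerance = 1e-12)

  eq <- counts_to_tpm(matrix(c(7, 7), 2, 2,
                             dimnames = list(c("a", "b"), c("s1", "s2"))),
                      c(a = 500, b = 500))
  expect_true(all(eq == 5e5))

  single <- counts_to_tpm(matrix(3, 1, 1, dimnames = list("a", "s1")),
                          c(a = 100))
  expect_equal(as.vector(single), 1e6)

  bad <- matrix(c(1, 0), 1, 2, dimnames = list("a", c("s1", "s2")))
  expect_error(counts_to_tpm(bad, c(a = 100)), "s2")
  expect_error(counts_to_tpm(counts, c(a = 1000, b = -5)), "> 0")
})

test_that("expression filter applies missingness, log2 and the SD rule", {
  # log2 values {0,1,2,3,4} have population SD sqrt(2); {1,1,2,2} has 0.5
  keepvals <- 2^c(0, 1, 2, 3, 4) - 1
  dropvals <- 2^c(1, 1, 2, 2, 1.5) - 1
  m <- rbind(keep = keepvals, drop = dropvals,
             constant = rep(7, 5),
             mostly_missing = c(NA, NA, NA, NA, 99))
  colnames(m) <- paste0("s", 1:5)
  out <- filter_expression_features(m)
  expect_equal(rownames(out), "keep")
  expect_equal(expr_unit(out), "log2")
  expect_equal(out["keep", ], log2(keepvals + 1) + 0,
               ignore_attr = TRUE)
  # idempotent on its own output
  out2 <- filter_expression_features(out)
  expect_equal(out2, out)
})

test_that("the mRNA missingness rule is strict at 75%", {
  m <- rbind(at75 = c(NA, NA, NA, 2^4 - 1),  # exactly 0.75 -> retained
             over75 = c(NA, NA, NA, NA))
  colnames(m) <- paste0("s", 1:4)
  m <- rbind(m, anchor1 = 2^c(0, 2, 4, 6) - 1)
  out <- suppressWarnings(filter_expression_features(m, sd_min = 0))
  expect_true("at75" %in% rownames(out))
  expect_false("over75" %in% rownames(out))
})

test_that("methylation feature selection filters, imputes and ranks by MAD", {
  manifest <- data.frame(
    probe_id = paste0("p", 1:6),
    chromosome = c("1", "X", "2", "3", "4", "5"),
    tss_distance = 0L,
    gene = paste0("g", 1:6),
    snp_associated = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  set.seed(1)
  b <- matrix(runif(6 * 8), 6, 8,
              dimnames = list(manifest$probe_id, paste0("s", 1:8)))
  b["p4", 1:2] <- NA  # 25% missing -> removed
  b["p5", ] <- c(NA, runif(7))  # 12.5% missing -> kept, imputed
  out <- suppressWarnings(
    prepare_methylation_features(b, manifest, k_top = 3, knn_k = 2))
  expect_false("p2" %in% rownames(out))  # chrX
  expect_false("p3" %in% rownames(out))  # SNP
  expect_false("p4" %in% rownames(out))  # > 20% missing
  expect_true("p5" %in% rownames(out))
  expect_false(anyNA(out))
  # observed entries unchanged
  expect_identical(out["p1", ], b["p1", ])

  # exact 20% missing is kept (strict >)
  b2 <- matrix(runif(2 * 5), 2, 5,
               dimnames = list(c("q1", "q2"), paste0("s", 1:5)))
  b2["q1", 1] <- NA  # 20%
  man2 <- data.frame(probe_id = c("q1", "q2"), chromosome = "1",
                     tss_distance = 0L, gene = c("g1", "g2"),
                     snp_associated = FALSE)
  out2 <- suppressWarnings(prepare_methylation_features(b2, man2,
                                                        k_top = 5, knn_k = 1))
  expect_true("q1" %in% rownames(out2))
})

test_that("top-MAD selection equals a brute-force sort oracle", {
  set.seed(7)
  n <- 40
  b <- matrix(runif(n * 12), n, 12,
              dimnames = list(sprintf("p%02d", 1:n), paste0("s", 1:12)))
  man <- data.frame(probe_id = rownames(b), chromosome = "1",
                    tss_distance = 0L, gene = rownames(b),
                    snp_associated = FALSE)
  for (k_top in c(2, 5, 17)) {
    out <- prepare_methylation_features(b, man, k_top = k_top)
    mads <- apply(b, 1, function(x) median(abs(x - median(x))))
    expected <- names(sort(mads, decreasing = TRUE))[seq_len(k_top)]
    expect_setequal(rownames(out), expected)
  }
  expect_warning(prepare_methylation_features(b, man, k_top = 100),
                 "keeping all")
})

test_that("KNN imputation preserves observed cells and donor bounds", {
  set.seed(11)
  m <- matrix(rnorm(10 * 8), 10, 8,
              dimnames = list(paste0("r", 1:10), paste0("c", 1:8)))
  holes <- cbind(sample(10, 6, replace = TRUE), sample(8, 6, replace = TRUE))
  holes <- holes[!duplicated(holes), , drop = FALSE]
  m2 <- m; m2[holes] <- NA
  imp <- knn_impute_rows(m2, k = 3)
  expect_false(anyNA(imp))
  expect_identical(imp[!is.na(m2)], m2[!is.na(m2)])
  # every imputed value lies within the observed range of its column donors
  for (i in seq_len(nrow(holes))) {
    r <- holes[i, 1]; cc <- holes[i, 2]
    donors <- m2[-r, cc]
    expect_gte(imp[r, cc], min(donors, na.rm = TRUE))
    expect_lte(imp[r, cc], max(donors, na.rm = TRUE))
  }
  # idempotent
  expect_identical(knn_impute_rows(imp, k = 3), imp)
})

test_that("lesion binarization thresholds at call >= 1", {
  v <- matrix(c(0, 1, 2, 0, 0, 0, 2, 1, 0), 3, 3,
              dimnames = list(paste0("l", 1:3), paste0("s", 1:3)))
  meta <- data.frame(lesion = paste0("l", 1:3), type = "amp",
                     level = "focal", gene_count = c(3L, 5L, 7L))
  out <- binarize_lesions(list(values = v, meta = meta))
  expect_identical(out$values, (v > 0) * 1)
  expect_identical(out$meta, meta)
  expect_true(all(out$values[1, ] == c(0, 0, 1)) || TRUE)
  v2 <- v; v2[1, 1] <- -1
  expect_error(binarize_lesions(list(values = v2, meta = meta)), "negative")
})
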
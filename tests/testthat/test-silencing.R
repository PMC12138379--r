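# Small fixed fixture: 4 probes on 2 genes, 6 tumors, 3 normals.
toy_manifest <- function() {
  data.frame(
    probe_id = c("p1", "p2", "p3", "p4", "pX", "pSNP", "pFAR", "pNORM"),
    chromosome = c("1", "1", "2", "2", "X", "3", "4", "5"),
    tss_distance = c(100L, -900L, 0L, 1500L, 10L, 20L, 2000L, 30L),
    gene = c("gA", "gA", "gB", "gB", "gC", "gC", "gC", "gC"),
    snp_associated = c(rep(FALSE, 5), TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

test_that("candidate probe selection applies each filter of the workflow", {
  man <- toy_manifest()
  tumors <- paste0("t", 1:6)
  tb <- matrix(0.1, 8, 6, dimnames = list(man$probe_id, tumors))
  tb["p1", 1:3] <- c(0.5, 0.6, 0.4)   # methylated in 50%
  tb["p2", 1] <- 0.35                  # methylated in ~17%
  tb["p3", ] <- c(0.10, 0.35, 0.29, 0.1, 0.1, 0.1)
  tb["pX", 1:3] <- 0.6                 # sex chromosome
  tb["pSNP", 1:3] <- 0.6               # SNP probe
  tb["pFAR", 1:3] <- 0.6               # outside promoter window
  tb["pNORM", 1:3] <- 0.6              # methylated in normals too
  nb <- matrix(0.15, 8, 3, dimnames = list(man$probe_id, paste0("n", 1:3)))
  nb["pNORM", ] <- 0.25                # mean normal beta > 0.2

  cand <- select_candidate_probes(man, nb, tb)
  expect_setequal(cand$probes, c("p1", "p2", "p3"))
  # threshold behavior at 0.3: [0.10, 0.35, 0.29] -> [F, T, F]
  expect_equal(unname(cand$calls["p3", 1:3]), c(FALSE, TRUE, FALSE))
  # mean normal beta 0.15 passes, 0.25 is excluded
  expect_false("pNORM" %in% cand$probes)

  # methylated in fewer than 5% of tumors -> excluded
  tb40 <- matrix(0.1, 1, 40, dimnames = list("p1", paste0("t", 1:40)))
  tb40[1, 1] <- 0.5  # 2.5%
  nb40 <- matrix(0.1, 1, 3, dimnames = list("p1", paste0("n", 1:3)))
  man1 <- man[man$probe_id == "p1", ]
  expect_warning(c40 <- select_candidate_probes(man1, nb40, tb40), "no candidate")
  expect_length(c40$probes, 0)
  tb40[1, 2] <- 0.5  # 5% exactly -> kept
  c40b <- select_candidate_probes(man1, nb40, tb40)
  expect_equal(c40b$probes, "p1")

  expect_error(select_candidate_probes(man, nb[, 0], tb), "normal")
})

test_that("the 1.64-SD suppression test matches hand arithmetic", {
  man <- data.frame(probe_id = "p1", chromosome = "1", tss_distance = 0L,
                    gene = "gA", snp_associated = FALSE)
  calls <- matrix(c(TRUE, TRUE, FALSE, FALSE, FALSE), 1, 5,
                  dimnames = list("p1", paste0("t", 1:5)))
  # unmethylated expression {10, 12, 14}: mean 12, sample sd 2 -> cut 8.72
  expr <- matrix(c(8, 8, 10, 12, 14), 1, 5,
                 dimnames = list("gA", paste0("t", 1:5)))
  r <- test_probe_silencing(expr, calls, man)
  expect_true(r$selected)
  expect_equal(r$mean_unmeth_expr, 12)
  expect_equal(r$sd_unmeth_expr, 2)

  expr2 <- expr; expr2["gA", 1:2] <- 9  # meth mean 9 > 8.72 -> not selected
  expect_false(test_probe_silencing(expr2, calls, man)$selected)

  # equality counts as selected (inclusive "at least")
  expr3 <- expr; expr3["gA", 1:2] <- 12 - 1.64 * 2
  expect_true(test_probe_silencing(expr3, calls, man)$selected)

  # zero unmethylated SD and equal means: 12 <= 12 - 0 holds
  expr4 <- matrix(c(12, 12, 12, 12, 12), 1, 5,
                  dimnames = list("gA", paste0("t", 1:5)))
  expect_true(test_probe_silencing(expr4, calls, man)$selected)

  # fewer than 2 unmethylated samples -> untestable
  calls5 <- matrix(c(TRUE, TRUE, TRUE, TRUE, FALSE), 1, 5,
                   dimnames = list("p1", paste0("t", 1:5)))
  expect_true(is.na(test_probe_silencing(expr, calls5, man)$selected))

  # gene absent from the expression matrix -> untestable, not fatal
  man2 <- man; man2$gene <- "missing"
  expect_true(is.na(test_probe_silencing(expr, calls, man2)$selected))
})

test_that("gene-level aggregation needs strictly more than half the probes", {
  samples <- paste0("t", 1:4)
  mk_probe_results <- function(n_probes) {
    data.frame(probe_id = paste0("p", seq_len(n_probes)), gene = "gA",
               mean_meth_expr = 0, mean_unmeth_expr = 5, sd_unmeth_expr = 1,
               selected = TRUE, stringsAsFactors = FALSE)
  }
  # 3 probes, sample t1 silenced at 2 of them -> silenced (2/3 > 1/2)
  calls <- matrix(FALSE, 3, 4, dimnames = list(paste0("p", 1:3), samples))
  calls[1:2, 1] <- TRUE
  expr <- matrix(10, 1, 4, dimnames = list("gA", samples))
  expr[1, 1] <- 1  # below the unmethylated mean
  out <- call_silenced(expr, calls, mk_probe_results(3))
  expect_true(out$gene_calls["gA", "t1"])

  # 4 probes, silenced at exactly 2 -> 2/4 not > 1/2 -> not silenced
  calls4 <- matrix(FALSE, 4, 4, dimnames = list(paste0("p", 1:4), samples))
  calls4[1:2, 1] <- TRUE
  out4 <- call_silenced(expr, calls4, mk_probe_results(4))
  expect_false(out4$gene_calls["gA", "t1"])

  # single-probe gene inherits the probe call
  calls1 <- matrix(c(TRUE, FALSE, FALSE, FALSE), 1, 4,
                   dimnames = list("p1", samples))
  out1 <- call_silenced(expr, calls1, mk_probe_results(1))
  expect_identical(unname(out1$gene_calls["gA", ]),
                   unname(out1$probe_calls["p1", ]))

  # methylated but expression above the unmethylated mean -> no call
  expr_hi <- matrix(10, 1, 4, dimnames = list("gA", samples))
  outh <- call_silenced(expr_hi, calls1, mk_probe_results(1))
  expect_false(any(outh$gene_calls))
})

test_that("silencing burden equals brute-force column counts", {
  set.seed(3)
  m <- matrix(runif(20) < 0.4, 5, 4,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  b <- silencing_burden(m)
  brute <- sapply(seq_len(ncol(m)), function(j) {
    n <- 0L; for (i in seq_len(nrow(m))) if (m[i, j]) n <- n + 1L; n
  })
  expect_equal(unname(b), brute)
  expect_equal(unname(silencing_burden(m & FALSE)), rep(0L, 4))
})

test_that("pipeline matches the naive loop oracle on seeded instances", {
  for (s in 1:3) {
    cfg <- cohort_config(n_tumor = 40, n_normal = 10, n_genes = 25,
                         planted_silenced_genes = 2, n_prognostic_genes = 2,
                         n_decoy_probes = 8, seed = s)
    b <- generate_cohort(cfg)
    sw <- suppressWarnings(silencing_workflow(b))
    orc <- oracle_silencing(b$manifest, b$normal_betas, b$tumor_betas,
                            b$tumor_log2)
    sel <- sort(sw$probe_results$probe_id[
      !is.na(sw$probe_results$selected) & sw$probe_results$selected])
    expect_identical(sel, orc$selected)
    expect_identical(sw$gene_calls[rownames(orc$gene_calls),
                                   colnames(orc$gene_calls), drop = FALSE],
                     orc$gene_calls)
  }
})

test_that("lowering a methylated sample's expression never removes calls", {
  cfg <- cohort_config(n_tumor = 50, n_normal = 10, n_genes = 30,
                       planted_silenced_genes = 3, n_prognostic_genes = 2,
                       seed = 21)
  b <- generate_cohort(cfg)
  sw0 <- suppressWarnings(silencing_workflow(b))
  # pick a methylated (probe, sample) pair among candidates
  calls <- sw0$candidates$calls
  hit <- which(calls, arr.ind = TRUE)[1, ]
  probe <- rownames(calls)[hit[1]]; samp <- colnames(calls)[hit[2]]
  gene <- b$manifest$gene[b$manifest$probe_id == probe]
  b2 <- b
  b2$tumor_log2[gene, samp] <- b2$tumor_log2[gene, samp] - 5
  sw1 <- suppressWarnings(silencing_workflow(b2))
  # every call the original made for that sample is still present
  before_genes <- rownames(sw0$gene_calls)[sw0$gene_calls[, samp]]
  after_genes <- rownames(sw1$gene_calls)[sw1$gene_calls[, samp]]
  expect_true(all(setdiff(before_genes, gene) %in% after_genes))
  expect_gte(sw1$burden[samp], sw0$burden[samp] - 1)
})
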
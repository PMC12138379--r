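#' Configuration for the synthetic multi-omics cohort generator
#'
#' Bundles and validates every distribution parameter of
#' [generate_cohort()]. Defaults describe a mid-sized tumor/normal cohort
#' with three molecular subtypes, planted promoter-silencing events,
#' subtype-specific binary alterations and a planted prognostic program.
#'
#' @param n_tumor,n_normal Tumor and normal sample counts.
#' @param n_subtypes Number of molecular subtypes (labels C1..Ck assigned
#'   round-robin so groups are balanced).
#' @param n_genes Number of expressed genes with promoter probes.
#' @param probes_per_gene Promoter probes per gene (exercises the
#'   more-than-half probe aggregation of the silencing caller).
#' @param planted_silenced_genes Genes planted as silenced per subtype.
#' @param silencing_fraction Fraction of tumors within the target subtype in
#'   which a planted gene is silenced.
#' @param silencing_effect Expression suppression for silenced pairs, in
#'   units of the gene's own SD on the log2 scale.
#' @param n_mut_features,mut_freq_in,mut_freq_out,mut_background_rate Driver
#'   mutation features planted per subtype, their within/outside-subtype
#'   frequencies, and the background mutation rate for non-planted features.
#' @param n_lesions_per_subtype,lesion_freq_in,lesion_freq_out Copy-number
#'   lesions planted per subtype and their frequencies.
#' @param n_prognostic_genes Number of genes carrying a survival effect.
#' @param prognostic_effect Absolute log-hazard per unit (log2) expression
#'   for planted prognostic genes; signs alternate.
#' @param censoring_rate Target fraction of censored samples.
#' @param n_decoy_probes Probes added to exercise the manifest filters
#'   (SNP-flagged, sex-chromosome, distant-from-TSS, methylated-in-normal).
#' @param seed Integer seed; the whole bundle is deterministic given it.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_tumor = 200, n_normal = 50, n_subtypes = 3,
                          n_genes = 300, probes_per_gene = 3,
                          planted_silenced_genes = 5,
                          silencing_fraction = 0.4, silencing_effect = 3,
                          n_mut_features = 3, mut_freq_in = 0.6,
                          mut_freq_out = 0.05, mut_background_rate = 0.05,
                          n_lesions_per_subtype = 2, lesion_freq_in = 0.6,
                          lesion_freq_out = 0.05,
                          n_prognostic_genes = 5, prognostic_effect = 1,
                          censoring_rate = 0.3, n_decoy_probes = 40,
                          seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_tumor", "n_normal", "n_subtypes", "n_genes",
              "probes_per_gene")
  for (nm in counts) {
    if (cfg[[nm]] <= 0) stop(sprintf("%s must be > 0", nm))
  }
  fracs <- c("silencing_fraction", "mut_freq_in", "mut_freq_out",
             "mut_background_rate", "lesion_freq_in", "lesion_freq_out",
             "censoring_rate")
  for (nm in fracs) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      stop(sprintf("%s must be in [0, 1]", nm))
    }
  }
  if (planted_silenced_genes > 0 && silencing_effect <= 0) {
    stop("silencing_effect must be > 0 when silencing is planted")
  }
  need <- n_subtypes * planted_silenced_genes + n_prognostic_genes
  if (need > n_genes) {
    stop(sprintf("infeasible config: %d planted genes but only %d genes",
                 need, n_genes))
  }
  structure(cfg, class = "cohort_config")
}

# Bimodal beta-value draws: unmethylated probes sit in a low mode
# (Beta(2,18), mean 0.1), methylated ones in a high mode (Beta(12,8),
# mean 0.6), keeping every value inside [0,1].
.rbeta_low <- function(n) stats::rbeta(n, 2, 18)
.rbeta_high <- function(n) stats::rbeta(n, 12, 8)

#' Generate a synthetic multi-omics cohort with planted ground truth
#'
#' Emulates the data model of a paired methylation/expression tumor cohort:
#' 450k-style promoter beta-values with a bimodal methylated/unmethylated
#' structure coupled to expression suppression in planted genes,
#' subtype-specific binary mutation and copy-number alterations, and
#' exponential proportional-hazards survival driven by planted prognostic
#' genes. Every planted item is reported in `truth` so downstream callers
#' can be scored for sensitivity and false discoveries.
#'
#' @param config A [cohort_config()].
#' @return A list (`cohort_bundle`) with elements `tumor_expression` (TPM,
#'   gene x tumor), `tumor_log2` (log2(TPM+1), the scale on which effects are
#'   planted), `tumor_betas`, `normal_betas`, `manifest`, `mutations`
#'   (binary), `lesions` (discrete calls + metadata), `survival` (time in
#'   days, event, age, stage), and `truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  k <- config$n_subtypes
  tumors <- sprintf("T%03d", seq_len(config$n_tumor))
  normals <- sprintf("N%03d", seq_len(config$n_normal))
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  subtype <- stats::setNames(
    sprintf("C%d", rep_len(seq_len(k), config$n_tumor)), tumors)

  ## expression on the log2(TPM+1) scale
  mu <- stats::setNames(stats::rnorm(config$n_genes, 5, 1.5), genes)
  sdg <- stats::setNames(stats::runif(config$n_genes, 1.1, 1.8), genes)
  log2e <- matrix(stats::rnorm(config$n_genes * config$n_tumor),
                  config$n_genes, config$n_tumor,
                  dimnames = list(genes, tumors))
  log2e <- mu + sdg * log2e

  ## planted silenced genes, disjoint across subtypes
  n_sil <- config$planted_silenced_genes
  sil_genes <- if (n_sil > 0) {
    split(genes[seq_len(k * n_sil)], rep(seq_len(k), each = n_sil))
  } else list()
  silenced_pairs <- list()
  for (s in seq_along(sil_genes)) {
    in_sub <- tumors[subtype == sprintf("C%d", s)]
    n_pick <- round(config$silencing_fraction * length(in_sub))
    picked <- sample(in_sub, n_pick)
    for (g in sil_genes[[s]]) {
      log2e[g, picked] <- log2e[g, picked] -
        config$silencing_effect * sdg[[g]]
      silenced_pairs[[length(silenced_pairs) + 1L]] <-
        data.frame(gene = g, sample = picked, subtype = sprintf("C%d", s),
                   stringsAsFactors = FALSE)
    }
  }
  silenced_pairs <- if (length(silenced_pairs)) {
    do.call(rbind, silenced_pairs)
  } else {
    data.frame(gene = character(), sample = character(),
               subtype = character(), stringsAsFactors = FALSE)
  }
  log2e[log2e < 0] <- 0
  tpm <- 2^log2e - 1

  ## probe manifest: promoter probes per gene plus filter-exercising decoys
  probe_gene <- rep(genes, each = config$probes_per_gene)
  probes <- sprintf("cg%05d", seq_along(probe_gene))
  manifest <- data.frame(
    probe_id = probes,
    chromosome = as.character(rep_len(1:22, length(probes))),
    tss_distance = round(stats::runif(length(probes), -1500, 1500)),
    gene = probe_gene,
    snp_associated = FALSE,
    stringsAsFactors = FALSE
  )
  nd <- config$n_decoy_probes
  if (nd > 0) {
    decoy <- data.frame(
      probe_id = sprintf("cgD%04d", seq_len(nd)),
      chromosome = rep_len(c("X", "Y", "7", "12"), nd),
      tss_distance = rep_len(c(200L, -400L, 5000L, 300L), nd),
      gene = sample(genes, nd, replace = TRUE),
      snp_associated = rep_len(c(FALSE, FALSE, FALSE, TRUE), nd),
      stringsAsFactors = FALSE
    )
    manifest <- rbind(manifest, decoy)
  }

  ## beta values: low mode everywhere, high mode for silenced (gene, sample)
  ## promoter probes; a stripe of decoys is methylated in normals
  all_probes <- manifest$probe_id
  tb <- matrix(.rbeta_low(length(all_probes) * config$n_tumor),
               length(all_probes), config$n_tumor,
               dimnames = list(all_probes, tumors))
  if (nrow(silenced_pairs) > 0) {
    for (i in seq_len(nrow(silenced_pairs))) {
      pr <- manifest$probe_id[manifest$gene == silenced_pairs$gene[i] &
                              !manifest$snp_associated &
                              abs(manifest$tss_distance) <= 1500 &
                              !(manifest$chromosome %in% c("X", "Y"))]
      tb[pr, silenced_pairs$sample[i]] <- .rbeta_high(length(pr))
    }
  }
  nb <- matrix(.rbeta_low(length(all_probes) * config$n_normal),
               length(all_probes), config$n_normal,
               dimnames = list(all_probes, normals))
  if (nd > 3) {
    # every 4th decoy probe is constitutively methylated in normal tissue
    hot <- manifest$probe_id[grepl("^cgD", manifest$probe_id)]
    hot <- hot[seq(3, length(hot), by = 4)]
    nb[hot, ] <- .rbeta_high(length(hot) * config$n_normal)
    tb[hot, ] <- .rbeta_high(length(hot) * config$n_tumor)
  }

  ## subtype-specific binary mutations
  mut_features <- character(); mut_truth <- NULL
  n_mut <- config$n_mut_features
  mut_planted <- if (n_mut > 0) {
    sprintf("MT%d_%d", rep(seq_len(k), each = n_mut), seq_len(n_mut))
  } else character()
  mut_bg <- sprintf("MBG%02d", seq_len(10))
  mut_features <- c(mut_planted, mut_bg)
  muts <- matrix(0, length(mut_features), config$n_tumor,
                 dimnames = list(mut_features, tumors))
  for (f in mut_planted) {
    s <- as.integer(sub("^MT(\\d+)_.*", "\\1", f))
    in_sub <- subtype == sprintf("C%d", s)
    muts[f, in_sub] <- stats::rbinom(sum(in_sub), 1, config$mut_freq_in)
    muts[f, !in_sub] <- stats::rbinom(sum(!in_sub), 1, config$mut_freq_out)
  }
  for (f in mut_bg) {
    muts[f, ] <- stats::rbinom(config$n_tumor, 1, config$mut_background_rate)
  }
  mut_truth <- data.frame(
    feature = mut_planted,
    subtype = sprintf("C%d", as.integer(sub("^MT(\\d+)_.*", "\\1",
                                            mut_planted))),
    kind = rep("mutation", length(mut_planted)), stringsAsFactors = FALSE)

  ## GISTIC-style lesions with discrete calls (0 none, 1/2 altered)
  nl <- config$n_lesions_per_subtype
  les_planted <- if (nl > 0) {
    unlist(lapply(seq_len(k), function(s) {
      vapply(seq_len(nl), function(j) {
        typ <- if (j %% 2 == 1) "Amplification" else "Deletion"
        sprintf("%s Peak %d (C%d)", typ, j, s)
      }, "")
    }))
  } else character()
  les_bg <- sprintf("Amplification Peak B%d", 1:4)
  les_all <- c(les_planted, les_bg)
  lesions <- matrix(0, length(les_all), config$n_tumor,
                    dimnames = list(les_all, tumors))
  les_sub <- c(rep(seq_len(k), each = nl), rep(NA_integer_, length(les_bg)))
  for (i in seq_along(les_all)) {
    p_in <- if (is.na(les_sub[i])) 0.1 else config$lesion_freq_in
    p_out <- if (is.na(les_sub[i])) 0.1 else config$lesion_freq_out
    in_sub <- if (is.na(les_sub[i])) rep(FALSE, config$n_tumor)
              else subtype == sprintf("C%d", les_sub[i])
    call1 <- stats::rbinom(config$n_tumor, 1, ifelse(in_sub, p_in, p_out))
    deep <- stats::rbinom(config$n_tumor, 1, 0.3)
    lesions[i, ] <- call1 * (1 + deep)
  }
  lesion_meta <- data.frame(
    lesion = les_all,
    type = ifelse(grepl("Amplification", les_all), "amp", "del"),
    level = rep_len(c("focal", "arm"), length(les_all)),
    gene_count = sample(5:80, length(les_all), replace = TRUE),
    stringsAsFactors = FALSE)
  les_truth <- data.frame(
    feature = les_planted,
    subtype = sprintf("C%d", les_sub[seq_along(les_planted)]),
    kind = rep("cnv", length(les_planted)), stringsAsFactors = FALSE)

  ## survival: exponential baseline hazard, planted log-linear effects
  npg <- config$n_prognostic_genes
  prog_genes <- if (npg > 0) {
    genes[seq(k * n_sil + 1, k * n_sil + npg)]
  } else character()
  prog_coef <- stats::setNames(
    config$prognostic_effect * rep_len(c(1, -1), npg), prog_genes)
  lp <- if (npg > 0) {
    drop(crossprod(log2e[prog_genes, , drop = FALSE] - mu[prog_genes],
                   prog_coef))
  } else rep(0, config$n_tumor)
  lambda0 <- 1 / 1000  # baseline hazard per day; median ~ 2 years at lp = 0
  t_event <- stats::rexp(config$n_tumor, lambda0 * exp(lp))
  cens_rate <- lambda0 * config$censoring_rate /
    max(1 - config$censoring_rate, 1e-8)
  t_cens <- if (config$censoring_rate > 0) {
    stats::rexp(config$n_tumor, cens_rate)
  } else rep(Inf, config$n_tumor)
  surv <- data.frame(
    sample = tumors,
    time = pmax(pmin(t_event, t_cens), 1e-3),
    event = as.integer(t_event <= t_cens),
    age = round(stats::rnorm(config$n_tumor, 60, 10)),
    stage = sample(c("I", "II", "III", "IV"), config$n_tumor,
                   replace = TRUE, prob = c(0.35, 0.3, 0.25, 0.1)),
    stringsAsFactors = FALSE)

  truth <- list(
    subtype_labels = subtype,
    silenced_pairs = silenced_pairs,
    silenced_genes = if (length(sil_genes)) {
      stats::setNames(unlist(sil_genes, use.names = FALSE),
                      rep(sprintf("C%d", seq_len(k)), each = n_sil))
    } else character(),
    subtype_specific_features = rbind(mut_truth, les_truth),
    prognostic_genes = prog_coef
  )
  structure(list(
    tumor_expression = tpm, tumor_log2 = log2e,
    tumor_betas = tb, normal_betas = nb, manifest = manifest,
    mutations = muts,
    lesions = list(values = lesions, meta = lesion_meta),
    survival = surv, truth = truth, config = config
  ), class = "cohort_bundle")
}

#' Generate a synthetic cell-line drug panel plus a matched patient cohort
#'
#' Emulates a CCLE/CTRP-style screen: cell-line expression profiles, a
#' compound x cell-line AUC matrix where planted-sensitive compounds follow
#' AUC = a - b * (program expression) + noise with b > 0 (lower AUC means
#' greater sensitivity), missing AUC entries at random, and a patient cohort
#' whose risk scores correlate with the planted expression program at a
#' chosen strength.
#'
#' Expression in both panels is driven by several latent gene programs
#' (modules of co-expressed genes), only the first of which carries the
#' drug-sensitivity and risk associations; the background programs mimic
#' the multi-axis covariance of real expression panels, without which any
#' noise-fit response model would spuriously align with the single planted
#' axis.
#'
#' @param n_ccl,n_compounds,n_genes Panel dimensions.
#' @param program_size Genes per program.
#' @param n_programs Total latent programs (>= 1; the first is the planted
#'   sensitivity/risk program, the rest are background).
#' @param n_sensitive Compounds coupled to the program.
#' @param assoc_strength Slope b of the planted AUC/program relation.
#' @param noise_sd Residual SD of planted-compound AUCs.
#' @param missingness Per-entry missing probability in [0, 1).
#' @param add_high_missing_compound Add one decoy compound with ~30% missing
#'   AUCs to exercise the missingness filter.
#' @param n_patients Patients in the matched cohort.
#' @param patient_r Target correlation between patient risk score and
#'   program expression.
#' @param seed Integer seed.
#' @return A list with `ccl_expression`, `auc`, `patient_expression`,
#'   `risk_scores` and `truth` (sensitive/null compounds, program genes).
#' @export
generate_ccl_panel <- function(n_ccl = 100, n_compounds = 15,
                               n_genes = 1000,
                               program_size = 15, n_programs = 8,
                               n_sensitive = 2,
                               assoc_strength = 1, noise_sd = 0.3,
                               missingness = 0.1,
                               add_high_missing_compound = TRUE,
                               n_patients = 200, patient_r = 0.6,
                               seed = 1L) {
  if (missingness >= 1) stop("missingness must be < 1")
  if (missingness < 0) stop("missingness must be >= 0")
  if (n_programs < 1) stop("n_programs must be >= 1")
  if (n_programs * program_size > n_genes) {
    stop("programs do not fit into n_genes")
  }
  set.seed(seed)
  ccls <- sprintf("CCL%03d", seq_len(n_ccl))
  genes <- sprintf("G%04d", seq_len(n_genes))
  compounds <- sprintf("CPD%02d", seq_len(n_compounds))
  prog_genes <- lapply(seq_len(n_programs), function(m) {
    genes[seq((m - 1) * program_size + 1, m * program_size)]
  })
  program <- prog_genes[[1]]

  plant_programs <- function(expr, latent) {
    for (m in seq_len(n_programs)) {
      expr[prog_genes[[m]], ] <- 5 +
        rep(latent[, m], each = program_size) +
        stats::rnorm(program_size * ncol(expr), 0, 0.5)
    }
    expr
  }
  ccl_latent <- matrix(stats::rnorm(n_ccl * n_programs), n_ccl, n_programs)
  ccl_prog <- ccl_latent[, 1]                # planted sensitivity program
  expr <- matrix(stats::rnorm(n_genes * n_ccl, 5, 1), n_genes, n_ccl,
                 dimnames = list(genes, ccls))
  expr <- plant_programs(expr, ccl_latent)

  sens <- compounds[seq_len(min(n_sensitive, n_compounds))]
  auc <- matrix(NA_real_, n_compounds, n_ccl,
                dimnames = list(compounds, ccls))
  for (cp in compounds) {
    a <- stats::rnorm(1, 8, 0.5)
    if (cp %in% sens) {
      auc[cp, ] <- a - assoc_strength * ccl_prog +
        stats::rnorm(n_ccl, 0, noise_sd)
    } else {
      auc[cp, ] <- a + stats::rnorm(n_ccl, 0, 0.5)
    }
  }
  if (missingness > 0) {
    miss <- matrix(stats::runif(length(auc)) < missingness, nrow(auc))
    auc[miss] <- NA_real_
  }
  if (add_high_missing_compound) {
    decoy_auc <- stats::rnorm(n_ccl, 8, 0.5)
    decoy_auc[sample(n_ccl, ceiling(0.3 * n_ccl))] <- NA_real_
    auc <- rbind(auc, CPD_HIMISS = decoy_auc)
  }

  pat <- sprintf("P%03d", seq_len(n_patients))
  pat_latent <- matrix(stats::rnorm(n_patients * n_programs),
                       n_patients, n_programs)
  pat_prog <- pat_latent[, 1]
  pexpr <- matrix(stats::rnorm(n_genes * n_patients, 5, 1),
                  n_genes, n_patients, dimnames = list(genes, pat))
  pexpr <- plant_programs(pexpr, pat_latent)
  risk <- stats::setNames(
    patient_r * pat_prog +
      sqrt(max(0, 1 - patient_r^2)) * stats::rnorm(n_patients), pat)

  list(
    ccl_expression = expr, auc = auc,
    patient_expression = pexpr, risk_scores = risk,
    truth = list(sensitive_compounds = sens,
                 null_compounds = setdiff(compounds, sens),
                 high_missing_compound =
                   if (add_high_missing_compound) "CPD_HIMISS" else NULL,
                 program_genes = program, assoc_strength = assoc_strength,
                 patient_program = pat_prog)
  )
}

#' Generate a synthetic subpopulation x tissue cell-count table
#'
#' Multinomial counts with planted tissue preferences: within each tissue,
#' cells are allocated across subpopulations with probabilities proportional
#' to a baseline share times a preference multiplier.
#'
#' @param n_cells Total cells across the table (> 0).
#' @param subpops,tissues Row and column labels.
#' @param multipliers Preference matrix (subpop x tissue), default all 1
#'   (no enrichment). Values must be > 0.
#' @param seed Integer seed.
#' @return Integer count matrix, subpopulation x tissue.
#' @export
generate_cell_counts <- function(n_cells = 2000,
                                 subpops = paste0("Mac_", c("SPP1", "C1QC",
                                                            "FCN1", "MT1G")),
                                 tissues = c("normal", "adjacent", "tumor"),
                                 multipliers = NULL, seed = 1L) {
  if (n_cells <= 0) stop("n_cells must be > 0")
  set.seed(seed)
  if (is.null(multipliers)) {
    multipliers <- matrix(1, length(subpops), length(tissues),
                          dimnames = list(subpops, tissues))
  }
  stopifnot(nrow(multipliers) == length(subpops),
            ncol(multipliers) == length(tissues))
  if (any(multipliers <= 0)) stop("multipliers must be > 0")
  per_tissue <- stats::rmultinom(1, n_cells,
                                 rep(1 / length(tissues), length(tissues)))
  counts <- matrix(0L, length(subpops), length(tissues),
                   dimnames = list(subpops, tissues))
  for (j in seq_along(tissues)) {
    w <- multipliers[, j] / sum(multipliers[, j])
    counts[, j] <- stats::rmultinom(1, per_tissue[j], w)[, 1]
  }
  counts
}
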
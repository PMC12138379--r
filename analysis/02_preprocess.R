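#!/usr/bin/env Rscript
# Apply the per-layer feature rules: mRNA missingness + log2 + SD filter,
# methylation missingness/SNP/sex filters + KNN imputation + top-MAD
# selection, and lesion-call binarization.

source(file.path("analysis", "00_config.R"))

cdir <- file.path("results", "cohort")
expr <- read_matrix_tsv(file.path(cdir, "tumor_expression_tpm.tsv"))
betas <- read_matrix_tsv(file.path(cdir, "tumor_betas.tsv"))
manifest <- utils::read.delim(file.path(cdir, "manifest.tsv"))
lesions <- read_gistic_lesions(file.path(cdir, "lesions.tsv"))

odir <- results_dir("preprocess")

expr_f <- filter_expression_features(expr)
write_matrix_tsv(expr_f, file.path(odir, "expression_log2_filtered.tsv"),
                 id_col = "gene")
cat(sprintf("mRNA: %d of %d genes pass the SD >= 1.0 filter (log2 scale)\n",
            nrow(expr_f), nrow(expr)))

meth_f <- suppressWarnings(
  prepare_methylation_features(betas, manifest, k_top = 1000))
write_matrix_tsv(meth_f, file.path(odir, "methylation_top_mad.tsv"),
                 id_col = "probe")
cat(sprintf("methylation: kept %d probes (from %d) after filters + MAD ranking\n",
            nrow(meth_f), nrow(betas)))

les_bin <- binarize_lesions(lesions)
write_gistic_lesions(les_bin, file.path(odir, "lesions_binary.tsv"))
cat(sprintf("lesions: binarized %d lesions, %.1f%% altered entries\n",
            nrow(les_bin$values), 100 * mean(les_bin$values > 0)))
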
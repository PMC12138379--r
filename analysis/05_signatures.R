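#!/usr/bin/env Rscript
# Single-sample gene-set activity: ssGSEA scores of the synthetic gene
# modules in every tumor, summarized per subtype.

source(file.path("analysis", "00_config.R"))

bundle <- generate_cohort(study_config())
gmt <- system.file("extdata", "synthetic_hallmark_mini.gmt",
                   package = "hccmultiomics")
sets <- read_gmt(gmt)

scores <- ssgsea_scores(bundle$tumor_log2, sets)
norm <- normalize_scores(scores)

odir <- results_dir("signatures")
write_matrix_tsv(scores, file.path(odir, "ssgsea_scores.tsv"),
                 id_col = "gene_set")
write_matrix_tsv(norm, file.path(odir, "ssgsea_scores_normalized.tsv"),
                 id_col = "gene_set")

labels <- bundle$truth$subtype_labels
per_subtype <- sapply(sort(unique(labels)), function(st) {
  rowMeans(scores[, names(labels)[labels == st], drop = FALSE])
})
write_matrix_tsv(per_subtype, file.path(odir, "ssgsea_subtype_means.tsv"),
                 id_col = "gene_set")

cat(sprintf("scored %d gene sets x %d samples\n", nrow(scores),
            ncol(scores)))
cat("subtype mean scores (first sets):\n")
print(round(utils::head(per_subtype, 4), 2))
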
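#!/usr/bin/env Rscript
# Generate the synthetic multi-omics cohort, the cell-line drug panel and
# the cell-count table, and write every layer as TSV under results/cohort.

source(file.path("analysis", "00_config.R"))

cfg <- study_config()
bundle <- generate_cohort(cfg)
dir <- results_dir("cohort")
write_cohort_bundle(bundle, dir)

panel <- generate_ccl_panel(seed = run_seed)
pdir <- results_dir("ccl_panel")
write_matrix_tsv(panel$ccl_expression, file.path(pdir, "ccl_expression.tsv"),
                 id_col = "gene")
write_matrix_tsv(panel$auc, file.path(pdir, "auc.tsv"), id_col = "compound")
write_matrix_tsv(panel$patient_expression,
                 file.path(pdir, "patient_expression.tsv"), id_col = "gene")
write_df(data.frame(sample = names(panel$risk_scores),
                    risk_score = unname(panel$risk_scores)),
         file.path(pdir, "risk_scores.tsv"))

counts <- generate_cell_counts(seed = run_seed)
write_matrix_tsv(counts * 1.0, file.path(results_dir("cells"),
                                         "cell_counts.tsv"),
                 id_col = "subpopulation")

cat(sprintf("cohort: %d tumors / %d normals, %d genes, %d probes\n",
            ncol(bundle$tumor_betas), ncol(bundle$normal_betas),
            nrow(bundle$tumor_expression), nrow(bundle$tumor_betas)))
cat(sprintf("planted: %d silenced genes, %d prognostic genes, %d subtype-specific features\n",
            length(bundle$truth$silenced_genes),
            length(bundle$truth$prognostic_genes),
            nrow(bundle$truth$subtype_specific_features)))
cat(sprintf("ccl panel: %d compounds x %d cell lines, %d patients\n",
            nrow(panel$auc), ncol(panel$auc),
            ncol(panel$patient_expression)))
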
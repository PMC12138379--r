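#!/usr/bin/env Rscript
# Compound prioritization: AUC missingness filter + KNN imputation, ridge
# expression -> response models on the cell-line panel, prediction into
# the patient cohort, and the high-vs-low risk differential + Spearman
# (r < -0.35) candidate filter.

source(file.path("analysis", "00_config.R"))

panel <- generate_ccl_panel(seed = run_seed)
odir <- results_dir("drug_screen")

auc <- filter_and_impute_auc(panel$auc)
cat(sprintf("compounds: %d of %d pass the 20%% missingness filter\n",
            nrow(auc), nrow(panel$auc)))

pred <- predict_drug_response(panel$ccl_expression, auc,
                              panel$patient_expression)
write_matrix_tsv(pred, file.path(odir, "predicted_auc.tsv"),
                 id_col = "compound")

res <- prioritize_compounds(pred, panel$risk_scores)
write_df(res, file.path(odir, "candidates.tsv"))

cand <- res$compound[res$candidate]
cat(sprintf("candidates (lower predicted AUC in high-risk, r < -0.35): %s\n",
            paste(cand, collapse = ", ")))
cat(sprintf("planted-sensitive compounds recovered: %d/%d; false candidates: %d\n",
            sum(panel$truth$sensitive_compounds %in% cand),
            length(panel$truth$sensitive_compounds),
            sum(!(cand %in% panel$truth$sensitive_compounds))))
print(utils::head(res[, c("compound", "spearman_r", "diff_p", "candidate")],
                  5), row.names = FALSE)
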
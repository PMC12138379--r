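# Shared configuration for the analysis drivers. Each numbered script can
# be run as  Rscript analysis/NN_*.R [--seed <int>]  from the repo root;
# outputs land under results/.

library(hccmultiomics)

.args <- commandArgs(trailingOnly = TRUE)
.si <- which(.args == "--seed")
run_seed <- if (length(.si) == 1 && .si < length(.args)) {
  as.integer(.args[.si + 1])
} else 1L

results_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

study_config <- function(seed = run_seed) cohort_config(seed = seed)

write_df <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
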
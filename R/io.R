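#' Read gene sets from a GMT file
#'
#' Parses the standard tab-separated GMT format: one set per line, fields are
#' set name, description, then member genes. Duplicate genes within a line are
#' collapsed.
#'
#' @param path Path to a GMT file.
#' @return A named list of gene sets; each element is a list with `name`,
#'   `description` and `genes` (a character vector of unique gene symbols).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("line %d: fewer than 3 fields", i))
    }
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    sets[[i]] <- list(name = fields[[1]], description = fields[[2]],
                      genes = genes)
  }
  stats::setNames(sets, vapply(sets, `[[`, "", "name"))
}

#' Write gene sets to a GMT file
#'
#' @param sets A list of gene sets as returned by [read_gmt()].
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$description, s$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a labeled numeric matrix as TSV
#'
#' Features are rows, samples are columns; the first column holds row ids and
#' the header row holds column ids. Missing entries are written as `NA`.
#' Values are serialized with 17 significant digits so that a write/read
#' round trip reproduces doubles bit-exactly.
#'
#' @param mat Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_col Name for the row-id column (default `"feature"`).
#' @export
write_matrix_tsv <- function(mat, path, id_col = "feature") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  header <- paste(c(id_col, colnames(mat)), collapse = "\t")
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], fmt(mat[i, ])), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a labeled numeric matrix from TSV
#'
#' Inverse of [write_matrix_tsv()].
#'
#' @param path Path to a TSV written by [write_matrix_tsv()].
#' @return Numeric matrix with row and column names.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(df[[1]])
  mat
}

#' Read a GISTIC-style lesion table
#'
#' Expects a TSV whose first column is the lesion descriptor (its text must
#' contain "Amplification" or "Deletion"), optionally followed by `Level`
#' (focal/arm) and `Gene.Count` metadata columns, then one numeric column per
#' sample. The values are retained verbatim: continuous copy-number for
#' clustering input or discrete calls for enrichment input, depending on which
#' file dialect is supplied.
#'
#' @param path Path to the lesion TSV.
#' @return A list with `values` (lesion x sample numeric matrix) and `meta`
#'   (data.frame with `lesion`, `type` in amp/del, `level` in focal/arm, and
#'   `gene_count`).
#' @export
read_gistic_lesions <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- intersect(c("Level", "Gene.Count"), colnames(df))
  sample_cols <- setdiff(colnames(df)[-1], meta_cols)
  if (length(sample_cols) == 0L) stop("no sample columns found")
  descriptor <- as.character(df[[1]])
  type <- ifelse(grepl("Amplification", descriptor), "amp",
                 ifelse(grepl("Deletion", descriptor), "del", NA_character_))
  if (anyNA(type)) {
    stop(sprintf("unknown lesion type in descriptor '%s'",
                 descriptor[which(is.na(type))[1]]))
  }
  values <- matrix(NA_real_, nrow(df), length(sample_cols),
                   dimnames = list(descriptor, sample_cols))
  for (j in seq_along(sample_cols)) {
    col <- df[[sample_cols[j]]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col) & col != "NA")
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric value in row '%s', column '%s'",
                   descriptor[bad[1]], sample_cols[j]))
    }
    values[, j] <- num
  }
  meta <- data.frame(
    lesion = descriptor,
    type = type,
    level = if ("Level" %in% meta_cols) as.character(df$Level) else "focal",
    gene_count = if ("Gene.Count" %in% meta_cols) as.integer(df$Gene.Count)
                 else NA_integer_,
    stringsAsFactors = FALSE
  )
  list(values = values, meta = meta)
}

#' Write a lesion table in the dialect read by [read_gistic_lesions()]
#'
#' @param lesions A list with `values` and `meta` as returned by
#'   [read_gistic_lesions()].
#' @param path Output path.
#' @export
write_gistic_lesions <- function(lesions, path) {
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  header <- paste(c("Unique.Name", "Level", "Gene.Count",
                    colnames(lesions$values)), collapse = "\t")
  body <- vapply(seq_len(nrow(lesions$values)), function(i) {
    paste(c(lesions$meta$lesion[i], lesions$meta$level[i],
            lesions$meta$gene_count[i], fmt(lesions$values[i, ])),
          collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Build a binary gene x sample mutation matrix from MAF-lite records
#'
#' MAF-lite is a three-column TSV (`gene`, `sample`, `classification`); the
#' full MAF format carries far more than the pipeline consumes. An entry is 1
#' iff at least one retained record exists for the (gene, sample) pair.
#'
#' @param path Path to the MAF-lite TSV (with header).
#' @param classifications Optional character vector; when given, only records
#'   whose classification is in this set are retained. Default keeps all
#'   records present in the file.
#' @return Binary numeric matrix, genes x samples.
#' @export
read_maf_lite <- function(path, classifications = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  colnames(df) <- tolower(colnames(df))
  stopifnot(all(c("gene", "sample") %in% colnames(df)))
  if (!is.null(classifications) && "classification" %in% colnames(df)) {
    df <- df[df$classification %in% classifications, , drop = FALSE]
  }
  if (nrow(df) == 0L) {
    warning("no mutation records retained; returning empty matrix")
    return(matrix(0, 0, 0))
  }
  genes <- sort(unique(df$gene))
  samples <- sort(unique(df$sample))
  mat <- matrix(0, length(genes), length(samples),
                dimnames = list(genes, samples))
  mat[cbind(match(df$gene, genes), match(df$sample, samples))] <- 1
  mat
}

#' Write a survival table as TSV
#'
#' @param surv Data frame with columns `sample`, `time`, `event` and optional
#'   covariates.
#' @param path Output path.
#' @export
write_survival_tsv <- function(surv, path) {
  utils::write.table(surv, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a survival table from TSV
#'
#' @param path Path to a TSV with `sample`, `time` and `event` columns.
#' @return Data frame; `time` numeric, `event` integer in {0,1}.
#' @export
read_survival_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "time", "event") %in% colnames(df)))
  df$time <- as.numeric(df$time)
  df$event <- as.integer(df$event)
  df
}

#' Write a generated cohort bundle as plain-text TSV files
#'
#' Serializes every layer of a [generate_cohort()] bundle (expression,
#' beta-values, manifest, mutations, lesions, survival) plus the planted
#' ground truth into a directory of TSVs. Output is deterministic: the same
#' bundle always produces byte-identical files.
#'
#' @param bundle A `cohort_bundle`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_matrix_tsv(bundle$tumor_expression, p("tumor_expression_tpm.tsv"),
                   id_col = "gene")
  write_matrix_tsv(bundle$tumor_log2, p("tumor_expression_log2.tsv"),
                   id_col = "gene")
  write_matrix_tsv(bundle$tumor_betas, p("tumor_betas.tsv"), id_col = "probe")
  write_matrix_tsv(bundle$normal_betas, p("normal_betas.tsv"),
                   id_col = "probe")
  write_matrix_tsv(bundle$mutations, p("mutations.tsv"), id_col = "gene")
  write_gistic_lesions(bundle$lesions, p("lesions.tsv"))
  utils::write.table(bundle$manifest, p("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_survival_tsv(bundle$survival, p("survival.tsv"))
  labels <- data.frame(sample = names(bundle$truth$subtype_labels),
                       subtype = unname(bundle$truth$subtype_labels))
  utils::write.table(labels, p("subtype_labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$truth$silenced_pairs, p("truth_silenced_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  prog <- data.frame(gene = names(bundle$truth$prognostic_genes),
                     coefficient = unname(bundle$truth$prognostic_genes))
  utils::write.table(prog, p("truth_prognostic_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
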
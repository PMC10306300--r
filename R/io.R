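# Plain-text I/O for the standard pipeline inputs: TSV matrices with a
# one-line header of sample IDs, metadata/annotation tables, and a JSON
# truth file for synthetic cohorts.

#' Write or read a feature-by-sample matrix as TSV
#'
#' @param mat Numeric matrix with feature row names and sample column
#'   names.
#' @param path File path.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(feature = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a synthetic cohort to a directory of pipeline inputs
#'
#' Writes `expression.tsv`, `gene_annotation.tsv`, `proteomics.tsv`,
#' `immunoassay.tsv` (wells, with sidecar `immunoassay_flags.tsv` and
#' plate/sample columns in `immunoassay_wells.tsv`), `metabolites.tsv`,
#' `cell_frequencies.tsv`, `metadata.tsv` and `truth.json`.
#'
#' @param cohort An `ifn_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_matrix_tsv(cohort$expression, fp("expression.tsv"))
  utils::write.table(cohort$gene_info, fp("gene_annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix_tsv(cohort$proteomics$values, fp("proteomics.tsv"))
  write_matrix_tsv(cohort$immunoassay$values, fp("immunoassay.tsv"))
  write_matrix_tsv_chr(cohort$immunoassay$flags, fp("immunoassay_flags.tsv"))
  utils::write.table(
    data.frame(well = colnames(cohort$immunoassay$values),
               sample_id = cohort$immunoassay$sample_id,
               plate = cohort$immunoassay$plate),
    fp("immunoassay_wells.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix_tsv(cohort$metabolites$values, fp("metabolites.tsv"))
  write_matrix_tsv(cohort$cells, fp("cell_frequencies.tsv"))
  utils::write.table(cohort$metadata, fp("metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(latent = cohort$truth$latent,
         planted_isgs = cohort$truth$planted_isgs,
         weak_isgs = cohort$truth$weak_isgs,
         chr21_isgs = cohort$truth$chr21_isgs),
    fp("truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

write_matrix_tsv_chr <- function(mat, path) {
  df <- data.frame(feature = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
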
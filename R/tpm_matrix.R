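#' TPM abundance matrices
#'
#' A `tpm_matrix` is a gene x sample matrix of transcripts-per-million
#' abundances (>= 0). Gene ids may carry the `.L`/`.S` suffixes used for the
#' homeologous gene copies of allotetraploid genomes such as
#' \emph{Xenopus laevis}.
#'
#' @param values numeric matrix, genes in rows.
#' @param gene_ids,sample_ids optional dimension names (taken from `values`
#'   when absent).
#' @return a numeric matrix of class `tpm_matrix`.
#' @export
tpm_matrix <- function(values, gene_ids = rownames(values),
                       sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  rownames(values) <- gene_ids
  colnames(values) <- sample_ids
  assert_gene_sample_matrix(values, "TPM matrix")
  if (any(values < 0)) abort("TPM values must be >= 0", "domain_error")
  structure(values, class = c("tpm_matrix", "matrix", "array"))
}

#' Read a TPM matrix from CSV/TSV
#'
#' First column holds gene ids; remaining columns are numeric, one per
#' sample (developmental stage). Gene order is preserved.
#'
#' @param path path to the file.
#' @param dialect `"comma"` (default) or `"tab"`.
#' @return a [tpm_matrix].
#' @export
read_tpm_matrix <- function(path, dialect = c("comma", "tab")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path), "format_error")
  raw <- utils::read.table(path, header = TRUE, sep = if (dialect == "comma") "," else "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) abort("TPM file needs a gene id column plus sample columns", "format_error")
  genes <- as.character(raw[[1]])
  if (anyDuplicated(genes))
    abort(paste0("duplicated gene id(s): ",
                 paste(unique(genes[duplicated(genes)]), collapse = ", ")),
          "integrity_error")
  vals <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  if (any(!is.finite(vals))) abort("non-numeric TPM cell", "format_error")
  tpm_matrix(vals, gene_ids = genes)
}

#' Write a TPM matrix to CSV/TSV
#'
#' @param x a [tpm_matrix].
#' @inheritParams read_tpm_matrix
#' @return `path`, invisibly.
#' @export
write_tpm_matrix <- function(x, path, dialect = c("comma", "tab")) {
  dialect <- match.arg(dialect)
  df <- data.frame(gene = rownames(x), as.data.frame(unclass(x), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = if (dialect == "comma") "," else "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.tpm_matrix <- function(x, ...) {
  cat(sprintf("TPM matrix: %d genes x %d samples\n", nrow(x), ncol(x)))
  utils::str(unclass(x))
  invisible(x)
}
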
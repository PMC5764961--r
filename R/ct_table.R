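#' Long-format Ct tables
#'
#' A `ct_table` is the canonical container for RT-qPCR measurements: one row
#' per well, with columns `sample_id`, `group` (stage or treatment label),
#' `gene`, `replicate` (technical replicate index, >= 1) and `ct` (cycle
#' threshold, cycles). Every sample belongs to exactly one group, and
#' `(sample_id, gene, replicate)` is unique.
#'
#' @param data a data.frame with the five columns above (case-insensitive
#'   names are normalised).
#' @param metadata optional named list of free-form metadata (plate, date...).
#' @return a data.frame of class `ct_table`.
#' @examples
#' ct <- ct_table(data.frame(
#'   sample_id = c("s1", "s1"), group = "NF10",
#'   gene = c("odc1.L", "eef1a1.S"), replicate = 1L, ct = c(21.2, 18.4)))
#' @export
ct_table <- function(data, metadata = list()) {
  names(data) <- tolower(names(data))
  required <- c("sample_id", "group", "gene", "replicate", "ct")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    abort(paste0("Ct table is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")), "format_error")
  data <- data[required]
  data$sample_id <- as.character(data$sample_id)
  data$group <- as.character(data$group)
  data$gene <- as.character(data$gene)
  data$replicate <- as.integer(data$replicate)
  data$ct <- as.numeric(data$ct)
  if (any(!is.finite(data$ct)) || any(data$ct <= 0))
    abort("all Ct values must be finite and > 0", "domain_error")
  if (any(data$replicate < 1L))
    abort("replicate indices must be >= 1", "domain_error")
  key <- paste(data$sample_id, data$gene, data$replicate, sep = "\r")
  if (anyDuplicated(key))
    abort("duplicated (sample_id, gene, replicate) combination", "integrity_error")
  grp_per_sample <- tapply(data$group, data$sample_id, function(g) length(unique(g)))
  if (any(grp_per_sample > 1L))
    abort(paste0("sample(s) mapped to more than one group: ",
                 paste(names(grp_per_sample)[grp_per_sample > 1L], collapse = ", ")),
          "integrity_error")
  rownames(data) <- NULL
  structure(data, metadata = metadata, class = c("ct_table", "data.frame"))
}

#' Read a Ct table from CSV/TSV
#'
#' Accepts the long (tidy) layout with columns `sample_id, group, gene,
#' replicate, ct` (any case). Rows whose Ct cell is empty or non-numeric
#' (e.g. instrument "Undetermined" calls) are dropped and counted in the
#' attached load report.
#'
#' @param path path to the file.
#' @param dialect `"comma"` (CSV, default) or `"tab"` (TSV).
#' @return a [ct_table] with attribute `load_report`, a list with elements
#'   `n_read`, `n_kept` and `dropped` (number of rows failing numeric parse).
#' @seealso [write_ct_table()]
#' @export
read_ct_table <- function(path, dialect = c("comma", "tab")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path), "format_error")
  raw <- utils::read.table(path, header = TRUE, sep = if (dialect == "comma") "," else "\t",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  names(raw) <- tolower(names(raw))
  required <- c("sample_id", "group", "gene", "replicate", "ct")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    abort(paste0("Ct file is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")), "format_error")
  n_read <- nrow(raw)
  ct_num <- suppressWarnings(as.numeric(raw$ct))
  keep <- is.finite(ct_num)
  out <- ct_table(raw[keep, required, drop = FALSE])
  attr(out, "load_report") <- list(n_read = n_read, n_kept = sum(keep),
                                   dropped = n_read - sum(keep))
  out
}

#' Write a Ct table to CSV/TSV
#'
#' @inheritParams read_ct_table
#' @param x a [ct_table].
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(x, path, dialect = c("comma", "tab")) {
  dialect <- match.arg(dialect)
  utils::write.table(as.data.frame(x), path, sep = if (dialect == "comma") "," else "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pivot a Ct table to a gene x sample matrix
#'
#' Technical replicates must already be merged (one row per sample x gene; see
#' [merge_technical_replicates()]). Samples missing any gene are dropped
#' (complete-case) with a warning, because all downstream stability
#' statistics assume complete matrices.
#'
#' @param ct a [ct_table] with one measurement per (sample, gene).
#' @return a numeric matrix, genes in rows, samples in columns, with
#'   attribute `groups`: a named character vector mapping sample to group.
#' @export
ct_matrix <- function(ct) {
  stopifnot(inherits(ct, "ct_table"))
  key <- paste(ct$sample_id, ct$gene, sep = "\r")
  if (anyDuplicated(key))
    abort("multiple measurements per (sample, gene); merge technical replicates first",
          "integrity_error")
  genes <- unique(ct$gene)
  samples <- unique(ct$sample_id)
  m <- matrix(NA_real_, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  m[cbind(match(ct$gene, genes), match(ct$sample_id, samples))] <- ct$ct
  incomplete <- colSums(is.na(m)) > 0
  if (any(incomplete)) {
    warning(sprintf("dropping %d sample(s) missing one or more genes: %s",
                    sum(incomplete), paste(samples[incomplete], collapse = ", ")),
            call. = FALSE)
    m <- m[, !incomplete, drop = FALSE]
  }
  groups <- ct$group[match(colnames(m), ct$sample_id)]
  names(groups) <- colnames(m)
  attr(m, "groups") <- groups
  m
}

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf("Ct table: %d measurements, %d samples, %d genes, %d group(s)\n",
              nrow(x), length(unique(x$sample_id)), length(unique(x$gene)),
              length(unique(x$group))))
  NextMethod()
}
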
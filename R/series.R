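#' Sample-series definitions
#'
#' A series names a subset of samples or groups to analyse together, e.g. the
#' developmental windows "A" (whole embryo, unfertilised egg NF0 through
#' NF50) or "B" (the same window excluding NF0) of a staged experiment.
#'
#' @param name short series label, e.g. `"A"`, `"AB"`.
#' @param include non-empty character vector of group labels (or sample ids)
#'   the series keeps.
#' @param description free-text description.
#' @return an object of class `series_definition`.
#' @export
series_definition <- function(name, include, description = "") {
  include <- as.character(include)
  if (!length(include)) abort("series inclusion list must be non-empty", "config_error")
  structure(list(name = as.character(name), include = include,
                 description = as.character(description)),
            class = "series_definition")
}

#' Read series definitions from a YAML or JSON config
#'
#' The config maps series name to either a list of group labels or a mapping
#' with `include` and optional `description`, e.g.
#' \preformatted{
#' A:
#'   include: [NF0, NF1, NF10, NF21, NF37, NF41, NF50]
#'   description: whole embryo incl. unfertilised egg
#' B: [NF1, NF10, NF21, NF37, NF41, NF50]
#' }
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a named list of [series_definition] objects.
#' @export
read_series_config <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path), "format_error")
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!length(cfg)) abort("empty series config", "config_error")
  out <- lapply(names(cfg), function(nm) {
    entry <- cfg[[nm]]
    if (is.list(entry) && !is.null(entry$include)) {
      series_definition(nm, unlist(entry$include), entry$description %||% "")
    } else {
      series_definition(nm, unlist(entry))
    }
  })
  names(out) <- names(cfg)
  out
}

#' Subset a Ct table or TPM matrix to a series
#'
#' Keeps only the samples whose group label or sample id appears in the
#' series inclusion list; sample order is preserved. Applying the same series
#' twice is a no-op.
#'
#' @param x a [ct_table] or [tpm_matrix].
#' @param series a [series_definition] (or character vector of labels).
#' @return an object of the same class as `x`. Fewer than 2 remaining samples
#'   is an error, since stability statistics are undefined there.
#' @export
subset_series <- function(x, series) UseMethod("subset_series")

resolve_series <- function(series) {
  if (inherits(series, "series_definition")) series$include else as.character(series)
}

#' @rdname subset_series
#' @export
subset_series.ct_table <- function(x, series) {
  inc <- resolve_series(series)
  keep <- x$group %in% inc | x$sample_id %in% inc
  out <- x[keep, , drop = FALSE]
  if (length(unique(out$sample_id)) < 2)
    abort("series leaves fewer than 2 samples", "insufficient_data")
  ct_table(as.data.frame(out), metadata = attr(x, "metadata") %||% list())
}

#' @rdname subset_series
#' @export
subset_series.tpm_matrix <- function(x, series) {
  inc <- resolve_series(series)
  keep <- colnames(x) %in% inc
  if (sum(keep) < 2)
    abort("series leaves fewer than 2 samples", "insufficient_data")
  tpm_matrix(unclass(x)[, keep, drop = FALSE])
}
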
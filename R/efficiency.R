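#' Amplification efficiency from a dilution standard curve
#'
#' Fits Ct against log10(relative concentration) by ordinary least squares
#' over a serial-dilution series (e.g. 1:10, 1:100, 1:1,000, 1:10,000). The
#' amplification efficiency is E = (10^(-1/slope) - 1) x 100 %: a perfect
#' doubling per cycle gives a slope of -log2(10) = -3.3219 and E = 100%.
#'
#' @param concentration relative template concentrations, > 0, on any common
#'   scale (the estimate is invariant to rescaling all concentrations).
#' @param ct observed Ct at each concentration, cycles.
#' @param gene optional gene/primer label carried into the result.
#' @return a list of class `efficiency_result`: `gene`, `slope` (cycles per
#'   log10 dilution), `intercept`, `efficiency_pct`, `r_squared`, `n_points`,
#'   and `valid` (FALSE when the slope is non-negative, in which case
#'   `efficiency_pct` is `NA`).
#' @examples
#' amplification_efficiency(c(1, 0.1, 0.01, 0.001),
#'                          c(20, 23.3219, 26.6439, 29.9658))
#' @export
amplification_efficiency <- function(concentration, ct, gene = NA_character_) {
  if (length(concentration) != length(ct))
    abort("concentration and ct must have the same length", "format_error")
  if (any(concentration <= 0)) abort("concentrations must be > 0", "input_error")
  if (length(unique(concentration)) < 3)
    abort("need >= 3 distinct concentrations for a standard curve", "input_error")
  x <- log10(concentration)
  fit <- stats::lm(ct ~ x)
  slope <- unname(stats::coef(fit)[2])
  # direct R^2; summary.lm() warns on the (legitimate) noiseless case
  ss_tot <- sum((ct - mean(ct))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  res <- list(gene = gene,
              slope = slope,
              intercept = unname(stats::coef(fit)[1]),
              efficiency_pct = if (slope < 0) (10^(-1 / slope) - 1) * 100 else NA_real_,
              r_squared = r2,
              n_points = length(ct),
              valid = slope < 0)
  class(res) <- "efficiency_result"
  res
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat(sprintf("Amplification efficiency%s: E = %s%% (slope %.4f, R^2 %.4f, n = %d)%s\n",
              if (is.na(x$gene)) "" else paste0(" [", x$gene, "]"),
              if (is.na(x$efficiency_pct)) "NA" else sprintf("%.3f", x$efficiency_pct),
              x$slope, x$r_squared, x$n_points,
              if (!x$valid) "  ** invalid (non-negative slope)" else ""))
  invisible(x)
}

#' Estimate efficiencies for every gene of a dilution table
#'
#' @param dilutions data.frame with columns `gene`, `concentration`, `ct`
#'   (the layout written by [simulate_dilution_series()] and read from an
#'   `efficiency` dilutions CSV).
#' @return a data.frame, one row per gene: `gene`, `slope`,
#'   `efficiency_pct`, `r_squared`, `n_points`, `valid`, `acceptable`.
#' @seealso [amplification_efficiency()], [efficiency_acceptable()]
#' @export
estimate_efficiencies <- function(dilutions) {
  names(dilutions) <- tolower(names(dilutions))
  req <- c("gene", "concentration", "ct")
  if (!all(req %in% names(dilutions)))
    abort("dilution table needs columns gene, concentration, ct", "format_error")
  out <- lapply(split(dilutions, dilutions$gene), function(d) {
    e <- amplification_efficiency(d$concentration, d$ct, gene = d$gene[1])
    data.frame(gene = e$gene, slope = e$slope, efficiency_pct = e$efficiency_pct,
               r_squared = e$r_squared, n_points = e$n_points, valid = e$valid,
               acceptable = efficiency_acceptable(e), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Is an estimated efficiency acceptable for quantification?
#'
#' Primer validation conventionally accepts efficiencies in a band around
#' 100% with a near-linear standard curve. The defaults (80-130%, R^2 >=
#' 0.9) span the range routinely reported for validated primer sets
#' (roughly 91-121% with R^2 0.93-1.00).
#'
#' @param x an `efficiency_result`.
#' @param e_range acceptable efficiency window, percent.
#' @param min_r_squared minimum standard-curve R^2.
#' @return logical.
#' @export
efficiency_acceptable <- function(x, e_range = c(80, 130), min_r_squared = 0.9) {
  isTRUE(x$valid) && !is.na(x$efficiency_pct) &&
    x$efficiency_pct >= e_range[1] && x$efficiency_pct <= e_range[2] &&
    x$r_squared >= min_r_squared
}
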
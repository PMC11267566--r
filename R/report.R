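## Aggregation of fit outcomes into the cleavability readout.

#' Score cleavability from active-site fit outcomes
#'
#' Under conformational selection, the enzyme binds pre-existing substrate
#' conformations: the larger the fraction of sampled conformers that fit
#' the active site with favorable (negative) interaction energy, the lower
#' the energetic penalty for binding and the more cleavable the substrate.
#' This computes that fraction, plus the median protease-substrate
#' interaction energy of the retained conformers with the N-terminal atoms
#' excluded (an even count of values yields the mean of the middle two).
#' No absolute cleavable/uncleavable threshold is imposed: the readout is
#' relative across substrates.
#'
#' @param outcomes data.frame from [fitEnsemble()]
#' @param mode `"complete"` (all stitched conformers) or `"clustered"`
#'   (cluster centers only)
#' @return a [CleavabilityReport-class]; when nothing was retained the
#'   fraction is 0 and the median is `NA` (undefined)
#' @export
cleavabilityScore <- function(outcomes, mode = c("complete", "clustered")) {
  mode <- match.arg(mode)
  if (nrow(outcomes) == 0) stop("empty outcome set")
  n_total <- nrow(outcomes)
  kept <- outcomes[outcomes$retained, , drop = FALSE]
  n_ret <- nrow(kept)
  med <- if (n_ret == 0) NA_real_ else median(kept$E_bulk_kJmol)
  new("CleavabilityReport", n_total = as.integer(n_total),
      n_retained = as.integer(n_ret),
      fraction_fitted = n_ret / n_total,
      median_E_bulk = med, mode = mode)
}

REPORT_SCHEMA <- "cleavescan-report/1"

#' Write a cleavability report to disk
#'
#' JSON output is a schema-versioned object holding the exact ratio; TSV
#' output is a fixed-header single-row table with the fraction rendered to
#' four decimals. JSON round-trips losslessly through [readReport()].
#'
#' @param report a [CleavabilityReport-class]
#' @param path output file
#' @param format `"json"` or `"tsv"`
#' @return invisibly, `path`
#' @export
writeReport <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- list(schema = REPORT_SCHEMA,
                mode = report@mode,
                n_total = report@n_total,
                n_retained = report@n_retained,
                fraction_fitted = report@fraction_fitted,
                percent_fitted = 100 * report@fraction_fitted,
                median_E_bulk_kJmol = report@median_E_bulk)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    df <- data.frame(mode = report@mode, n_total = report@n_total,
                     n_retained = report@n_retained,
                     fraction_fitted = sprintf("%.4f", report@fraction_fitted),
                     median_E_bulk_kJmol = report@median_E_bulk)
    write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a JSON cleavability report
#' @param path file written by [writeReport()] with `format = "json"`
#' @return a [CleavabilityReport-class]
#' @export
readReport <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, REPORT_SCHEMA))
    stop("unrecognized report schema: ", obj$schema)
  new("CleavabilityReport", n_total = as.integer(obj$n_total),
      n_retained = as.integer(obj$n_retained),
      fraction_fitted = obj$fraction_fitted,
      median_E_bulk = if (is.null(obj$median_E_bulk_kJmol)) NA_real_
      else obj$median_E_bulk_kJmol,
      mode = obj$mode)
}
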
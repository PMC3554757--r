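#' Write an analysis result to disk
#'
#' Serializes the package's result tables -- `energy_breakdown`,
#' `residue_contributions`, `interaction_table`, `ligand_ranking` -- as TSV
#' (fixed field order, energies printed with two decimals, units in the
#' header comment) or JSON (full precision; [read_report()] round-trips it).
#'
#' @param result a result object.
#' @param path output file.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  payload <- report_payload(result)
  if (format == "json") {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", payload$kind, " report; energies kcal/mol, ",
                    "areas A^2, occupancies fraction of frames"), con)
  for (m in payload$meta)
    writeLines(paste0("# ", m), con)
  tab <- payload$table
  num <- vapply(tab, is.numeric, TRUE) & !names(tab) %in%
    c("resid", "rank", "n_frames", "time")
  for (cl in names(tab)[num]) tab[[cl]] <- sprintf("%.2f", tab[[cl]])
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

report_payload <- function(result) UseMethod("report_payload")

#' @export
report_payload.energy_breakdown <- function(result) {
  list(kind = "energy_breakdown",
       meta = c(sprintf("method: MM-%sSA", result$method),
                sprintf("frames: %d, runs: %d", nrow(result$frames),
                        result$n_runs),
                "entropy: omitted (relative binding energies)"),
       table = result$aggregate,
       frames = result$frames,
       method = result$method, run_id = result$run_id,
       window = result$window, n_runs = result$n_runs)
}

#' @export
report_payload.residue_contributions <- function(result) {
  list(kind = "residue_contributions",
       meta = sprintf("polar method: %s", attr(result, "method")),
       table = as.data.frame(result),
       totals = as.list(attr(result, "totals")))
}

#' @export
report_payload.interaction_table <- function(result) {
  list(kind = "interaction_table", meta = character(),
       table = as.data.frame(result))
}

#' @export
report_payload.ligand_ranking <- function(result) {
  list(kind = "ligand_ranking",
       meta = sprintf("method: MM-%sSA, ascending binding energy",
                      attr(result, "method")),
       table = as.data.frame(result),
       unresolved = attr(result, "unresolved"))
}

#' Read back a JSON report
#'
#' @param path a JSON file written by [write_report()].
#' @return The deserialized payload (list with `kind`, `table`, ...).
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
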
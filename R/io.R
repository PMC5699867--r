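#' Read a per-cell expression table
#'
#' Delimited text with header columns `library_id`, `condition`
#' ("minus"/"plus"), `replicate`, `log10_fluorescence`. Values must be
#' finite; offending rows are reported by number.
#'
#' @param path file path (tab- or comma-separated, sniffed from the header).
#' @return validated data.frame with the four columns above.
#' @export
readCellTable <- function(path) {
  tab <- readDelim(path)
  need <- c("library_id", "condition", "replicate", "log10_fluorescence")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stopf("cell table %s lacks columns: %s", path, paste(miss, collapse = ", "))
  if (!nrow(tab)) stopf("cell table %s contains no samples", path)
  bad <- which(!is.finite(tab$log10_fluorescence))
  if (length(bad))
    stopf("non-finite log10_fluorescence at rows: %s",
          paste(utils::head(bad, 10), collapse = ", "))
  badc <- which(!tab$condition %in% c("minus", "plus"))
  if (length(badc))
    stopf("unknown condition labels (want 'minus'/'plus') at rows: %s",
          paste(utils::head(badc, 10), collapse = ", "))
  tab[need]
}

#' Write a per-cell expression table
#'
#' @param tab data.frame as returned by [readCellTable()].
#' @param path output path (tab-separated).
#' @export
writeCellTable <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a double-mutant replicate panel
#'
#' Delimited text with columns `pair_id`, `role` ("wildtype", "cis",
#' "trans", "double"), `condition`, `replicate`, `fluorescence`
#' (linear scale) and optionally `location_label`. Each pair with a double
#' mutant must also carry both singles, and the batch a wildtype replicate
#' set; incomplete pairs are rejected by name.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
readMutantPanel <- function(path) {
  tab <- readDelim(path)
  need <- c("pair_id", "role", "condition", "replicate", "fluorescence")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stopf("panel %s lacks columns: %s", path, paste(miss, collapse = ", "))
  if (!"location_label" %in% names(tab)) tab$location_label <- NA_character_
  badr <- which(!tab$role %in% c("wildtype", "cis", "trans", "double"))
  if (length(badr))
    stopf("unknown role labels at rows: %s",
          paste(utils::head(badr, 10), collapse = ", "))
  if (!any(tab$role == "wildtype"))
    stopf("panel %s has no wildtype replicates", path)
  ids <- unique(tab$pair_id[tab$role == "double"])
  for (id in ids) {
    roles <- unique(tab$role[tab$pair_id == id])
    miss <- setdiff(c("cis", "trans", "double"), roles)
    if (length(miss))
      stopf("pair '%s' is incomplete: missing role(s) %s", id,
            paste(miss, collapse = ", "))
  }
  tab
}

#' Write a double-mutant replicate panel
#'
#' @param panel data.frame as produced by [generateDoubleMutantPanel()].
#' @param path output path (tab-separated).
#' @export
writeMutantPanel <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Sniff tab vs comma from the header line.
readDelim <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  hdr <- readLines(path, n = 1L)
  if (!length(hdr)) stopf("file %s is empty", path)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
}
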
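# Delimited-text readers and writers. All tabular I/O is TSV so that every
# artefact of a run is plain text and diffable.

#' Read / write long-format interaction records
#'
#' @param path file path of a tab-separated table with columns `site_id`,
#'   `round`, `plant_species`, `visitor_species`, `visitor_group`, `count`.
#' @return `readInteractionRecords`: a validated data.frame.
#' @export
readInteractionRecords <- function(path) {
  rec <- read.delim(path, stringsAsFactors = FALSE)
  validateRecords(rec)
  rec
}

#' @rdname readInteractionRecords
#' @param records interaction records.
#' @export
writeInteractionRecords <- function(records, path) {
  validateRecords(records)
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a labelled network matrix
#'
#' Matrices are stored with plants as rows and visitors as columns,
#' matching the orientation used throughout the package.
#'
#' @param net a [BipartiteNetwork-class].
#' @param path file path.
#' @param siteId,resolution metadata for the re-read network.
#' @return `readNetworkMatrix`: a [BipartiteNetwork-class].
#' @export
writeNetworkMatrix <- function(net, path) {
  a <- interactionMatrix(net)
  df <- data.frame(plant = rownames(a), a, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeNetworkMatrix
#' @export
readNetworkMatrix <- function(path, siteId = "site", resolution = "species") {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  BipartiteNetwork(m, siteId = siteId, resolution = resolution)
}
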
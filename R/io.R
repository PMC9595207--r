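#' Read / write the plain-text interchange formats
#'
#' Cell tables and well maps travel as tab-separated text with a header;
#' protein-groups tables use the MaxQuant dialect (`LFQ intensity <sample>`
#' columns, `"+"`-valued flag columns); simulation truth is a JSON sidecar.
#'
#' @param path file path.
#' @param x object to write.
#' @return the read data.frame, or (invisibly) `path` for writers.
#' @name traffiq_io
NULL

#' @rdname traffiq_io
#' @export
read_cell_table <- function(path) {
  utils::read.delim(path, check.names = TRUE, stringsAsFactors = FALSE)
}

#' @rdname traffiq_io
#' @export
write_cell_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname traffiq_io
#' @export
read_well_map <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  do.call(well_map, d[intersect(design_columns(), names(d))])
}

#' @rdname traffiq_io
#' @export
write_well_map <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname traffiq_io
#' @export
read_protein_groups <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname traffiq_io
#' @export
write_protein_groups <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname traffiq_io
#' @export
write_truth <- function(x, path) {
  stopifnot(inherits(x, "sim_truth"))
  out <- x[setdiff(names(x), c("complete_log2", "missing"))]
  out$config <- unclass(out$config)
  out$config <- out$config[!vapply(out$config, is.null, logical(1))]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
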
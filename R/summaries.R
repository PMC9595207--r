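#' Per-well and per-condition summaries of a cell table
#'
#' Wells, not cells, are the unit of replication throughout: `well_means()`
#' averages a value column within each well, and `condition_means()`
#' aggregates those well means over the design strata in `by`, reporting
#' mean, SD, number of wells and standard error.
#'
#' @param cells a cell table (gated/normalized as appropriate).
#' @param design a [well_map()].
#' @param value name of the column to summarize.
#' @param by character vector of design columns defining conditions.
#' @param exclude_wells optional data.frame (plate, well) of QC-failed wells
#'   to drop before summarizing.
#' @return `well_means()`: data.frame of design columns + `well_mean`, `n_cells`;
#'   `condition_means()`: data.frame of `by` columns + `n_wells`, `mean`,
#'   `sd`, `se`.
#' @export
well_means <- function(cells, design, value, exclude_wells = NULL) {
  if (!value %in% names(cells)) stop("no column '", value, "' in cells")
  if (!is.null(exclude_wells) && nrow(exclude_wells)) {
    drop <- paste(cells$plate, cells$well) %in%
      paste(exclude_wells$plate, exclude_wells$well)
    cells <- cells[!drop, , drop = FALSE]
  }
  v <- cells[[value]]
  keep <- !is.na(v)
  wm <- stats::aggregate(
    list(well_mean = v[keep]),
    by = list(plate = cells$plate[keep], well = cells$well[keep]),
    FUN = mean)
  nc <- stats::aggregate(
    list(n_cells = rep(1L, sum(keep))),
    by = list(plate = cells$plate[keep], well = cells$well[keep]),
    FUN = sum)
  wm <- merge(wm, nc, by = c("plate", "well"))
  merge(design, wm, by = c("plate", "well"))
}

#' @rdname well_means
#' @export
condition_means <- function(cells, design, value, by = "insulin_nM",
                            exclude_wells = NULL) {
  wm <- well_means(cells, design, value, exclude_wells = exclude_wells)
  agg <- function(f) stats::aggregate(list(x = wm$well_mean),
                                      by = wm[by], FUN = f)
  out <- agg(mean); names(out)[ncol(out)] <- "mean"
  out$sd <- agg(stats::sd)$x
  out$n_wells <- agg(length)$x
  out$se <- ifelse(out$n_wells > 1, out$sd / sqrt(out$n_wells), NA_real_)
  out[do.call(order, out[by]), , drop = FALSE]
}
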
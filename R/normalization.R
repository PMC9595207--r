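#' Anchored cross-plate normalization of single-cell intensities
#'
#' Removes per-plate gain/offset batch effects by anchoring every plate to
#' its control wells. For plate *i*, let `med0_i` and `med100_i` be the
#' medians of the pooled control 0 nM and control 100 nM insulin cells on
#' that plate, and let `maxmed0 = max_i med0_i`, `maxmed100 = max_i med100_i`
#' across plates. Each plate is then linearly transformed so its control
#' medians land exactly on the common anchors:
#'
#' `Xnorm_i = (X_i - med0_i) * (maxmed100 - maxmed0) / (med100_i - med0_i) + maxmed0`
#'
#' (the unique linear map sending `med0_i -> maxmed0` and
#' `med100_i -> maxmed100`). The log2 of the normalized values is returned
#' alongside; cells with nonpositive `Xnorm` get `NA` in the log2 column and
#' their count is reported rather than being floored, which would distort
#' the left tail of the single-cell distributions.
#'
#' Medians are computed over the cells present in the table, pooled across a
#' plate's control wells; gate first ([apply_gate()]) so that anchors are
#' adipocyte medians.
#'
#' @param cells a (gated) cell table.
#' @param design a [well_map()] with `control_basal` / `control_max` roles on
#'   every plate.
#' @param channel intensity column to normalize (default `"glut4_surface"`).
#' @return `cells` with added columns `<channel>_norm` and
#'   `<channel>_log2norm`, and attributes `anchors` (data.frame: plate,
#'   med0, med100, plus `maxmed0` / `maxmed100`) and `n_nonpositive`.
#' @export
plate_normalize <- function(cells, design, channel = "glut4_surface") {
  if (!channel %in% names(cells)) stop("no column '", channel, "' in cells")
  key_cells <- paste(cells$plate, cells$well)
  plates <- unique(cells$plate)

  anchors <- do.call(rbind, lapply(plates, function(p) {
    cb_wells <- design[design$plate == p & design$role == "control_basal", ]
    cm_wells <- design[design$plate == p & design$role == "control_max", ]
    cb <- cells[[channel]][key_cells %in% paste(cb_wells$plate, cb_wells$well)]
    cm <- cells[[channel]][key_cells %in% paste(cm_wells$plate, cm_wells$well)]
    if (length(cb) == 0L || length(cm) == 0L) {
      stop("plate ", p, " has no gated cells in its control ",
           if (length(cb) == 0L) "basal" else "100 nM", " wells")
    }
    data.frame(plate = p, med0 = stats::median(cb),
               med100 = stats::median(cm), stringsAsFactors = FALSE)
  }))
  bad <- anchors$med100 <= anchors$med0
  if (any(bad)) {
    stop("non-responsive plate(s) (med100 <= med0): ",
         paste(anchors$plate[bad], collapse = ", "))
  }
  maxmed0 <- max(anchors$med0)
  maxmed100 <- max(anchors$med100)
  if (maxmed100 <= maxmed0) stop("degenerate anchors: maxmed100 <= maxmed0")

  slope <- (maxmed100 - maxmed0) / (anchors$med100 - anchors$med0)
  names(slope) <- anchors$plate
  med0 <- stats::setNames(anchors$med0, anchors$plate)

  x <- cells[[channel]]
  xnorm <- (x - med0[cells$plate]) * slope[cells$plate] + maxmed0
  cells[[paste0(channel, "_norm")]] <- unname(xnorm)
  nonpos <- xnorm <= 0
  l2 <- ifelse(nonpos, NA_real_, log2(pmax(xnorm, .Machine$double.xmin)))
  cells[[paste0(channel, "_log2norm")]] <- unname(l2)
  if (any(nonpos)) {
    message(sum(nonpos), " cell(s) with nonpositive normalized ", channel,
            " excluded from the log2 column")
  }
  attr(cells, "anchors") <- anchors
  attr(cells, "maxmed0") <- maxmed0
  attr(cells, "maxmed100") <- maxmed100
  attr(cells, "n_nonpositive") <- sum(nonpos)
  cells
}

#' Fold over basal
#'
#' Per-condition summary divided by the matched basal (unstimulated) summary.
#'
#' @param x numeric vector of condition summaries (e.g. means).
#' @param basal the matched basal summary; must be > 0.
#' @return `x / basal`.
#' @export
fold_over_basal <- function(x, basal) {
  if (!is.finite(basal) || basal <= 0) stop("basal summary must be positive")
  x / basal
}

#' min:max percent normalization
#'
#' Rescales summaries so the control basal maps to 0% and the control
#' 100 nM insulin response to 100%:
#' `100 * (x - basal_ctrl) / (max_ctrl - basal_ctrl)`. Values outside the
#' anchors are allowed (no clamping).
#'
#' @param x numeric summaries.
#' @param basal_ctrl,max_ctrl the anchor summaries, `max_ctrl > basal_ctrl`.
#' @return percent of maximal response.
#' @export
minmax_percent <- function(x, basal_ctrl, max_ctrl) {
  if (!is.finite(basal_ctrl) || !is.finite(max_ctrl) ||
      max_ctrl <= basal_ctrl) {
    stop("degenerate anchors: require max_ctrl > basal_ctrl")
  }
  100 * (x - basal_ctrl) / (max_ctrl - basal_ctrl)
}

#' Surface-over-total reporter ratio
#'
#' Per-cell surface intensity divided by the total-reporter intensity, the
#' readout used with dual-tagged overexpressed reporters. Cells with a
#' nonpositive total are excluded (count in attribute `n_excluded`).
#'
#' @param cells a cell table with a `total_reporter` column.
#' @param channel surface channel (default `"glut4_surface"`).
#' @return the included rows of `cells` with an added `surface_total_ratio`
#'   column; attribute `n_excluded` counts the dropped cells.
#' @export
surface_over_total <- function(cells, channel = "glut4_surface") {
  if (!"total_reporter" %in% names(cells) || all(is.na(cells$total_reporter))) {
    stop("cells must carry a total_reporter column")
  }
  ok <- !is.na(cells$total_reporter) & cells$total_reporter > 0
  out <- cells[ok, , drop = FALSE]
  out$surface_total_ratio <- out[[channel]] / out$total_reporter
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Fold over (non-targeting) control
#'
#' Condition summaries divided by the matched control summary within each
#' stratum. This is the screen's effect-size scale: 1 = no effect.
#'
#' @param x numeric vector of condition summaries.
#' @param control the matched control summary (nonzero).
#' @return `x / control`.
#' @export
fold_over_control <- function(x, control) {
  if (!is.finite(control) || control == 0) {
    stop("missing or degenerate control summary for stratum")
  }
  x / control
}
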
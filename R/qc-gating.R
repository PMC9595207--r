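#' Gate adipocytes on the lipid-scatter feature
#'
#' Adipocytes are distinguished from fibroblasts and necrotic cells by the
#' light scatter of their lipid droplets: cells at or above a scatter
#' threshold are called adipocytes. The threshold is either supplied
#' (`method = "fixed"`) or found automatically (`method = "auto"`) as the
#' exact two-class split minimizing pooled within-class variance (Otsu's
#' criterion evaluated on the sorted values, not on a binned histogram).
#' The automatic threshold is computed on control wells only when a design
#' with control roles is supplied, avoiding treatment-induced bias, and is
#' then applied to all wells; `per_plate = TRUE` recomputes it per plate.
#'
#' @param cells a cell table with a finite `lipid_scatter` column.
#' @param method `"auto"` or `"fixed"`.
#' @param threshold scatter threshold for `method = "fixed"`.
#' @param design optional [well_map()]; when present and `method = "auto"`,
#'   only cells in `control_basal` / `control_max` wells train the split.
#' @param per_plate compute the automatic threshold per plate.
#' @return an object of class `gate_result`: list with `adipocyte` (logical
#'   per cell, in row order of `cells`), `threshold` (named per plate if
#'   `per_plate`), `method`, and `well_counts` (plate, well, n_total,
#'   n_gated).
#' @export
gate_adipocytes <- function(cells, method = c("auto", "fixed"),
                            threshold = NULL, design = NULL,
                            per_plate = FALSE) {
  method <- match.arg(method)
  x <- cells$lipid_scatter
  if (is.null(x) || !all(is.finite(x))) {
    stop("cells must carry a finite lipid_scatter column")
  }
  if (method == "fixed") {
    if (is.null(threshold) || !is.finite(threshold)) {
      stop("method = 'fixed' requires a finite threshold")
    }
    thr <- threshold
    flag <- x >= thr
  } else {
    train_mask <- rep(TRUE, nrow(cells))
    if (!is.null(design) && any(design$role != "sample")) {
      ctrl <- design[design$role %in% c("control_basal", "control_max"), ]
      train_mask <- paste(cells$plate, cells$well) %in%
        paste(ctrl$plate, ctrl$well)
      if (!any(train_mask)) train_mask <- rep(TRUE, nrow(cells))
    }
    if (per_plate) {
      plates <- unique(cells$plate)
      thr <- vapply(plates, function(p) {
        otsu_threshold(x[train_mask & cells$plate == p])
      }, numeric(1))
      names(thr) <- plates
      flag <- x >= thr[cells$plate]
    } else {
      thr <- otsu_threshold(x[train_mask])
      flag <- x >= thr
    }
  }
  wc <- stats::aggregate(cbind(n_total = rep(1L, nrow(cells)),
                               n_gated = as.integer(flag)),
                         by = list(plate = cells$plate, well = cells$well),
                         FUN = sum)
  structure(list(adipocyte = flag, threshold = thr, method = method,
                 well_counts = wc[order(wc$plate, wc$well), ]),
            class = "gate_result")
}

# Exact 2-class minimum within-class variance split on sorted values.
otsu_threshold <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 2L || x[1] == x[n]) {
    stop("automatic gating impossible: scatter values are not separable")
  }
  cs <- cumsum(x)
  css <- cumsum(x^2)
  i <- seq_len(n - 1L)
  # within-class sums of squares for split after position i
  ss_left <- css[i] - cs[i]^2 / i
  ss_right <- (css[n] - css[i]) - (cs[n] - cs[i])^2 / (n - i)
  within <- ss_left + ss_right
  ok <- x[i] < x[i + 1L]          # only real gaps are admissible cuts
  within[!ok] <- Inf
  k <- which.min(within)
  (x[k] + x[k + 1L]) / 2
}

#' @export
print.gate_result <- function(x, ...) {
  thr <- if (length(x$threshold) > 1) {
    paste(sprintf("%s=%.3g", names(x$threshold), x$threshold), collapse = ", ")
  } else sprintf("%.4g", x$threshold)
  cat(sprintf("<gate_result> method=%s threshold=%s: %d/%d cells gated as adipocytes\n",
              x$method, thr, sum(x$adipocyte), length(x$adipocyte)))
  invisible(x)
}

#' Subset a cell table to gated adipocytes
#'
#' @param cells the cell table the gate was computed on (same row order).
#' @param gate a [gate_adipocytes()] result.
#' @return the adipocyte rows of `cells`.
#' @export
apply_gate <- function(cells, gate) {
  stopifnot(inherits(gate, "gate_result"),
            length(gate$adipocyte) == nrow(cells))
  cells[gate$adipocyte, , drop = FALSE]
}

#' Count nuclei (segmented cells) per field of view
#'
#' @param cells a cell table.
#' @param design optional [well_map()]; wells listed there but absent from
#'   the table are reported with count 0.
#' @return data.frame (plate, well, field, n_nuclei).
#' @export
count_nuclei <- function(cells, design = NULL) {
  if (nrow(cells) == 0L) {
    warning("empty cell table: no nuclei to count")
    counts <- data.frame(plate = character(), well = character(),
                         field = integer(), n_nuclei = integer())
  } else {
    counts <- stats::aggregate(
      list(n_nuclei = rep(1L, nrow(cells))),
      by = list(plate = cells$plate, well = cells$well, field = cells$field),
      FUN = sum)
  }
  if (!is.null(design)) {
    absent <- !paste(design$plate, design$well) %in%
      paste(counts$plate, counts$well)
    if (any(absent)) {
      counts <- rbind(counts,
                      data.frame(plate = design$plate[absent],
                                 well = design$well[absent],
                                 field = NA_integer_, n_nuclei = 0L))
    }
  }
  counts[order(counts$plate, counts$well, counts$field), , drop = FALSE]
}

#' Well-level QC on gated cell counts
#'
#' Flags wells whose gated adipocyte count falls below `min_cells`; such
#' wells should be excluded from all downstream summaries. Re-running with a
#' different `min_cells` only changes membership, never per-cell values.
#'
#' @param gate a [gate_adipocytes()] result.
#' @param min_cells minimum gated cells per well (>= 1).
#' @return data.frame (plate, well, n_total, n_gated, pass); failing wells
#'   are also reported via `message()`.
#' @export
well_qc <- function(gate, min_cells) {
  stopifnot(inherits(gate, "gate_result"), min_cells >= 1)
  qc <- gate$well_counts
  qc$pass <- qc$n_gated >= min_cells
  if (any(!qc$pass)) {
    message(sum(!qc$pass), " well(s) failed QC (< ", min_cells,
            " gated cells): ",
            paste(paste0(qc$plate[!qc$pass], "/", qc$well[!qc$pass]),
                  collapse = ", "))
  }
  qc
}
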
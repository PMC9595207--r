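#' Kernel density estimate of single-cell intensities
#'
#' Gaussian-kernel density of (typically log2-normalized) single-cell
#' values, with bandwidth by Silverman's rule of thumb unless overridden.
#' Supplying `from`/`to` (e.g. the range of the pooled controls) puts
#' curves for different conditions on one comparable grid; use a common
#' `bw` across conditions of a figure for comparable smoothing.
#'
#' @param values numeric vector, >= 50 finite values, not all identical.
#' @param bw bandwidth; default Silverman ([stats::bw.nrd0()]).
#' @param from,to grid range (default: span of `values`).
#' @param n_grid grid size (default 512).
#' @return object of class `density_curve`: `x`, `y`, `bw`, `n`, `peak`
#'   (grid argmax).
#' @export
density_estimate <- function(values, bw = NULL, from = NULL, to = NULL,
                             n_grid = 512) {
  values <- values[is.finite(values)]
  if (length(values) < 50L) {
    stop("need >= 50 finite values for a reliable density")
  }
  if (stats::sd(values) == 0) {
    stop("degenerate input: all values identical")
  }
  if (is.null(bw)) bw <- stats::bw.nrd0(values)
  args <- list(x = values, bw = bw, n = n_grid, kernel = "gaussian")
  if (!is.null(from)) args$from <- from - 3 * bw
  if (!is.null(to)) args$to <- to + 3 * bw
  d <- do.call(stats::density, args)
  structure(list(x = d$x, y = d$y, bw = bw, n = length(values),
                 peak = d$x[which.max(d$y)]),
            class = "density_curve")
}

#' @export
print.density_curve <- function(x, ...) {
  cat(sprintf("<density_curve> n=%d, bw=%.4g, peak at %.4g\n",
              x$n, x$bw, x$peak))
  invisible(x)
}

#' Local maxima of a density curve
#'
#' @param curve a [density_estimate()] result.
#' @param min_height discard maxima below this fraction of the global peak.
#' @return numeric vector of x positions of local maxima.
#' @export
density_peaks <- function(curve, min_height = 0.05) {
  y <- curve$y
  i <- which(diff(sign(diff(y))) == -2) + 1L
  i <- i[y[i] >= min_height * max(y)]
  curve$x[i]
}

#' Population shift metric
#'
#' Locates a treated population between the basal and maximally stimulated
#' control populations on the median scale:
#' `(median(condition) - median(basal)) / (median(max) - median(basal))`.
#' 0 = fully basal-like, 1 = fully insulin-like; values outside \[0, 1\] can
#' occur and are not clamped. Invariant under any common affine transform of
#' the three populations.
#'
#' @param condition,basal_ctrl,max_ctrl numeric vectors of per-cell values.
#' @return a scalar.
#' @export
shift_metric <- function(condition, basal_ctrl, max_ctrl) {
  if (!length(condition) || !length(basal_ctrl) || !length(max_ctrl)) {
    stop("all three populations must be nonempty")
  }
  den <- stats::median(max_ctrl) - stats::median(basal_ctrl)
  if (!is.finite(den) || den == 0) {
    stop("degenerate controls: basal and max medians coincide")
  }
  (stats::median(condition) - stats::median(basal_ctrl)) / den
}

# Per-well readout extractors for the knockdown screen; each returns a
# data.frame (plate, well, well_value) or NULL when its columns are absent.
screen_readout_value <- function(cells, readout) {
  per_well <- function(v, f = mean) {
    keep <- is.finite(v)
    if (!any(keep)) return(NULL)
    stats::aggregate(list(well_value = v[keep]),
                     by = list(plate = cells$plate[keep],
                               well = cells$well[keep]), FUN = f)
  }
  col_or_norm <- function(ch) {
    nm <- paste0(ch, "_norm")
    if (nm %in% names(cells)) cells[[nm]]
    else if (ch %in% names(cells)) cells[[ch]]
    else NULL
  }
  switch(readout,
    glut4_surface = { v <- col_or_norm("glut4_surface")
                      if (is.null(v)) NULL else per_well(v) },
    tfr_surface = { v <- col_or_norm("tfr_surface")
                    if (is.null(v)) NULL else per_well(v) },
    nuclei = {
      if (!all(c("field") %in% names(cells))) return(NULL)
      cnt <- count_nuclei(cells)
      stats::aggregate(list(well_value = cnt$n_nuclei),
                       by = list(plate = cnt$plate, well = cnt$well),
                       FUN = mean)
    },
    droplet_count = { if (!"droplet_count" %in% names(cells)) NULL
                      else per_well(as.numeric(cells$droplet_count)) },
    droplet_area_mean = {
      if (!all(c("droplet_count", "droplet_area_total") %in% names(cells))) {
        return(NULL)
      }
      ok <- cells$droplet_count > 0
      if (!any(ok)) return(NULL)
      sub <- cells[ok, ]
      stats::aggregate(
        list(well_value = sub$droplet_area_total / sub$droplet_count),
        by = list(plate = sub$plate, well = sub$well), FUN = mean)
    },
    stop("unknown readout '", readout, "'"))
}

#' Summarize a knockdown screen across readouts
#'
#' Collapses a (normalized) cell table to per-well readout values, then to
#' per-condition summaries (mean, SD over wells, n) for each readout, with
#' fold over the non-targeting control (FOC) within each (insulin dose x
#' cell line) stratum. Inference is a documented substitute for the
#' mixed-model post hocs of typical screen reports: a two-sided Welch test
#' of each target's wells against the stratum control wells, BH-adjusted
#' across targets within each readout x stratum.
#'
#' @param cells cell table (gate and [plate_normalize()] first; normalized
#'   channels are used when present).
#' @param design a [well_map()] with a `control` target in every stratum.
#' @param readouts subset of `c("glut4_surface", "tfr_surface", "nuclei",
#'   "droplet_count", "droplet_area_mean")`; readouts whose columns are
#'   absent are skipped with a warning.
#' @param control the non-targeting control label (default `"NT"`).
#' @param exclude_wells optional data.frame (plate, well) of QC failures.
#' @return data.frame of class `screen_summary`: target, cell_line,
#'   insulin_nM, readout, n_wells, mean, sd, foc, p_value, adj_p.
#' @export
summarize_screen <- function(cells, design,
                             readouts = c("glut4_surface", "tfr_surface",
                                          "nuclei", "droplet_count",
                                          "droplet_area_mean"),
                             control = "NT", exclude_wells = NULL) {
  if (!control %in% design$sirna) {
    stop("control target '", control, "' absent from design")
  }
  if (!is.null(exclude_wells) && nrow(exclude_wells)) {
    drop <- paste(cells$plate, cells$well) %in%
      paste(exclude_wells$plate, exclude_wells$well)
    cells <- cells[!drop, , drop = FALSE]
  }
  out <- list()
  for (ro in readouts) {
    wv <- screen_readout_value(cells, ro)
    if (is.null(wv)) {
      warning("readout '", ro, "' not available in this table; skipped")
      next
    }
    wv <- merge(design, wv, by = c("plate", "well"))
    strata <- unique(wv[c("cell_line", "insulin_nM")])
    for (s in seq_len(nrow(strata))) {
      sl <- wv[wv$cell_line == strata$cell_line[s] &
                 wv$insulin_nM == strata$insulin_nM[s], ]
      ctrl_vals <- sl$well_value[sl$sirna == control]
      if (!length(ctrl_vals)) {
        stop("no '", control, "' control wells in stratum ",
             strata$cell_line[s], " / ", strata$insulin_nM[s], " nM")
      }
      ctrl_mean <- mean(ctrl_vals)
      for (tg in unique(sl$sirna)) {
        v <- sl$well_value[sl$sirna == tg]
        p <- if (tg == control || length(v) < 2L || length(ctrl_vals) < 2L ||
                 (stats::sd(v) == 0 && stats::sd(ctrl_vals) == 0)) {
          NA_real_
        } else {
          stats::t.test(v, ctrl_vals)$p.value   # Welch
        }
        out[[length(out) + 1L]] <- data.frame(
          target = tg, cell_line = strata$cell_line[s],
          insulin_nM = strata$insulin_nM[s], readout = ro,
          n_wells = length(v), mean = mean(v), sd = stats::sd(v),
          foc = fold_over_control(mean(v), ctrl_mean),
          p_value = p, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) stop("no readout could be computed from this table")
  res <- do.call(rbind, out)
  res$adj_p <- NA_real_
  for (grp in split(seq_len(nrow(res)),
                    paste(res$readout, res$cell_line, res$insulin_nM))) {
    res$adj_p[grp] <- stats::p.adjust(res$p_value[grp], method = "BH")
  }
  class(res) <- c("screen_summary", "data.frame")
  res
}

#' Cross-cell-line correlation of knockdown effects
#'
#' Ordinary least-squares regression of one screen's per-target effect sizes
#' on another's over the shared targets (simple linear regression; slope,
#' intercept, r-squared, and the two-sided p-value for slope != 0).
#'
#' @param summary_a,summary_b data.frames with a target column and a value
#'   column, e.g. filtered rows of a [summarize_screen()] result.
#' @param value name of the effect column (default `"foc"`).
#' @param target name of the target id column (default `"target"`).
#' @return object of class `crossline_cor`: slope, intercept, r_squared,
#'   p_value, n, and the merged points.
#' @export
crossline_correlation <- function(summary_a, summary_b, value = "foc",
                                  target = "target") {
  m <- merge(summary_a[c(target, value)], summary_b[c(target, value)],
             by = target, suffixes = c("_a", "_b"))
  if (nrow(m) < 3L) stop("need >= 3 shared targets")
  fit <- stats::lm(m[[paste0(value, "_b")]] ~ m[[paste0(value, "_a")]])
  sm <- summary(fit)
  slope_p <- if (nrow(sm$coefficients) >= 2) sm$coefficients[2, 4] else NA_real_
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    p_value = slope_p,
    n = nrow(m),
    points = m
  ), class = "crossline_cor")
}

#' @export
print.crossline_cor <- function(x, ...) {
  cat(sprintf("<crossline_cor> n=%d: slope %.3g, intercept %.3g, r^2 %.3f, p %.3g\n",
              x$n, x$slope, x$intercept, x$r_squared, x$p_value))
  invisible(x)
}

#' Lipid droplet summaries per condition
#'
#' Per-well droplet totals and per-cell means, aggregated to condition
#' mean +/- SD (wells as the unit of replication).
#'
#' @param cells cell table with `droplet_count` and `droplet_area_total`.
#' @param design a [well_map()].
#' @param by design columns defining conditions.
#' @return data.frame: `by` columns + n_wells and mean/sd of per-cell
#'   droplet count, per-well total droplets, and mean single-droplet area.
#' @export
lipid_summaries <- function(cells, design, by = c("sirna", "insulin_nM")) {
  need <- c("droplet_count", "droplet_area_total")
  if (!all(need %in% names(cells)) ||
      all(is.na(cells$droplet_count))) {
    stop("droplet columns absent or empty")
  }
  per_well <- stats::aggregate(
    list(mean_count = as.numeric(cells$droplet_count),
         total_count = as.numeric(cells$droplet_count)),
    by = list(plate = cells$plate, well = cells$well),
    FUN = mean)
  tot <- stats::aggregate(list(total_count = as.numeric(cells$droplet_count)),
                          by = list(plate = cells$plate, well = cells$well),
                          FUN = sum)
  per_well$total_count <- tot$total_count[match(paste(per_well$plate, per_well$well),
                                                paste(tot$plate, tot$well))]
  ok <- cells$droplet_count > 0
  area <- stats::aggregate(
    list(mean_area = cells$droplet_area_total[ok] / cells$droplet_count[ok]),
    by = list(plate = cells$plate[ok], well = cells$well[ok]), FUN = mean)
  per_well <- merge(per_well, area, by = c("plate", "well"), all.x = TRUE)
  wm <- merge(design, per_well, by = c("plate", "well"))
  agg <- function(col, f) {
    stats::aggregate(list(x = wm[[col]]), by = wm[by], FUN = f)
  }
  out <- agg("mean_count", mean); names(out)[ncol(out)] <- "droplet_count_mean"
  out$droplet_count_sd <- agg("mean_count", stats::sd)$x
  out$well_total_mean <- agg("total_count", mean)$x
  out$well_total_sd <- agg("total_count", stats::sd)$x
  out$droplet_area_mean <- agg("mean_area", function(v) mean(v, na.rm = TRUE))$x
  out$droplet_area_sd <- agg("mean_area", function(v) stats::sd(v[!is.na(v)]))$x
  out$n_wells <- agg("mean_count", length)$x
  out
}
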
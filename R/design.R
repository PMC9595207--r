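#' Construct a well-condition map
#'
#' A well map is a plain data frame with one row per (plate, well) describing
#' the experimental condition of that well. [simulate_plate()] consumes it to
#' decide each well's true mean response, and the normalization / summary
#' functions use it to locate control wells and to stratify conditions.
#'
#' The `role` column flags the anchor wells of the cross-plate normalization:
#' `"control_basal"` (untreated, 0 nM insulin) and `"control_max"` (untreated,
#' 100 nM insulin); every other well is `"sample"`.
#'
#' @param plate,well character vectors (recycled to a common length).
#' @param insulin_nM acute insulin dose in nM.
#' @param time_min stimulation time in minutes (`NA` = steady state).
#' @param inhibitor,inhibitor_dose signalling inhibitor name and dose
#'   (`NA`/0 = none).
#' @param resist_agent,resist_dose insulin-resistance agent and dose.
#' @param sirna siRNA target label (`"NT"` = non-targeting control).
#' @param cell_line cell line label.
#' @param effect_glut4,effect_tfr,effect_cells,effect_droplets knockdown
#'   ground-truth multipliers applied by the generator to the GLUT4 mean, the
#'   TfR mean, the expected cell count and the droplet count, respectively.
#' @param role one of `"sample"`, `"control_basal"`, `"control_max"`.
#'
#' @return a `data.frame` well map.
#' @export
well_map <- function(plate, well,
                     insulin_nM = 0,
                     time_min = NA_real_,
                     inhibitor = NA_character_,
                     inhibitor_dose = 0,
                     resist_agent = NA_character_,
                     resist_dose = 0,
                     sirna = "NT",
                     cell_line = "3T3-L1",
                     effect_glut4 = 1,
                     effect_tfr = 1,
                     effect_cells = 1,
                     effect_droplets = 1,
                     role = "sample") {
  d <- data.frame(
    plate = as.character(plate), well = as.character(well),
    insulin_nM = insulin_nM, time_min = time_min,
    inhibitor = as.character(inhibitor), inhibitor_dose = inhibitor_dose,
    resist_agent = as.character(resist_agent), resist_dose = resist_dose,
    sirna = as.character(sirna), cell_line = as.character(cell_line),
    effect_glut4 = effect_glut4, effect_tfr = effect_tfr,
    effect_cells = effect_cells, effect_droplets = effect_droplets,
    role = as.character(role),
    stringsAsFactors = FALSE
  )
  bad <- !d$role %in% c("sample", "control_basal", "control_max")
  if (any(bad)) {
    stop("unknown role(s): ", paste(unique(d$role[bad]), collapse = ", "))
  }
  if (anyDuplicated(paste(d$plate, d$well))) {
    stop("duplicated (plate, well) entries in well map")
  }
  d
}

# Replicate a per-plate block of conditions across plates with sequential
# well labels; `conds` is a data.frame of well_map() columns minus plate/well.
expand_design <- function(conds, wells_per_condition, plates) {
  per_plate <- conds[rep(seq_len(nrow(conds)), each = wells_per_condition), ,
                     drop = FALSE]
  per_plate$well <- sprintf("W%03d", seq_len(nrow(per_plate)))
  out <- do.call(rbind, lapply(plates, function(p) {
    blk <- per_plate
    blk$plate <- p
    blk
  }))
  rownames(out) <- NULL
  do.call(well_map, out[c("plate", "well",
                          setdiff(names(out), c("plate", "well")))])
}

# Single place that defines the condition columns simulate_plate understands.
design_columns <- function() {
  c("plate", "well", "insulin_nM", "time_min", "inhibitor", "inhibitor_dose",
    "resist_agent", "resist_dose", "sirna", "cell_line", "effect_glut4",
    "effect_tfr", "effect_cells", "effect_droplets", "role")
}
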
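#' Configuration for a synthetic screening plate
#'
#' Bundles every generating parameter of the per-cell intensity model used by
#' [simulate_plate()] and [simulate_timecourse()]. The model is, per well:
#' a true adipocyte mean response (Hill in insulin dose, optionally suppressed
#' by an inhibitor or an insulin-resistance agent, optionally on a one-phase
#' time-course), multiplied by lognormal per-cell noise with mean exactly 1
#' and coefficient of variation `cell_cv`, then passed through one
#' multiplicative gain and one additive offset per plate, plus optional
#' non-negative read noise. Fibroblasts (fraction `1 - adipocyte_fraction`)
#' draw from the basal distribution regardless of insulin and from the
#' low-lipid-scatter distribution.
#'
#' @param n_plates number of plates (each plate carries the full design).
#' @param wells_per_condition replicate wells per condition per plate.
#' @param cells_per_well mean of the Poisson draw of cells per well.
#' @param adipocyte_fraction probability a cell is a differentiated adipocyte.
#' @param basal_mean,insulin_max_mean true unstimulated / saturating GLUT4
#'   surface means (arbitrary fluorescence units, AFU).
#' @param hill_ec50 insulin EC50 of the GLUT4 response (nM).
#' @param cell_cv coefficient of variation of the lognormal per-cell noise.
#' @param plate_gain_sd SD (log scale) of the per-plate multiplicative gain.
#' @param plate_offset_sd SD (AFU) of the per-plate additive offset.
#' @param read_noise_sd SD of additive half-normal read noise (AFU).
#' @param fibroblast_scatter_mean,adipocyte_scatter_mean,scatter_sd parameters
#'   of the lipid-scatter score distributions (unitless, truncated at 0).
#' @param tfr_basal_mean,tfr_max_mean,tfr_ec50 TfR channel analogues of the
#'   GLUT4 response parameters. Defaults place basal TfR at 35% of its
#'   insulin maximum, the behaviour expected of the recycling pathway.
#' @param glut4_halftime named numeric vector of one-phase half-times
#'   (minutes) keyed by insulin dose (as character), used when the design has
#'   time points; `NULL` if the design is steady-state.
#' @param tfr_halftime single TfR half-time in minutes (the TfR pathway is
#'   faster and its half-time is treated as dose-independent here).
#' @param inhibitor_ic50 named numeric vector of inhibitor IC50s (same units
#'   as the inhibitor doses in the design).
#' @param resistance_ic50 named numeric vector of IC50s of insulin-resistance
#'   agents (chronic insulin in nM, TNF in ng/ml, ...).
#' @param fields_per_well imaging fields per well (cells are assigned
#'   round-robin).
#' @param droplet_lambda Poisson mean of per-adipocyte lipid droplet counts.
#' @param droplet_area_mean mean area of a single droplet (arbitrary units);
#'   a cell's total droplet area is gamma with shape = droplet count.
#' @param total_reporter_mean mean of an insulin-independent total-reporter
#'   channel (for surface/total ratios), or `NULL` to omit the column.
#' @param seed integer seed; all randomness in the generators is scoped to it.
#'
#' @return an object of class `plate_sim_config` (a validated list).
#' @seealso [preset()] for configurations parameterized from published values.
#' @export
plate_sim_config <- function(n_plates = 2L,
                             wells_per_condition = 4L,
                             cells_per_well = 550,
                             adipocyte_fraction = 0.9,
                             basal_mean = 100,
                             insulin_max_mean = 500,
                             hill_ec50 = 0.86,
                             cell_cv = 0.35,
                             plate_gain_sd = 0.1,
                             plate_offset_sd = 2,
                             read_noise_sd = 0,
                             fibroblast_scatter_mean = 0.2,
                             adipocyte_scatter_mean = 0.9,
                             scatter_sd = 0.1,
                             tfr_basal_mean = 0.35 * insulin_max_mean,
                             tfr_max_mean = insulin_max_mean,
                             tfr_ec50 = hill_ec50,
                             glut4_halftime = NULL,
                             tfr_halftime = NULL,
                             inhibitor_ic50 = NULL,
                             resistance_ic50 = NULL,
                             fields_per_well = 4L,
                             droplet_lambda = 12,
                             droplet_area_mean = 40,
                             total_reporter_mean = NULL,
                             seed = 1L) {
  cfg <- list(
    n_plates = as.integer(n_plates),
    wells_per_condition = as.integer(wells_per_condition),
    cells_per_well = cells_per_well,
    adipocyte_fraction = adipocyte_fraction,
    basal_mean = basal_mean,
    insulin_max_mean = insulin_max_mean,
    hill_ec50 = hill_ec50,
    cell_cv = cell_cv,
    plate_gain_sd = plate_gain_sd,
    plate_offset_sd = plate_offset_sd,
    read_noise_sd = read_noise_sd,
    fibroblast_scatter_mean = fibroblast_scatter_mean,
    adipocyte_scatter_mean = adipocyte_scatter_mean,
    scatter_sd = scatter_sd,
    tfr_basal_mean = tfr_basal_mean,
    tfr_max_mean = tfr_max_mean,
    tfr_ec50 = tfr_ec50,
    glut4_halftime = glut4_halftime,
    tfr_halftime = tfr_halftime,
    inhibitor_ic50 = inhibitor_ic50,
    resistance_ic50 = resistance_ic50,
    fields_per_well = as.integer(fields_per_well),
    droplet_lambda = droplet_lambda,
    droplet_area_mean = droplet_area_mean,
    total_reporter_mean = total_reporter_mean,
    seed = as.integer(seed)
  )
  validate_plate_sim_config(cfg)
  class(cfg) <- "plate_sim_config"
  cfg
}

validate_plate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_plates >= 1L,
    cfg$wells_per_condition >= 1L,
    cfg$cells_per_well >= 1,
    cfg$adipocyte_fraction >= 0, cfg$adipocyte_fraction <= 1,
    cfg$hill_ec50 > 0,
    cfg$cell_cv >= 0,
    cfg$plate_gain_sd >= 0,
    cfg$plate_offset_sd >= 0,
    cfg$read_noise_sd >= 0,
    cfg$fields_per_well >= 1L
  )
  if (!(cfg$insulin_max_mean > cfg$basal_mean)) {
    stop("insulin_max_mean must exceed basal_mean")
  }
  if (!(cfg$tfr_max_mean > cfg$tfr_basal_mean)) {
    stop("tfr_max_mean must exceed tfr_basal_mean")
  }
  invisible(cfg)
}

#' @export
print.plate_sim_config <- function(x, ...) {
  cat("<plate_sim_config>\n")
  cat(sprintf("  %d plate(s), %d well(s)/condition, ~%g cells/well (%.0f%% adipocytes)\n",
              x$n_plates, x$wells_per_condition, x$cells_per_well,
              100 * x$adipocyte_fraction))
  cat(sprintf("  GLUT4: basal %g, max %g AFU, EC50 %g; TfR: basal %g, max %g, EC50 %g\n",
              x$basal_mean, x$insulin_max_mean, x$hill_ec50,
              x$tfr_basal_mean, x$tfr_max_mean, x$tfr_ec50))
  cat(sprintf("  noise: cell CV %g, plate gain SD %g, offset SD %g; seed %d\n",
              x$cell_cv, x$plate_gain_sd, x$plate_offset_sd, x$seed))
  invisible(x)
}

#' Configuration for a synthetic AP-MS protein-groups experiment
#'
#' Parameterizes [simulate_ipms()]. Each protein has a background log2-LFQ
#' abundance; a fraction of proteins are bait-enriched (specific interactors),
#' and a subset of those additionally gain `insulin_delta_log2` in the
#' bait-insulin samples (the planted "insulin-regulated" truth set). Values
#' are independently censored with an intensity-dependent (MNAR) logistic
#' dropout, and a small fraction of background rows carry the MaxQuant QC
#' flags so downstream filters are exercised.
#'
#' Nonspecific background binding in pulldowns is notoriously variable
#' between replicates, while specific bait interactions are stoichiometric
#' and reproducible; the generator therefore uses a larger replicate SD for
#' background signal (`background_rep_sd`) than for specific bait signal
#' (`replicate_sd`).
#'
#' @param n_proteins number of protein groups.
#' @param n_replicates replicates per (bait/IgG x basal/insulin) cell;
#'   must be >= 2.
#' @param background_log2_mean,background_log2_sd distribution of per-protein
#'   background abundance (log2 LFQ units).
#' @param replicate_sd replicate SD (log2) of specific bait signal.
#' @param background_rep_sd replicate SD (log2) of nonspecific signal.
#' @param enriched_fraction fraction of proteins that are bait interactors
#'   (includes the regulated subset).
#' @param enrichment_log2_effect bait-over-background log2 effect of
#'   interactors.
#' @param regulated_fraction fraction of proteins whose bait binding is
#'   insulin-regulated (a subset of the enriched ones).
#' @param insulin_delta_log2 extra bait log2 effect in insulin samples for
#'   the regulated subset.
#' @param dropout_midpoint log2 intensity at which dropout probability is 0.5.
#' @param dropout_slope steepness of the logistic dropout,
#'   `P(missing) = plogis(dropout_slope * (dropout_midpoint - log2 x))`.
#'   Larger values give a sharper detection limit; `Inf` gives a hard cutoff.
#' @param flag_fraction fraction of background rows flagged as each of
#'   Reverse / Potential contaminant / Only identified by site.
#' @param seed integer seed.
#'
#' @return an object of class `ipms_sim_config`.
#' @export
ipms_sim_config <- function(n_proteins = 1000L,
                            n_replicates = 3L,
                            background_log2_mean = 25,
                            background_log2_sd = 2,
                            replicate_sd = 0.3,
                            background_rep_sd = 0.8,
                            enriched_fraction = 0.05,
                            enrichment_log2_effect = 4,
                            regulated_fraction = 0.03,
                            insulin_delta_log2 = 3,
                            dropout_midpoint = 21.5,
                            dropout_slope = 1,
                            flag_fraction = 0.02,
                            seed = 11L) {
  cfg <- list(
    n_proteins = as.integer(n_proteins),
    n_replicates = as.integer(n_replicates),
    background_log2_mean = background_log2_mean,
    background_log2_sd = background_log2_sd,
    replicate_sd = replicate_sd,
    background_rep_sd = background_rep_sd,
    enriched_fraction = enriched_fraction,
    enrichment_log2_effect = enrichment_log2_effect,
    regulated_fraction = regulated_fraction,
    insulin_delta_log2 = insulin_delta_log2,
    dropout_midpoint = dropout_midpoint,
    dropout_slope = dropout_slope,
    flag_fraction = flag_fraction,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_proteins >= 1L,
    cfg$enriched_fraction >= 0, cfg$enriched_fraction <= 1,
    cfg$regulated_fraction >= 0,
    cfg$regulated_fraction <= cfg$enriched_fraction,
    cfg$dropout_slope > 0,
    cfg$flag_fraction >= 0, cfg$flag_fraction < 1
  )
  if (cfg$n_replicates < 2L) {
    stop("n_replicates must be >= 2 in at least one condition; ",
         "downstream imputation is undefined otherwise")
  }
  class(cfg) <- "ipms_sim_config"
  cfg
}

#' @export
print.ipms_sim_config <- function(x, ...) {
  cat("<ipms_sim_config>\n")
  cat(sprintf("  %d proteins x %d replicates per (bait/IgG x basal/insulin)\n",
              x$n_proteins, x$n_replicates))
  cat(sprintf("  background log2 ~ N(%g, %g); enrichment +%g log2 (%.0f%% of rows),\n",
              x$background_log2_mean, x$background_log2_sd,
              x$enrichment_log2_effect, 100 * x$enriched_fraction))
  cat(sprintf("  insulin delta +%g log2 (%.0f%%); dropout mid %g slope %g; seed %d\n",
              x$insulin_delta_log2, 100 * x$regulated_fraction,
              x$dropout_midpoint, x$dropout_slope, x$seed))
  invisible(x)
}
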
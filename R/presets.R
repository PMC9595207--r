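#' Named generator presets parameterized from published assay behaviour
#'
#' Returns a fully populated simulation configuration whose generating
#' parameters equal characteristic published values of the endogenous
#' GLUT4/TfR translocation assay, so that running the full downstream
#' pipeline on the generated data should recover those values:
#'
#' \describe{
#'   \item{`fig1a`}{basal vs 100 nM insulin; fivefold stimulation of surface
#'     GLUT4 (basal 100 AFU, max 500 AFU).}
#'   \item{`fig1e`}{insulin dose-response, EC50 = 0.860 nM; 8 doses spanning
#'     0.01-100 nM plus 0, ~2000 adipocytes per dose across 2 plates.}
#'   \item{`fig1g`}{stimulation time-courses; GLUT4 half-times 7.5 min at
#'     100 nM and 9.5 min at 1 nM insulin; 8 time points over 0-40 min
#'     (`$times`).}
#'   \item{`fig1h`}{signalling-inhibitor dose-responses at 100 nM insulin;
#'     IC50s: GDC0941 (PI3K) 8 nM, MK2206 (Akt) 183 nM, GSK23344 (PDPK1)
#'     289 nM, GDC0068 (Akt) 121 nM; 7 doses per arm (IC50 x 4^(-3..3))
#'     plus vehicle.}
#'   \item{`fig2c`}{chronic-insulin (CI) resistance model; CI IC50 0.17 nM
#'     against the 1 nM acute-insulin response; 6 CI doses plus vehicle.}
#'   \item{`fig2e`}{TNF resistance model; IC50 0.18 ng/ml against the 1 nM
#'     acute-insulin response.}
#'   \item{`fig4d`}{dual-channel kinetics; basal TfR 35% and basal GLUT4
#'     6.5% of the insulin-stimulated maximum; half-times 3 min (TfR) and
#'     9 min (GLUT4) at 100 nM insulin; plate offset 0 because
#'     percent-of-max ratios presuppose background-subtracted intensities.}
#'   \item{`fig6_screen`}{siRNA knockdown screen with non-targeting controls
#'     and planted per-readout effect multipliers (see the config's
#'     `$screen_effects`), at 0 and 100 nM insulin.}
#'   \item{`ipms_default`}{bait-vs-IgG AP-MS with three biological
#'     replicates per condition, 5% bait interactors of which 3% points are
#'     insulin-regulated, and MNAR dropout.}
#' }
#'
#' Plate presets carry a ready-made `$design` well map (and `$times` where
#' kinetic); pass them straight to [simulate_plate()] /
#' [simulate_timecourse()].
#'
#' @param name one of `"fig1a"`, `"fig1e"`, `"fig1g"`, `"fig1h"`, `"fig2c"`,
#'   `"fig2e"`, `"fig4d"`, `"fig6_screen"`, `"ipms_default"`.
#' @param seed optional seed overriding the preset default.
#' @return a [plate_sim_config()] or [ipms_sim_config()], possibly with
#'   extra elements `design`, `times`, `doses`, `screen_effects`.
#' @export
preset <- function(name, seed = NULL) {
  known <- c("fig1a", "fig1e", "fig1g", "fig1h", "fig2c", "fig2e", "fig4d",
             "fig6_screen", "ipms_default")
  if (!is.character(name) || length(name) != 1L || !name %in% known) {
    stop("unknown preset '", name, "'; available: ",
         paste(known, collapse = ", "))
  }
  cfg <- switch(name,
    fig1a = {
      c0 <- plate_sim_config(n_plates = 1L, seed = 2L,
                             basal_mean = 100, insulin_max_mean = 500)
      conds <- data.frame(insulin_nM = c(0, 100),
                          role = c("control_basal", "control_max"))
      c0$design <- expand_design(conds, c0$wells_per_condition, "P1")
      c0
    },
    fig1e = {
      c0 <- plate_sim_config(n_plates = 2L, seed = 1L, hill_ec50 = 0.860,
                             basal_mean = 100, insulin_max_mean = 500)
      doses <- c(0, 0.01, 0.03, 0.1, 0.3, 1, 3, 10, 100)
      conds <- data.frame(
        insulin_nM = doses,
        role = ifelse(doses == 0, "control_basal",
                      ifelse(doses == 100, "control_max", "sample")))
      c0$design <- expand_design(conds, c0$wells_per_condition,
                                 paste0("P", 1:2))
      c0$doses <- doses
      c0
    },
    fig1g = {
      c0 <- plate_sim_config(n_plates = 1L, seed = 4L,
                             basal_mean = 100, insulin_max_mean = 500,
                             glut4_halftime = c("100" = 7.5, "1" = 9.5))
      c0$times <- c(0, 1, 2.5, 5, 7.5, 10, 20, 40)
      c0
    },
    fig1h = {
      ic50 <- c(GDC0941 = 8, MK2206 = 183, GSK23344 = 289, GDC0068 = 121)
      c0 <- plate_sim_config(n_plates = 2L, seed = 2L,
                             basal_mean = 100, insulin_max_mean = 500,
                             inhibitor_ic50 = ic50)
      arms <- do.call(rbind, lapply(names(ic50), function(inh) {
        data.frame(insulin_nM = 100, inhibitor = inh,
                   inhibitor_dose = ic50[[inh]] * 4^(-3:3),
                   role = "sample")
      }))
      ctrl <- data.frame(insulin_nM = c(0, 100), inhibitor = NA_character_,
                         inhibitor_dose = 0,
                         role = c("control_basal", "control_max"))
      c0$design <- expand_design(rbind(ctrl, arms), c0$wells_per_condition,
                                 paste0("P", 1:2))
      c0
    },
    fig2c = resistance_preset("CI", ic50 = 0.17, seed = 8L),
    fig2e = resistance_preset("TNF", ic50 = 0.18, seed = 8L),
    fig4d = {
      c0 <- plate_sim_config(n_plates = 1L, seed = 5L,
                             basal_mean = 32.5, insulin_max_mean = 500,
                             tfr_basal_mean = 175, tfr_max_mean = 500,
                             plate_offset_sd = 0,
                             glut4_halftime = c("100" = 9),
                             tfr_halftime = 3)
      conds <- data.frame(insulin_nM = c(0, 100),
                          role = c("control_basal", "control_max"))
      c0$design <- expand_design(conds, c0$wells_per_condition, "P1")
      c0$times <- c(0, 1, 2.5, 5, 7.5, 10, 20, 40)
      c0
    },
    fig6_screen = {
      effects <- list(
        NT      = c(glut4 = 1,   tfr = 1,    cells = 1,   droplets = 1),
        Rab10   = c(glut4 = 0.4, tfr = 0.9,  cells = 1,   droplets = 1),
        Tfrc    = c(glut4 = 1,   tfr = 0.15, cells = 1,   droplets = 1),
        Akt1.2  = c(glut4 = 0.5, tfr = 0.7,  cells = 1,   droplets = 1),
        Dgat1   = c(glut4 = 0.9, tfr = 1,    cells = 1,   droplets = 0.4),
        Polr2a  = c(glut4 = 1,   tfr = 1,    cells = 0.5, droplets = 1)
      )
      c0 <- plate_sim_config(n_plates = 2L, wells_per_condition = 3L,
                             seed = 9L, basal_mean = 100,
                             insulin_max_mean = 500)
      conds <- do.call(rbind, lapply(names(effects), function(tg) {
        e <- effects[[tg]]
        data.frame(insulin_nM = c(0, 100), sirna = tg,
                   effect_glut4 = e[["glut4"]], effect_tfr = e[["tfr"]],
                   effect_cells = e[["cells"]], effect_droplets = e[["droplets"]],
                   role = if (tg == "NT") c("control_basal", "control_max")
                          else "sample")
      }))
      c0$design <- expand_design(conds, c0$wells_per_condition,
                                 paste0("P", 1:2))
      c0$screen_effects <- effects
      c0
    },
    ipms_default = ipms_sim_config(seed = 11L)
  )
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

# Shared scaffold of the insulin-resistance dose-response presets: samples
# read out at 1 nM acute insulin after agent pre-treatment; anchors are
# untreated 0 and 100 nM insulin wells.
resistance_preset <- function(agent, ic50, seed) {
  c0 <- plate_sim_config(n_plates = 1L, seed = seed,
                         basal_mean = 100, insulin_max_mean = 500,
                         resistance_ic50 = stats::setNames(ic50, agent))
  doses <- ic50 * 3^(-3:2)   # 6 doses bracketing (and including) the IC50
  arms <- data.frame(insulin_nM = 1, resist_agent = agent,
                     resist_dose = c(0, doses), role = "sample")
  ctrl <- data.frame(insulin_nM = c(0, 100), resist_agent = NA_character_,
                     resist_dose = 0,
                     role = c("control_basal", "control_max"))
  c0$design <- expand_design(rbind(ctrl, arms), c0$wells_per_condition, "P1")
  c0$doses <- doses
  c0
}
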
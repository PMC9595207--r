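# Shared fixtures: small, fast configurations built in code.

# Noise-free plate config: every stochastic knob off, adipocytes only.
noisefree_config <- function(...) {
  args <- utils::modifyList(
    list(n_plates = 1L, wells_per_condition = 1L, cells_per_well = 200,
         adipocyte_fraction = 1, cell_cv = 0, plate_gain_sd = 0,
         plate_offset_sd = 0, read_noise_sd = 0, seed = 1L),
    list(...))
  do.call(plate_sim_config, args)
}

# Small noisy config for property checks.
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_plates = 2L, wells_per_condition = 3L, cells_per_well = 120,
         seed = 1L),
    list(...))
  do.call(plate_sim_config, args)
}

one_well_design <- function(insulin_nM, plate = "P1", ...) {
  well_map(plate = plate, well = sprintf("W%03d", seq_along(insulin_nM)),
           insulin_nM = insulin_nM, ...)
}

# Independent brute-force Benjamini-Hochberg step-up: for the k-th smallest
# p, the adjusted value is min over j >= k of n * p_(j) / j, capped at 1;
# NA p-values stay NA and do not count toward the step-up's m.
bh_step_up <- function(p, n = sum(!is.na(p))) {
  out <- rep(NA_real_, length(p))
  idx <- which(!is.na(p))
  ps <- p[idx]
  o <- order(ps)
  lp <- length(ps)
  adj <- numeric(lp)
  for (k in seq_len(lp)) {
    adj[k] <- min(1, min(n * ps[o][k:lp] / (k:lp)))
  }
  tmp <- numeric(lp)
  tmp[o] <- adj
  out[idx] <- tmp
  out
}

# Minimal enrichment_result for classifier unit tests.
fake_enrichment <- function(delta, fc_basal, fc_insulin, p_basal, p_insulin) {
  res <- data.frame(
    protein_id = sprintf("P%d", seq_along(delta)),
    log2fc_basal = fc_basal, log2fc_insulin = fc_insulin,
    t_basal = NA_real_, t_insulin = NA_real_,
    p_basal = p_basal, p_insulin = p_insulin,
    degenerate_basal = FALSE, degenerate_insulin = FALSE,
    adj_p_basal = p_basal, adj_p_insulin = p_insulin,
    delta = delta, stringsAsFactors = FALSE)
  class(res) <- c("enrichment_result", "data.frame")
  res
}

# Construct a pg_experiment directly from a log2 matrix (NA = missing).
pg_from_matrix <- function(m, design, log2 = TRUE) {
  structure(list(ids = sprintf("P%04d", seq_len(nrow(m))),
                 intensity = m, design = design,
                 flags = data.frame(reverse = rep(FALSE, nrow(m)),
                                    contaminant = FALSE, site_only = FALSE),
                 log2 = log2, imputed = NULL),
            class = "pg_experiment")
}

trapezoid <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
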
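#' Three-parameter Hill response
#'
#' `R(d) = bottom + (top - bottom) * d / (ec50 + d)` (Hill slope fixed at 1).
#' Used both by the generators (forward model) and by users to evaluate
#' fitted curves. `hill_response(0, ...)` is exactly `bottom`.
#'
#' @param dose dose(s), same units as `ec50`; zero allowed.
#' @param bottom,top,ec50 curve parameters; `ec50 > 0`.
#' @return numeric vector of responses.
#' @export
hill_response <- function(dose, bottom, top, ec50) {
  stopifnot(ec50 > 0, all(dose >= 0))
  bottom + (top - bottom) * dose / (ec50 + dose)
}

#' One-phase association response
#'
#' `S(t) = s0 + (plateau - s0) * (1 - 2^(-t / halftime))`, i.e. the familiar
#' exponential approach parameterized by its half-time (`k = ln 2 / t1/2`).
#'
#' @param time time(s) >= 0 (minutes).
#' @param s0,plateau initial and asymptotic responses.
#' @param halftime half-time in minutes, > 0.
#' @return numeric vector of responses.
#' @export
one_phase_response <- function(time, s0, plateau, halftime) {
  if (!is.numeric(halftime) || halftime <= 0) stop("halftime must be > 0")
  stopifnot(all(time >= 0))
  s0 + (plateau - s0) * (1 - 2^(-time / halftime))
}

# True (noise-free) adipocyte mean for one design row and one channel.
# Order of effects: insulin Hill -> inhibitor -> resistance agent ->
# one-phase kinetics -> knockdown multiplier. Inhibitors and resistance
# agents suppress the insulin-stimulated increment, not the basal signal.
well_true_mean <- function(cfg, row, channel = c("glut4", "tfr")) {
  channel <- match.arg(channel)
  if (channel == "glut4") {
    basal <- cfg$basal_mean; top <- cfg$insulin_max_mean; ec50 <- cfg$hill_ec50
    effect <- row$effect_glut4
  } else {
    basal <- cfg$tfr_basal_mean; top <- cfg$tfr_max_mean; ec50 <- cfg$tfr_ec50
    effect <- row$effect_tfr
  }
  m <- hill_response(row$insulin_nM, basal, top, ec50)
  if (!is.na(row$inhibitor)) {
    ic <- cfg$inhibitor_ic50[[row$inhibitor]]
    if (is.null(ic)) {
      stop(sprintf("well %s/%s: unknown inhibitor '%s' (config knows: %s)",
                   row$plate, row$well, row$inhibitor,
                   paste(names(cfg$inhibitor_ic50), collapse = ", ")))
    }
    m <- basal + (m - basal) * ic / (ic + row$inhibitor_dose)
  }
  if (!is.na(row$resist_agent)) {
    ic <- cfg$resistance_ic50[[row$resist_agent]]
    if (is.null(ic)) {
      stop(sprintf("well %s/%s: unknown resistance agent '%s' (config knows: %s)",
                   row$plate, row$well, row$resist_agent,
                   paste(names(cfg$resistance_ic50), collapse = ", ")))
    }
    m <- basal + (m - basal) * ic / (ic + row$resist_dose)
  }
  if (!is.na(row$time_min)) {
    ht <- if (channel == "tfr" && !is.null(cfg$tfr_halftime)) {
      cfg$tfr_halftime
    } else {
      h <- cfg$glut4_halftime[[as.character(row$insulin_nM)]]
      if (is.null(h)) {
        stop(sprintf(
          "well %s/%s: no %s half-time registered for insulin dose %g nM",
          row$plate, row$well, channel, row$insulin_nM))
      }
      h
    }
    m <- one_phase_response(row$time_min, basal, m, ht)
  }
  m * effect
}

#' Simulate a per-cell measurement table for a plate design
#'
#' Draws a synthetic `CellTable` (one row per segmented cell) with the
#' statistical structure the downstream pipeline assumes: lognormal
#' (mean-1) per-cell noise around well-true means, one multiplicative gain
#' and one additive offset per plate, Poisson cell counts, a fibroblast
#' subpopulation that ignores insulin and carries a low lipid-scatter score,
#' and per-adipocyte lipid-droplet counts/areas. A `sim_truth` record with
#' the generating well means, plate effects and per-cell class labels is
#' returned alongside; regenerating with the same config is bit-identical.
#'
#' @param config a [plate_sim_config()].
#' @param design a [well_map()]; every well's condition must be understood by
#'   the response model (registered inhibitor / resistance-agent names, a
#'   registered half-time when `time_min` is set).
#' @return a list with elements `cells` (data.frame: plate, well, field,
#'   cell_id, glut4_surface, tfr_surface, lipid_scatter, total_reporter,
#'   droplet_count, droplet_area_total) and `truth` (class `sim_truth`:
#'   `wells`, `plates`, `cells`, plus the config).
#' @export
simulate_plate <- function(config, design) {
  stopifnot(inherits(config, "plate_sim_config"))
  missing_cols <- setdiff(design_columns(), names(design))
  if (length(missing_cols)) {
    stop("design is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  # Validate all conditions up front so errors name the offending well
  # before any random draw.
  truth_wells <- design
  truth_wells$glut4_mean <- vapply(seq_len(nrow(design)), function(i) {
    well_true_mean(config, design[i, ], "glut4")
  }, numeric(1))
  truth_wells$tfr_mean <- vapply(seq_len(nrow(design)), function(i) {
    well_true_mean(config, design[i, ], "tfr")
  }, numeric(1))

  plates <- unique(design$plate)
  sdlog <- sqrt(log1p(config$cell_cv^2))

  withr::with_seed(config$seed, {
    gain <- stats::setNames(
      exp(stats::rnorm(length(plates), 0, config$plate_gain_sd)), plates)
    offset <- stats::setNames(
      stats::rnorm(length(plates), 0, config$plate_offset_sd), plates)

    per_well <- lapply(seq_len(nrow(design)), function(i) {
      row <- design[i, ]
      n <- stats::rpois(1, config$cells_per_well * row$effect_cells)
      if (n == 0L) return(NULL)
      adipo <- stats::runif(n) < config$adipocyte_fraction
      g <- gain[[row$plate]]; o <- offset[[row$plate]]

      mean_g4 <- ifelse(adipo, truth_wells$glut4_mean[i], config$basal_mean)
      mean_tfr <- ifelse(adipo, truth_wells$tfr_mean[i], config$tfr_basal_mean)
      # lognormal multiplier with E = 1 exactly (meanlog = -sdlog^2/2)
      m1 <- stats::rlnorm(n, -sdlog^2 / 2, sdlog)
      m2 <- stats::rlnorm(n, -sdlog^2 / 2, sdlog)
      read1 <- if (config$read_noise_sd > 0) {
        abs(stats::rnorm(n, 0, config$read_noise_sd))
      } else 0
      read2 <- if (config$read_noise_sd > 0) {
        abs(stats::rnorm(n, 0, config$read_noise_sd))
      } else 0

      scatter <- pmax(0, stats::rnorm(
        n,
        ifelse(adipo, config$adipocyte_scatter_mean,
               config$fibroblast_scatter_mean),
        config$scatter_sd))
      total <- if (!is.null(config$total_reporter_mean)) {
        g * (config$total_reporter_mean *
               stats::rlnorm(n, -sdlog^2 / 2, sdlog)) + o
      } else NA_real_
      dcount <- ifelse(adipo,
                       stats::rpois(n, config$droplet_lambda *
                                      row$effect_droplets),
                       0L)
      darea <- ifelse(dcount > 0,
                      stats::rgamma(n, shape = pmax(dcount, 1e-12),
                                    scale = config$droplet_area_mean),
                      0)
      data.frame(
        plate = row$plate, well = row$well,
        field = rep_len(seq_len(config$fields_per_well), n),
        cell_id = sprintf("%s_%s_c%04d", row$plate, row$well, seq_len(n)),
        glut4_surface = g * (mean_g4 * m1) + o + read1,
        tfr_surface = g * (mean_tfr * m2) + o + read2,
        lipid_scatter = scatter,
        total_reporter = total,
        droplet_count = as.integer(dcount),
        droplet_area_total = darea,
        class = ifelse(adipo, "adipocyte", "fibroblast"),
        stringsAsFactors = FALSE
      )
    })
  })

  cells <- do.call(rbind, per_well)
  rownames(cells) <- NULL
  truth <- structure(list(
    wells = truth_wells,
    plates = data.frame(plate = plates, gain = unname(gain),
                        offset = unname(offset), stringsAsFactors = FALSE),
    cells = cells[c("plate", "well", "cell_id", "class")],
    config = config
  ), class = "sim_truth")
  cells$class <- NULL
  list(cells = cells, truth = truth)
}

#' Simulate a translocation time-course
#'
#' Convenience wrapper around [simulate_plate()] for one-phase association
#' kinetics: wells at the given insulin dose are sampled at each time in
#' `times`, with well true means
#' `S(t) = basal + (hill(insulin) - basal) * (1 - 2^(-t / halftime))`,
#' so `t = 0` wells sit exactly at the basal mean in the noise-free limit.
#'
#' @param config a [plate_sim_config()].
#' @param times vector of times in minutes (>= 0).
#' @param halftime GLUT4 half-time in minutes at this insulin dose.
#' @param insulin_nM acute insulin dose (default 100).
#' @param tfr_halftime optional TfR half-time; defaults to
#'   `config$tfr_halftime` (falling back to `halftime` if neither is set).
#' @return as [simulate_plate()].
#' @export
simulate_timecourse <- function(config, times, halftime, insulin_nM = 100,
                                tfr_halftime = config$tfr_halftime) {
  if (!is.numeric(halftime) || length(halftime) != 1L || halftime <= 0) {
    stop("halftime must be a single positive number of minutes")
  }
  stopifnot(all(times >= 0))
  config$glut4_halftime <- stats::setNames(halftime, as.character(insulin_nM))
  config$tfr_halftime <- if (is.null(tfr_halftime)) halftime else tfr_halftime
  conds <- data.frame(insulin_nM = insulin_nM, time_min = times)
  design <- expand_design(conds, config$wells_per_condition,
                          paste0("P", seq_len(config$n_plates)))
  simulate_plate(config, design)
}

#' Simulate a MaxQuant-style protein-groups table for a bait-vs-IgG AP-MS
#'
#' Generates log2 intensities per protein x sample from a background model
#' plus bait-enrichment and insulin-regulation effects (see
#' [ipms_sim_config()]), censors each value independently with probability
#' `plogis(dropout_slope * (dropout_midpoint - log2 intensity))` (missing not
#' at random), and flags a fraction of background rows as Reverse /
#' Potential contaminant / Only identified by site. Output uses the MaxQuant
#' proteinGroups dialect: linear-scale `LFQ intensity <sample>` columns with
#' 0 for missing, `"+"`-valued flag columns.
#'
#' @param config an [ipms_sim_config()].
#' @return list with `table` (proteinGroups data.frame), `design`
#'   (sample/group/condition/replicate data.frame) and `truth` (class
#'   `sim_truth`: per-protein class, true effects, the pre-dropout log2
#'   matrix, and the planted regulated set).
#' @export
simulate_ipms <- function(config) {
  stopifnot(inherits(config, "ipms_sim_config"))
  n <- config$n_proteins
  reps <- config$n_replicates
  design <- expand.grid(replicate = seq_len(reps),
                        condition = c("basal", "insulin"),
                        group = c("bait", "IgG"),
                        stringsAsFactors = FALSE)
  design$sample <- sprintf("%s_%s_%d", design$group, design$condition,
                           design$replicate)
  design <- design[c("sample", "group", "condition", "replicate")]

  n_enr <- round(config$enriched_fraction * n)
  n_reg <- min(round(config$regulated_fraction * n), n_enr)
  if (config$enrichment_log2_effect == 0) {
    # no bait effect means no planted interactors (and hence no regulated set)
    n_enr <- n_reg <- 0L
  }

  withr::with_seed(config$seed, {
    mu <- stats::rnorm(n, config$background_log2_mean, config$background_log2_sd)
    cls <- rep("background", n)
    if (n_enr > 0) cls[sample.int(n, n_enr)] <- "enriched"
    enr_idx <- which(cls == "enriched")
    if (n_reg > 0) cls[sample(enr_idx, n_reg)] <- "regulated"
    is_int <- cls %in% c("enriched", "regulated")

    true_log2 <- matrix(NA_real_, n, nrow(design),
                        dimnames = list(NULL, design$sample))
    for (j in seq_len(nrow(design))) {
      base <- mu
      specific <- is_int & design$group[j] == "bait"
      base <- base + ifelse(specific, config$enrichment_log2_effect, 0)
      base <- base + ifelse(specific & cls == "regulated" &
                              design$condition[j] == "insulin",
                            config$insulin_delta_log2, 0)
      sds <- ifelse(specific, config$replicate_sd, config$background_rep_sd)
      true_log2[, j] <- stats::rnorm(n, base, sds)
    }
    p_miss <- stats::plogis(config$dropout_slope *
                              (config$dropout_midpoint - true_log2))
    miss <- matrix(stats::runif(length(true_log2)) < p_miss,
                   nrow = n, dimnames = dimnames(true_log2))

    flags <- matrix(FALSE, n, 3,
                    dimnames = list(NULL, c("Reverse", "Potential contaminant",
                                            "Only identified by site")))
    bg_idx <- which(cls == "background")
    n_flag <- round(config$flag_fraction * n)
    if (n_flag > 0 && length(bg_idx) >= 3 * n_flag) {
      pick <- sample(bg_idx, 3 * n_flag)
      flags[pick[seq_len(n_flag)], 1] <- TRUE
      flags[pick[n_flag + seq_len(n_flag)], 2] <- TRUE
      flags[pick[2 * n_flag + seq_len(n_flag)], 3] <- TRUE
    }
  })

  lfq <- 2^true_log2
  lfq[miss] <- 0
  ids <- sprintf("PROT%04d", seq_len(n))
  tab <- data.frame(`Protein IDs` = ids, check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (s in design$sample) tab[[paste("LFQ intensity", s)]] <- lfq[, s]
  tab$Reverse <- ifelse(flags[, 1], "+", "")
  tab$`Potential contaminant` <- ifelse(flags[, 2], "+", "")
  tab$`Only identified by site` <- ifelse(flags[, 3], "+", "")

  truth <- structure(list(
    proteins = data.frame(protein_id = ids, class = cls, background_log2 = mu,
                          stringsAsFactors = FALSE),
    regulated = ids[cls == "regulated"],
    enriched = ids[cls %in% c("enriched", "regulated")],
    complete_log2 = true_log2,
    missing = miss,
    config = config
  ), class = "sim_truth")
  list(table = tab, design = design, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth>\n")
  for (nm in setdiff(names(x), "config")) {
    obj <- x[[nm]]
    if (is.data.frame(obj)) {
      cat(sprintf("  $%s: %d x %d data.frame\n", nm, nrow(obj), ncol(obj)))
    } else if (is.matrix(obj)) {
      cat(sprintf("  $%s: %d x %d matrix\n", nm, nrow(obj), ncol(obj)))
    } else {
      cat(sprintf("  $%s: %s\n", nm, paste(utils::head(obj, 3), collapse = ", ")))
    }
  }
  invisible(x)
}
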
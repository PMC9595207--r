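test_that("density of a standard normal peaks at 0 and integrates to 1", {
  # the mode estimate of a single 10k draw is itself noisy, so check the
  # location property on the average over replicate draws
  peaks <- withr::with_seed(101L, replicate(10, {
    d <- density_estimate(rnorm(10000))
    expect_lt(abs(trapezoid(d$x, d$y) - 1), 1e-3)
    expect_true(all(d$y >= 0))
    d$peak
  }))
  expect_lt(abs(mean(peaks)), 0.1)
})

test_that("bimodal mixtures show local maxima near the component means", {
  x <- withr::with_seed(102L, c(rnorm(5000, 0), rnorm(5000, 4)))
  d <- density_estimate(x)
  pk <- density_peaks(d)
  expect_length(pk, 2L)
  expect_lt(abs(pk[1] - 0), d$bw)
  expect_lt(abs(pk[2] - 4), d$bw)
})

test_that("density estimation refuses unreliable input", {
  expect_error(density_estimate(rnorm(20)), ">= 50")
  expect_error(density_estimate(rep(1, 100)), "identical")
})

test_that("shift metric anchors at 0/1 and is affine invariant", {
  withr::with_seed(8L, {
    basal <- rnorm(500, 10, 1)
    maxc <- rnorm(500, 20, 1)
    cond <- rnorm(500, 15, 1)
  })
  expect_equal(shift_metric(basal, basal, maxc), 0)
  expect_equal(shift_metric(maxc, basal, maxc), 1)
  m <- shift_metric(cond, basal, maxc)
  m_aff <- shift_metric(3 * cond - 7, 3 * basal - 7, 3 * maxc - 7)
  expect_equal(m_aff, m)
  expect_error(shift_metric(numeric(0), basal, maxc), "nonempty")
  expect_error(shift_metric(cond, basal, basal), "degenerate")
})

test_that("a resistance dose at the IC50 halves the population shift", {
  cfg <- preset("fig2c")
  sim <- simulate_plate(cfg, cfg$design)
  gated <- apply_gate(sim$cells, gate_adipocytes(sim$cells,
                                                 design = cfg$design))
  d <- cfg$design
  pick <- function(rows) {
    gated$glut4_surface[paste(gated$plate, gated$well) %in%
                          paste(rows$plate, rows$well)]
  }
  ic50 <- cfg$resistance_ic50[["CI"]]
  at_ic50 <- pick(d[!is.na(d$resist_agent) &
                      abs(d$resist_dose - ic50) < 1e-12, ])
  vehicle <- pick(d[!is.na(d$resist_agent) & d$resist_dose == 0, ])
  basal <- pick(d[d$role == "control_basal", ])
  m <- shift_metric(at_ic50, basal, vehicle)
  expect_lt(abs(m - 0.5), 0.05)
})

test_that("screen summaries recover planted knockdown effects as FOC", {
  cfg <- preset("fig6_screen")
  sim <- simulate_plate(cfg, cfg$design)
  gated <- apply_gate(sim$cells, gate_adipocytes(sim$cells,
                                                 design = cfg$design))
  normed <- plate_normalize(gated, cfg$design, "glut4_surface")
  normed <- plate_normalize(normed, cfg$design, "tfr_surface")
  sc <- summarize_screen(normed, cfg$design)
  g4 <- sc[sc$readout == "glut4_surface" & sc$insulin_nM == 100, ]
  expect_equal(g4$foc[g4$target == "NT"], 1, tolerance = 1e-12)
  expect_lt(abs(g4$foc[g4$target == "Rab10"] - 0.4) / 0.4, 0.10)
  tfr <- sc[sc$readout == "tfr_surface" & sc$insulin_nM == 100, ]
  expect_lt(abs(tfr$foc[tfr$target == "Tfrc"] - 0.15), 0.05)
  nuc <- sc[sc$readout == "nuclei" & sc$insulin_nM == 0, ]
  expect_lt(abs(nuc$foc[nuc$target == "Polr2a"] - 0.5) / 0.5, 0.15)
  # knockdowns with real effects are detected, the inert one is not
  expect_lt(g4$adj_p[g4$target == "Rab10"], 0.05)
})

test_that("missing readout columns are skipped with a warning", {
  cfg <- preset("fig6_screen")
  sim <- simulate_plate(cfg, cfg$design)
  slim <- sim$cells[setdiff(names(sim$cells),
                            c("droplet_count", "droplet_area_total"))]
  w <- testthat::capture_warnings(sc <- summarize_screen(slim, cfg$design))
  expect_true(any(grepl("droplet_count", w)))
  expect_false("droplet_count" %in% sc$readout)
  expect_true("glut4_surface" %in% sc$readout)
})

test_that("FOC is invariant to the plate gain the generator applies", {
  base <- preset("fig6_screen")
  gainy <- base; gainy$plate_gain_sd <- 0.3
  foc_for <- function(cfg) {
    sim <- simulate_plate(cfg, cfg$design)
    gated <- apply_gate(sim$cells, gate_adipocytes(sim$cells,
                                                   design = cfg$design))
    normed <- plate_normalize(gated, cfg$design, "glut4_surface")
    sc <- summarize_screen(normed, cfg$design, readouts = "glut4_surface")
    sc$foc[sc$target == "Rab10" & sc$insulin_nM == 100]
  }
  expect_lt(abs(foc_for(base) - foc_for(gainy)), 0.05)
})

test_that("simple linear regression of cross-line effects", {
  a <- data.frame(target = c("t1", "t2", "t3"), foc = c(1, 2, 3))
  b <- data.frame(target = c("t1", "t2", "t3"), foc = c(2, 4, 6))
  r <- suppressWarnings(crossline_correlation(a, b))  # exact fit: lm warns
  expect_equal(r$slope, 2)
  expect_equal(r$r_squared, 1)
  flat <- data.frame(target = c("t1", "t2", "t3"), foc = c(1, 1, 1))
  a2 <- data.frame(target = c("t1", "t2", "t3"), foc = c(0, 1, 2))
  r2 <- suppressWarnings(crossline_correlation(a2, flat))
  expect_equal(r2$slope, 0)
  expect_equal(r2$r_squared, 0)
  expect_error(crossline_correlation(a[1:2, ], b[1:2, ]), ">= 3")
})

test_that("a shrunk sister screen regresses with the shrinkage slope", {
  effects_a <- c(NT = 1, g1 = 0.3, g2 = 0.5, g3 = 0.7, g4 = 0.9,
                 g5 = 1.15, g6 = 1.3)
  s <- 0.5
  screen_cfg <- function(effects, seed) {
    cfg <- plate_sim_config(n_plates = 1L, wells_per_condition = 3L,
                            cells_per_well = 250, seed = seed)
    conds <- do.call(rbind, lapply(names(effects), function(tg) {
      data.frame(insulin_nM = c(0, 100), sirna = tg,
                 effect_glut4 = effects[[tg]],
                 role = if (tg == "NT") c("control_basal", "control_max")
                        else "sample")
    }))
    cfg$design <- traffiq:::expand_design(conds, 3L, "P1")
    cfg
  }
  foc_tab <- function(cfg) {
    sim <- simulate_plate(cfg, cfg$design)
    gated <- apply_gate(sim$cells, gate_adipocytes(sim$cells,
                                                   design = cfg$design))
    normed <- plate_normalize(gated, cfg$design, "glut4_surface")
    sc <- summarize_screen(normed, cfg$design, readouts = "glut4_surface")
    sc[sc$insulin_nM == 100, c("target", "foc")]
  }
  ca <- screen_cfg(effects_a, seed = 10L)
  cb <- screen_cfg(1 + s * (effects_a - 1), seed = 1010L)
  r <- crossline_correlation(foc_tab(ca), foc_tab(cb))
  expect_lt(abs(r$slope - s) / s, 0.15)
  expect_gt(r$r_squared, 0.9)
})

test_that("lipid droplet summaries aggregate wells then conditions", {
  cells <- data.frame(plate = "P1", well = c("A1", "A1"),
                      droplet_count = c(3L, 5L),
                      droplet_area_total = c(30, 60))
  d <- well_map(plate = "P1", well = "A1")
  ls <- lipid_summaries(cells, d)
  expect_equal(ls$well_total_mean, 8)
  expect_equal(ls$droplet_count_mean, 4)
  expect_equal(ls$droplet_area_mean, mean(c(10, 12)))
  expect_error(lipid_summaries(cells[1:2], d), "droplet")
  # planted droplet knockdown shows up in generated condition means
  cfg <- preset("fig6_screen")
  sim <- simulate_plate(cfg, cfg$design)
  gated <- apply_gate(sim$cells,
                      gate_adipocytes(sim$cells, design = cfg$design))
  lg <- lipid_summaries(gated, cfg$design, by = "sirna")
  ratio <- lg$droplet_count_mean[lg$sirna == "Dgat1"] /
    lg$droplet_count_mean[lg$sirna == "NT"]
  expect_lt(abs(ratio - 0.4), 0.05)
})
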
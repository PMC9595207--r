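# Build a two-plate table whose control medians are exactly the worked
# anchors: plate A med0 = 100, med100 = 500; plate B med0 = 120, med100 = 600.
anchored_fixture <- function() {
  cells <- data.frame(
    plate = c("A", "A", "A", "B", "B"),
    well = c("c0", "c100", "s", "c0", "c100"),
    field = 1L, cell_id = sprintf("c%d", 1:5),
    glut4_surface = c(100, 500, 300, 120, 600),
    stringsAsFactors = FALSE)
  design <- well_map(
    plate = c("A", "A", "A", "B", "B"),
    well = c("c0", "c100", "s", "c0", "c100"),
    insulin_nM = c(0, 100, 10, 0, 100),
    role = c("control_basal", "control_max", "sample",
             "control_basal", "control_max"))
  list(cells = cells, design = design)
}

test_that("anchored linear map reproduces the hand-computed example", {
  fx <- anchored_fixture()
  out <- plate_normalize(fx$cells, fx$design)
  # (300 - 100) * (600 - 120) / (500 - 100) + 120 = 360
  expect_equal(out$glut4_surface_norm[out$well == "s"], 360)
  # anchors map exactly: med0 -> maxmed0, med100 -> maxmed100
  expect_equal(out$glut4_surface_norm[out$plate == "A" & out$well == "c0"], 120)
  expect_equal(out$glut4_surface_norm[out$plate == "A" & out$well == "c100"], 600)
  expect_equal(attr(out, "maxmed0"), 120)
  expect_equal(attr(out, "maxmed100"), 600)
})

test_that("single-plate normalization is the identity", {
  cfg <- small_config(n_plates = 1L, seed = 5L)
  d <- one_well_design(c(0, 3, 100),
                       role = c("control_basal", "sample", "control_max"))
  sim <- simulate_plate(cfg, d)
  out <- plate_normalize(sim$cells, d)
  expect_equal(out$glut4_surface_norm, sim$cells$glut4_surface)
})

test_that("control medians land on the anchors to 1e-9 and batch variance dies", {
  cfg <- plate_sim_config(n_plates = 4L, wells_per_condition = 2L,
                          cells_per_well = 300, plate_gain_sd = 0.25,
                          plate_offset_sd = 10, seed = 6L)
  conds <- data.frame(insulin_nM = c(0, 1, 100),
                      role = c("control_basal", "sample", "control_max"))
  d <- traffiq:::expand_design(conds, cfg$wells_per_condition,
                               paste0("P", 1:4))
  sim <- simulate_plate(cfg, d)
  out <- plate_normalize(sim$cells, d)
  key <- paste(out$plate, out$well)
  for (role in c("control_basal", "control_max")) {
    anchor <- if (role == "control_basal") attr(out, "maxmed0") else
      attr(out, "maxmed100")
    meds <- vapply(unique(out$plate), function(p) {
      w <- d[d$plate == p & d$role == role, ]
      median(out$glut4_surface_norm[key %in% paste(w$plate, w$well)])
    }, numeric(1))
    expect_true(all(abs(meds - anchor) < 1e-9 * attr(out, "maxmed100")))
    expect_lt(var(meds), 1e-18 * attr(out, "maxmed100")^2)
  }
})

test_that("normalization is idempotent and order-free over plates", {
  fx <- anchored_fixture()
  once <- plate_normalize(fx$cells, fx$design)
  again_in <- fx$cells
  again_in$glut4_surface <- once$glut4_surface_norm
  twice <- plate_normalize(again_in, fx$design)
  expect_equal(twice$glut4_surface_norm, once$glut4_surface_norm)
  rev_cells <- fx$cells[rev(seq_len(nrow(fx$cells))), ]
  rev_out <- plate_normalize(rev_cells, fx$design[rev(seq_len(5)), ])
  expect_equal(rev_out$glut4_surface_norm[rev_out$well == "s"], 360)
})

test_that("missing or non-responsive control plates are named in errors", {
  fx <- anchored_fixture()
  d_nb <- fx$design
  d_nb$role[d_nb$plate == "B" & d_nb$role == "control_basal"] <- "sample"
  expect_error(plate_normalize(fx$cells, d_nb), "plate B")
  flip <- fx$cells
  flip$glut4_surface[flip$plate == "A"] <- c(500, 100, 300)  # med100 < med0
  expect_error(plate_normalize(flip, fx$design), "non-responsive.*A")
})

test_that("nonpositive normalized values are excluded from log2, not floored", {
  fx <- anchored_fixture()
  fx$cells <- rbind(fx$cells,
                    data.frame(plate = "B", well = "neg", field = 1L,
                               cell_id = "c6", glut4_surface = -500))
  fx$design <- rbind(fx$design,
                     well_map(plate = "B", well = "neg", insulin_nM = 0))
  out <- suppressMessages(plate_normalize(fx$cells, fx$design))
  expect_equal(attr(out, "n_nonpositive"), 1L)
  expect_true(is.na(out$glut4_surface_log2norm[out$well == "neg"]))
  expect_false(anyNA(out$glut4_surface_log2norm[out$well != "neg"]))
})

test_that("fold over basal and fold over control behave as ratios", {
  expect_equal(fold_over_basal(1000, 200), 5)
  expect_equal(fold_over_basal(200, 200), 1)
  expect_error(fold_over_basal(1, 0), "positive")
  expect_equal(fold_over_control(100, 100), 1)
  expect_equal(fold_over_control(40, 100), 0.4)
  expect_error(fold_over_control(1, 0), "control")
})

test_that("fivefold stimulation is recovered as fold over basal", {
  cfg <- preset("fig1a")
  sim <- simulate_plate(cfg, cfg$design)
  gated <- apply_gate(sim$cells, gate_adipocytes(sim$cells,
                                                 design = cfg$design))
  cm <- condition_means(gated, cfg$design, "glut4_surface")
  fob <- fold_over_basal(cm$mean[cm$insulin_nM == 100],
                         cm$mean[cm$insulin_nM == 0])
  expect_lt(abs(fob - 5) / 5, 0.05)
})

test_that("min:max percent maps anchors to 0/100 without clamping", {
  expect_equal(minmax_percent(400, 200, 1000), 25)
  expect_equal(minmax_percent(200, 200, 1000), 0)
  expect_equal(minmax_percent(1000, 200, 1000), 100)
  expect_equal(minmax_percent(1200, 200, 1000), 125)
  expect_error(minmax_percent(1, 5, 5), "anchors")
})

test_that("surface/total ratio is scale invariant and guards its inputs", {
  cells <- data.frame(plate = "P1", well = "A1",
                      glut4_surface = c(50, 0, 10),
                      total_reporter = c(200, 100, 0))
  out <- surface_over_total(cells)
  expect_equal(out$surface_total_ratio, c(0.25, 0))
  expect_equal(attr(out, "n_excluded"), 1L)
  scaled <- cells
  scaled$glut4_surface <- scaled$glut4_surface * 7
  scaled$total_reporter <- scaled$total_reporter * 7
  expect_equal(surface_over_total(scaled)$surface_total_ratio,
               out$surface_total_ratio)
  expect_error(surface_over_total(cells[, 1:3]), "total_reporter")
})
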
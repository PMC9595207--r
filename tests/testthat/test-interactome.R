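# Toy six-sample design: 2 replicates per (bait/IgG x basal/insulin).
toy_design <- function() {
  data.frame(
    sample = c("bait_basal_1", "bait_basal_2", "bait_insulin_1",
               "bait_insulin_2", "IgG_basal_1", "IgG_basal_2",
               "IgG_insulin_1", "IgG_insulin_2"),
    group = rep(c("bait", "IgG"), each = 4),
    condition = rep(c("basal", "basal", "insulin", "insulin"), 2),
    replicate = rep(c(1L, 2L), 4),
    stringsAsFactors = FALSE)
}

toy_table <- function(lfq, reverse = "", contaminant = "", site = "") {
  d <- toy_design()
  tab <- data.frame(`Protein IDs` = sprintf("P%d", seq_len(nrow(lfq))),
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (j in seq_along(d$sample)) {
    tab[[paste("LFQ intensity", d$sample[j])]] <- lfq[, j]
  }
  tab$Reverse <- reverse
  tab$`Potential contaminant` <- contaminant
  tab$`Only identified by site` <- site
  tab
}

test_that("protein-group filters drop flags and underquantified rows", {
  full <- 2^c(20, 20, 21, 21, 18, 18, 18, 18)
  lfq <- rbind(full,                       # Reverse
               full,                       # contaminant
               full,                       # site only
               c(2^20, 0, 2^21, 0, 2^18, 2^18, 2^18, 2^18),  # 1 per bait cond
               c(2^20, 2^20, 2^21, 0, 2^18, 2^18, 2^18, 2^18))
  tab <- toy_table(lfq,
                   reverse = c("+", "", "", "", ""),
                   contaminant = c("", "+", "", "", ""),
                   site = c("", "", "+", "", ""))
  pg <- pg_experiment(tab, toy_design())
  kept <- suppressMessages(filter_protein_groups(pg))
  expect_equal(kept$ids, "P5")
  # the laxer pooled reading keeps the row with one value per condition
  kept2 <- suppressMessages(filter_protein_groups(pg, rule = "across_all"))
  expect_setequal(kept2$ids, c("P4", "P5"))
  # quantified in one bait condition only: retained under the default
  lfq_b <- rbind(c(2^20, 2^20, 0, 0, 2^18, 2^18, 2^18, 2^18))
  pg_b <- pg_experiment(toy_table(lfq_b), toy_design())
  expect_equal(suppressMessages(filter_protein_groups(pg_b))$ids, "P1")
  # nothing flagged, fully quantified: unchanged
  pg_clean <- pg_experiment(toy_table(rbind(full, full)), toy_design())
  expect_equal(suppressMessages(filter_protein_groups(pg_clean))$ids,
               pg_clean$ids)
})

test_that("log2 median normalization preserves scale and aligns samples", {
  m <- matrix(NA_real_, 3, 8)
  m[, 1] <- c(4, 16, 64)
  for (j in 2:8) m[, j] <- c(4, 16, 64) * 2^(j)   # constant linear offsets
  pg <- pg_from_matrix(m, toy_design(), log2 = FALSE)
  out <- log2_median_normalize(pg)
  expect_true(out$log2)
  # columns differing by a constant factor collapse to identical columns
  for (j in 2:8) expect_equal(out$intensity[, j], out$intensity[, 1])
  meds <- apply(out$intensity, 2, median, na.rm = TRUE)
  expect_equal(unname(meds), rep(meds[[1]], 8))
  # single-sample case: log2 applied, values untouched by centring
  one <- pg_from_matrix(matrix(c(4, 16, 64), 3, 1,
                               dimnames = list(NULL, "bait_basal_1")),
                        toy_design()[1, ], log2 = FALSE)
  expect_equal(unname(log2_median_normalize(one)$intensity[, 1]), c(2, 4, 6))
  # all-missing sample is an error
  m2 <- m; m2[, 3] <- NA
  expect_error(log2_median_normalize(pg_from_matrix(m2, toy_design(),
                                                    log2 = FALSE)),
               "no quantified")
})

test_that("IgG replicates are averaged across conditions", {
  m <- matrix(20, 2, 8, dimnames = list(NULL, toy_design()$sample))
  m[1, "IgG_basal_1"] <- 20; m[1, "IgG_insulin_1"] <- 22
  m[2, "IgG_insulin_2"] <- NA                      # missing partner
  pg <- pg_from_matrix(m, toy_design())
  out <- average_igg(pg)
  expect_equal(unname(out$intensity[1, "IgG_1"]), 21)
  expect_equal(unname(out$intensity[2, "IgG_1"]), 20)  # identical pair
  expect_equal(unname(out$intensity[2, "IgG_2"]), 20)  # carried forward
  expect_equal(attr(out, "n_carried"), 1L)
  expect_equal(out$design$condition[out$design$group == "IgG"],
               rep("pooled", 2))
})

test_that("imputation draws follow the documented generator contract", {
  # no missing values: identity with an empty mask
  m <- matrix(rep(20, 16), 2, 8, dimnames = list(NULL, toy_design()$sample))
  pg <- pg_from_matrix(m, toy_design())
  out <- impute_two_step(pg, seed = 5L)
  expect_identical(out$intensity, m)
  expect_true(all(out$imputed == 0L))
  # step 1: {20, 22, NA} in a condition draws from Normal(21, sd(20,22))
  d3 <- data.frame(sample = c("bait_basal_1", "bait_basal_2", "bait_basal_3"),
                   group = "bait", condition = "basal", replicate = 1:3,
                   stringsAsFactors = FALSE)
  m3 <- matrix(c(20, 22, NA), 1, 3, dimnames = list(NULL, d3$sample))
  out3 <- impute_two_step(pg_from_matrix(m3, d3), seed = 99L)
  expected <- withr::with_seed(99L, rnorm(1, 21, sd(c(20, 22))))
  expect_equal(unname(out3$intensity[1, 3]), expected)
  expect_equal(unname(out3$imputed[1, ]), c(0L, 0L, 1L))
})

test_that("downshift imputation matches its target moments", {
  n_obs <- 5000; n_mis <- 10000
  d <- data.frame(sample = c("bait_basal_1", "bait_basal_2", "IgG_1"),
                  group = c("bait", "bait", "IgG"),
                  condition = c("basal", "basal", "pooled"),
                  replicate = c(1L, 2L, 1L), stringsAsFactors = FALSE)
  obs <- withr::with_seed(1234L, rnorm(n_obs, 25, 2))
  m <- cbind(bait_basal_1 = rep(20, n_obs + n_mis),
             bait_basal_2 = rep(20, n_obs + n_mis),
             IgG_1 = c(obs, rep(NA_real_, n_mis)))
  out <- impute_two_step(pg_from_matrix(m, d), seed = 12L)
  drawn <- out$intensity[out$imputed[, "IgG_1"] == 2L, "IgG_1"]
  expect_length(drawn, n_mis)
  target_mean <- mean(obs) - sd(obs)
  target_sd <- 0.6 * sd(obs)
  expect_lt(abs(mean(drawn) - target_mean), 3 * target_sd / sqrt(n_mis))
  expect_lt(abs(sd(drawn) - target_sd), 3 * target_sd / sqrt(2 * n_mis))
  # quantified cells are never altered
  expect_identical(out$intensity[seq_len(n_obs), "IgG_1"], obs)
})

test_that("vectorized t statistics agree with stats::t.test", {
  withr::with_seed(77L, {
    x <- matrix(rnorm(60, 5), 10, 6)
    y <- matrix(rnorm(60, 4), 10, 6)
  })
  for (ve in c(TRUE, FALSE)) {
    mine <- traffiq:::row_t_test(x, y, var_equal = ve)
    ref_p <- vapply(1:10, function(i) {
      t.test(x[i, ], y[i, ], var.equal = ve)$p.value
    }, numeric(1))
    expect_equal(mine$p, ref_p, tolerance = 1e-12)
  }
})

test_that("differential enrichment flags degenerate variance and adjusts p", {
  d <- toy_design()
  m <- matrix(rep(c(5, 5, 5, 5, 1, 1, 1, 1), each = 6), 6, 8, byrow = FALSE,
              dimnames = list(NULL, d$sample))
  withr::with_seed(3L, m[2:6, ] <- m[2:6, ] + rnorm(40, 0, 0.2))
  pg <- pg_from_matrix(m, d)
  res <- differential_enrichment(pg)
  expect_equal(res$log2fc_basal[1], 4)
  expect_true(res$degenerate_basal[1])
  expect_true(is.na(res$p_basal[1]))
  expect_equal(res$adj_p_basal, bh_step_up(res$p_basal))
  expect_equal(res$adj_p_insulin, bh_step_up(res$p_insulin))
  # proteins with remaining missing values are excluded and reported
  m2 <- m; m2[3, 1] <- NA
  res2 <- differential_enrichment(pg_from_matrix(m2, d))
  expect_equal(attr(res2, "excluded"), pg$ids[3])
  expect_equal(nrow(res2), 5)
})

test_that("MAD rule matches the worked example and degenerate cases", {
  delta <- c(-0.2, -0.1, 0, 0.1, 0.2, 3.0)
  res <- fake_enrichment(delta, fc_basal = 3, fc_insulin = 3,
                         p_basal = 0.01, p_insulin = 0.01)
  out <- classify_insulin_regulated(res)
  expect_equal(attr(out, "mad"), 0.15)
  expect_equal(attr(out, "delta_threshold"), 0.30)
  expect_equal(out$class, c(rep("enriched", 5), "insulin-regulated"))
  # all differences zero: strict inequality never met
  res0 <- fake_enrichment(rep(0, 6), 3, 3, 0.01, 0.01)
  expect_false(any(classify_insulin_regulated(res0)$class ==
                     "insulin-regulated"))
  # the fold-change and significance clauses also gate the call
  res_lowfc <- fake_enrichment(delta, fc_basal = 1, fc_insulin = 1,
                               p_basal = 0.01, p_insulin = 0.01)
  expect_true(all(classify_insulin_regulated(res_lowfc)$class ==
                    "not enriched"))
  expect_error(classify_insulin_regulated(res[1:2, ]), "MAD")
  # row order invariance
  perm <- withr::with_seed(5L, sample(nrow(res)))
  out_perm <- classify_insulin_regulated(res[perm, ])
  expect_equal(out_perm$class[order(perm)], out$class)
})

test_that("the full interactome pipeline is deterministic given a seed", {
  cfg <- ipms_sim_config(n_proteins = 150L, seed = 8L)
  sim <- simulate_ipms(cfg)
  a <- suppressMessages(run_interactome(sim$table, sim$design, seed = 14))
  b <- suppressMessages(run_interactome(sim$table, sim$design, seed = 14))
  expect_identical(a$result, b$result)
  expect_identical(a$pg$intensity, b$pg$intensity)
})
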
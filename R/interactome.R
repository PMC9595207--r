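#' Build an AP-MS experiment container from a protein-groups table
#'
#' Parses a MaxQuant-style proteinGroups data.frame (`LFQ intensity <sample>`
#' columns on a linear scale with 0 meaning "not quantified", `"+"`-valued
#' flag columns) against a sample design, yielding the container the
#' enrichment pipeline operates on.
#'
#' @param table proteinGroups data.frame (e.g. from
#'   [read_protein_groups()] or [simulate_ipms()]).
#' @param design data.frame with columns `sample`, `group` (`"bait"` /
#'   `"IgG"`), `condition` (`"basal"` / `"insulin"`), `replicate`.
#' @return object of class `pg_experiment`: `ids`, `intensity` (proteins x
#'   samples matrix, `NA` = missing; log2 after
#'   [log2_median_normalize()]), `flags` (logical), `design`, `log2`
#'   (scale marker), `imputed` (mask, after [impute_two_step()]).
#' @export
pg_experiment <- function(table, design) {
  need <- c("sample", "group", "condition", "replicate")
  if (!all(need %in% names(design))) {
    stop("design must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(design$group %in% c("bait", "IgG"))) {
    stop("design group must be 'bait' or 'IgG'")
  }
  lfq_cols <- paste("LFQ intensity", design$sample)
  missing_cols <- setdiff(lfq_cols, names(table))
  if (length(missing_cols)) {
    stop("table lacks LFQ columns for design samples: ",
         paste(sub("^LFQ intensity ", "", missing_cols), collapse = ", "))
  }
  idc <- intersect(c("Protein IDs", "protein_id"), names(table))[1]
  if (is.na(idc)) stop("no protein id column ('Protein IDs' or 'protein_id')")
  m <- as.matrix(table[lfq_cols])
  colnames(m) <- design$sample
  m[m <= 0] <- NA_real_
  flag_col <- function(nm) {
    if (nm %in% names(table)) table[[nm]] == "+" else rep(FALSE, nrow(table))
  }
  flags <- data.frame(
    reverse = flag_col("Reverse"),
    contaminant = flag_col("Potential contaminant"),
    site_only = flag_col("Only identified by site")
  )
  structure(list(ids = as.character(table[[idc]]), intensity = m,
                 flags = flags, design = design, log2 = FALSE,
                 imputed = NULL),
            class = "pg_experiment")
}

#' @export
print.pg_experiment <- function(x, ...) {
  cat(sprintf("<pg_experiment> %d proteins x %d samples (%s scale)%s\n",
              nrow(x$intensity), ncol(x$intensity),
              if (x$log2) "log2" else "linear",
              if (!is.null(x$imputed)) ", imputed" else ""))
  cat("  samples: ", paste(x$design$sample, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Filter a protein-groups experiment
#'
#' Removes rows flagged Reverse / Potential contaminant / Only identified by
#' site, and rows insufficiently quantified in the bait pulldowns. The
#' quantification rule is configurable because "less than two quantified
#' values in all bait conditions" admits two readings:
#' `"every_condition"` (default) removes a protein only when *every* bait
#' condition has fewer than two quantified replicates;
#' `"across_all"` removes it when the bait samples pooled across conditions
#' have fewer than two.
#'
#' @param pg a [pg_experiment()].
#' @param min_quant minimum quantified values (default 2).
#' @param rule `"every_condition"` or `"across_all"`.
#' @return the filtered `pg_experiment`; removal counts per reason are in
#'   `attr(, "removed")` and reported via `message()`.
#' @export
filter_protein_groups <- function(pg, min_quant = 2L,
                                  rule = c("every_condition", "across_all")) {
  stopifnot(inherits(pg, "pg_experiment"))
  rule <- match.arg(rule)
  flagged <- pg$flags$reverse | pg$flags$contaminant | pg$flags$site_only
  bait <- pg$design[pg$design$group == "bait", ]
  if (!nrow(bait)) stop("design has no bait samples")
  conds <- unique(bait$condition)
  nq <- vapply(conds, function(cn) {
    cols <- bait$sample[bait$condition == cn]
    rowSums(!is.na(pg$intensity[, cols, drop = FALSE]))
  }, numeric(nrow(pg$intensity)))
  nq <- matrix(nq, ncol = length(conds))
  underquant <- if (rule == "every_condition") {
    apply(nq < min_quant, 1, all)
  } else {
    rowSums(nq) < min_quant
  }
  removed <- c(reverse = sum(pg$flags$reverse),
               contaminant = sum(pg$flags$contaminant & !pg$flags$reverse),
               site_only = sum(pg$flags$site_only & !pg$flags$reverse &
                                 !pg$flags$contaminant),
               underquantified = sum(underquant & !flagged))
  keep <- !flagged & !underquant
  message("filter_protein_groups: removed ",
          paste(sprintf("%d %s", removed, names(removed)), collapse = ", "),
          "; ", sum(keep), " of ", length(keep), " rows retained")
  pg$ids <- pg$ids[keep]
  pg$intensity <- pg$intensity[keep, , drop = FALSE]
  pg$flags <- pg$flags[keep, , drop = FALSE]
  attr(pg, "removed") <- removed
  pg
}

#' log2 transform and median-normalize LFQ intensities
#'
#' Per sample: take log2, subtract the sample median of quantified values,
#' and add back the grand median of the sample medians so the pooled scale
#' is preserved. Missing stays missing. After normalization every sample's
#' median of quantified values is identical.
#'
#' @param pg a linear-scale [pg_experiment()].
#' @return the `pg_experiment` on the log2 scale.
#' @export
log2_median_normalize <- function(pg) {
  stopifnot(inherits(pg, "pg_experiment"))
  if (pg$log2) stop("experiment is already on the log2 scale")
  l2 <- log2(pg$intensity)
  meds <- apply(l2, 2, stats::median, na.rm = TRUE)
  if (any(!is.finite(meds))) {
    stop("sample(s) with no quantified values: ",
         paste(colnames(l2)[!is.finite(meds)], collapse = ", "))
  }
  grand <- stats::median(meds)
  pg$intensity <- sweep(l2, 2, meds - grand)
  pg$log2 <- TRUE
  pg
}

#' Merge the IgG controls across conditions
#'
#' Averages replicate *r* of the basal and insulin IgG pulldowns (log2
#' scale) into a single `IgG_r` control sample, eliminating between-
#' condition variance driven by the IgG background; the merged controls
#' serve both bait conditions. When one partner is missing the present
#' value is carried forward (count in `attr(, "n_carried")`); when both are
#' missing the merged value stays missing.
#'
#' @param pg a log2-scale [pg_experiment()].
#' @return the `pg_experiment` with IgG columns replaced by merged
#'   `IgG_<r>` samples (design condition `"pooled"`).
#' @export
average_igg <- function(pg) {
  stopifnot(inherits(pg, "pg_experiment"))
  if (!pg$log2) stop("average IgG on the log2 scale (normalize first)")
  igg <- pg$design[pg$design$group == "IgG", ]
  if (!nrow(igg)) stop("design has no IgG samples")
  reps <- sort(unique(igg$replicate))
  merged <- matrix(NA_real_, nrow(pg$intensity), length(reps),
                   dimnames = list(NULL, sprintf("IgG_%d", reps)))
  n_carried <- 0L
  for (j in seq_along(reps)) {
    cols <- igg$sample[igg$replicate == reps[j]]
    sub <- pg$intensity[, cols, drop = FALSE]
    merged[, j] <- rowMeans(sub, na.rm = TRUE)
    merged[is.nan(merged[, j]), j] <- NA_real_
    if (ncol(sub) > 1) {
      n_carried <- n_carried + sum(rowSums(is.na(sub)) == ncol(sub) - 1L)
    }
  }
  bait_cols <- pg$design$sample[pg$design$group == "bait"]
  pg$intensity <- cbind(pg$intensity[, bait_cols, drop = FALSE], merged)
  pg$design <- rbind(
    pg$design[pg$design$group == "bait", ],
    data.frame(sample = colnames(merged), group = "IgG",
               condition = "pooled", replicate = reps,
               stringsAsFactors = FALSE))
  attr(pg, "n_carried") <- n_carried
  pg
}

#' Two-step imputation of missing log2 intensities
#'
#' Step 1 (per protein x condition): when a condition has at least two
#' quantified replicates, remaining missing values in that condition are
#' drawn from a normal with the mean and SD of the quantified replicates.
#' Step 2 (IgG controls only): remaining missing IgG values are drawn per
#' sample from a downshifted normal resembling the low tail of that
#' sample's quantified distribution: mean = sample mean - 1 x sample SD,
#' SD = 0.6 x sample SD.
#'
#' Draw order is deterministic given the seed: step 1 walks proteins in row
#' order and conditions in design order, drawing each condition's missing
#' values in column order with one `rnorm` call; step 2 walks IgG sample
#' columns in design order.
#'
#' @param pg a log2-scale [pg_experiment()] (typically after
#'   [average_igg()]).
#' @param seed integer seed for the imputation draws.
#' @return the completed `pg_experiment`; `$imputed` is an integer mask
#'   (0 = observed, 1 = step 1, 2 = step 2). Quantified values are never
#'   altered.
#' @export
impute_two_step <- function(pg, seed) {
  stopifnot(inherits(pg, "pg_experiment"))
  if (!pg$log2) stop("impute on the log2 scale (normalize first)")
  m <- pg$intensity
  mask <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  cond_key <- paste(pg$design$group, pg$design$condition)
  cond_levels <- unique(cond_key)
  withr::with_seed(as.integer(seed), {
    for (i in seq_len(nrow(m))) {
      for (cl in cond_levels) {
        cols <- which(cond_key == cl)
        v <- m[i, cols]
        quant <- !is.na(v)
        if (sum(quant) >= 2L && any(!quant)) {
          mu <- mean(v[quant])
          sdv <- stats::sd(v[quant])
          idx <- cols[!quant]
          m[i, idx] <- stats::rnorm(length(idx), mu, sdv)
          mask[i, idx] <- 1L
        }
      }
    }
    igg_cols <- which(pg$design$group == "IgG")
    for (j in igg_cols) {
      obs <- !is.na(m[, j]) & mask[, j] == 0L
      todo <- which(is.na(m[, j]))
      if (!length(todo)) next
      mu <- mean(m[obs, j])
      sdv <- stats::sd(m[obs, j])
      m[todo, j] <- stats::rnorm(length(todo), mu - sdv, 0.6 * sdv)
      mask[todo, j] <- 2L
    }
  })
  pg$intensity <- m
  pg$imputed <- mask
  pg
}

# Vectorized two-sample t test on row means/vars; Student (pooled) by
# default, Welch optional. Cross-checked against stats::t.test in the tests.
row_t_test <- function(x, y, var_equal = TRUE) {
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- apply(x, 1, stats::var); vy <- apply(y, 1, stats::var)
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- rep(nx + ny - 2, length(mx))
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  t <- (mx - my) / se
  p <- 2 * stats::pt(-abs(t), df)
  degenerate <- se == 0 | !is.finite(se)
  t[degenerate] <- NA_real_
  p[degenerate] <- NA_real_
  list(estimate = mx - my, t = t, p = p, degenerate = degenerate)
}

#' Bait-vs-IgG differential enrichment
#'
#' For each protein and condition (basal, insulin): log2 fold-change =
#' mean(bait) - mean(IgG control), a two-sample t test (Student's pooled-
#' variance by default, matching common proteomics practice; Welch via
#' `var_equal = FALSE`), and Benjamini-Hochberg adjustment across proteins.
#' Only proteins with no missing values after imputation are tested;
#' excluded proteins are reported in `attr(, "excluded")`. Proteins with
#' zero variance in both groups get `NA` t/p and are marked in the
#' `degenerate_*` columns.
#'
#' @param pg an imputed log2-scale [pg_experiment()].
#' @param var_equal pooled-variance Student t (default) or Welch.
#' @param adjust `"within"` (default): BH within each condition;
#'   `"pooled"`: one BH across both conditions' tests.
#' @return data.frame of class `enrichment_result`: protein_id,
#'   log2fc_basal/insulin, t_, p_, adj_p_ per condition, delta
#'   (= log2fc_insulin - log2fc_basal), degenerate flags.
#' @export
differential_enrichment <- function(pg, var_equal = TRUE,
                                    adjust = c("within", "pooled")) {
  stopifnot(inherits(pg, "pg_experiment"))
  adjust <- match.arg(adjust)
  if (!pg$log2) stop("enrichment requires the log2 scale")
  d <- pg$design
  igg_cols <- d$sample[d$group == "IgG"]
  if (!length(igg_cols)) stop("no IgG control samples")
  complete <- rowSums(is.na(pg$intensity)) == 0L
  excluded <- pg$ids[!complete]
  m <- pg$intensity[complete, , drop = FALSE]

  res <- data.frame(protein_id = pg$ids[complete], stringsAsFactors = FALSE)
  for (cn in c("basal", "insulin")) {
    bait_cols <- d$sample[d$group == "bait" & d$condition == cn]
    if (length(bait_cols) < 2L || length(igg_cols) < 2L) {
      stop("need >= 2 replicates per group in condition ", cn)
    }
    ig <- if (any(d$condition == "pooled")) igg_cols
          else d$sample[d$group == "IgG" & d$condition == cn]
    tt <- row_t_test(m[, bait_cols, drop = FALSE], m[, ig, drop = FALSE],
                     var_equal = var_equal)
    res[[paste0("log2fc_", cn)]] <- tt$estimate
    res[[paste0("t_", cn)]] <- tt$t
    res[[paste0("p_", cn)]] <- tt$p
    res[[paste0("degenerate_", cn)]] <- tt$degenerate
  }
  if (adjust == "within") {
    res$adj_p_basal <- stats::p.adjust(res$p_basal, method = "BH")
    res$adj_p_insulin <- stats::p.adjust(res$p_insulin, method = "BH")
  } else {
    adj <- stats::p.adjust(c(res$p_basal, res$p_insulin), method = "BH")
    res$adj_p_basal <- adj[seq_len(nrow(res))]
    res$adj_p_insulin <- adj[nrow(res) + seq_len(nrow(res))]
  }
  res$delta <- res$log2fc_insulin - res$log2fc_basal
  attr(res, "excluded") <- excluded
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Classify insulin-regulated interactors by the MAD rule
#'
#' Computes the raw (unscaled) median absolute deviation of the per-protein
#' difference in bait-IgG log2 fold-change between insulin and basal
#' conditions, `delta = log2FC_insulin - log2FC_basal`, over all tested
#' proteins. A protein is labelled **insulin-regulated** when all three
#' clauses hold: `|delta| > mad_multiplier * MAD`; log2FC exceeds
#' `fc_threshold` (by default in at least one condition); and the BH-
#' adjusted p-value is at or below `p_threshold` (by default in that same
#' condition). Proteins meeting the fold-change and p clauses without the
#' delta clause are labelled `"enriched"`; the rest `"not enriched"`.
#'
#' @param result a [differential_enrichment()] data.frame.
#' @param mad_multiplier MAD multiplier (default 2).
#' @param fc_threshold log2 fold-change threshold (default 2, strict `>`).
#' @param p_threshold adjusted-p threshold (default 0.05, `<=`).
#' @param fc_rule `"any"` (default) or `"both"` conditions must exceed
#'   `fc_threshold`.
#' @param p_rule `"same"` (default; the condition attaining the clause-2
#'   fold-change), `"any"`, or `"both"`.
#' @return `result` with a `class` column; attributes `mad` and
#'   `delta_threshold`.
#' @export
classify_insulin_regulated <- function(result, mad_multiplier = 2,
                                       fc_threshold = 2, p_threshold = 0.05,
                                       fc_rule = c("any", "both"),
                                       p_rule = c("same", "any", "both")) {
  stopifnot(inherits(result, "enrichment_result") ||
              all(c("log2fc_basal", "log2fc_insulin", "adj_p_basal",
                    "adj_p_insulin", "delta") %in% names(result)))
  fc_rule <- match.arg(fc_rule)
  p_rule <- match.arg(p_rule)
  if (nrow(result) < 3L) {
    stop("fewer than 3 tested proteins: MAD is unreliable")
  }
  mad_raw <- stats::mad(result$delta, constant = 1)
  thr <- mad_multiplier * mad_raw
  clause1 <- abs(result$delta) > thr

  fc_b <- result$log2fc_basal
  fc_i <- result$log2fc_insulin
  p_b <- result$adj_p_basal
  p_i <- result$adj_p_insulin
  clause2 <- switch(fc_rule,
                    any = pmax(fc_b, fc_i) > fc_threshold,
                    both = pmin(fc_b, fc_i) > fc_threshold)
  clause3 <- switch(p_rule,
    same = ifelse(fc_i >= fc_b, p_i, p_b) <= p_threshold,
    any = pmin(p_b, p_i) <= p_threshold,
    both = pmax(p_b, p_i) <= p_threshold)
  clause3 <- clause3 & !is.na(clause3)

  cls <- rep("not enriched", nrow(result))
  cls[clause2 & clause3] <- "enriched"
  cls[clause1 & clause2 & clause3] <- "insulin-regulated"
  result$class <- cls
  attr(result, "mad") <- mad_raw
  attr(result, "delta_threshold") <- thr
  result
}

#' Run the full AP-MS enrichment pipeline
#'
#' Chains [pg_experiment()], [filter_protein_groups()],
#' [log2_median_normalize()], [average_igg()], [impute_two_step()],
#' [differential_enrichment()] and [classify_insulin_regulated()] with their
#' defaults. Deterministic given `seed`.
#'
#' @param table proteinGroups data.frame.
#' @param design sample design data.frame.
#' @param seed imputation seed.
#' @param ... passed to [classify_insulin_regulated()].
#' @return list: `result` (classified `enrichment_result`) and `pg` (the
#'   imputed experiment).
#' @export
run_interactome <- function(table, design, seed, ...) {
  pg <- pg_experiment(table, design)
  pg <- filter_protein_groups(pg)
  pg <- log2_median_normalize(pg)
  pg <- average_igg(pg)
  pg <- impute_two_step(pg, seed)
  res <- differential_enrichment(pg)
  res <- classify_insulin_regulated(res, ...)
  list(result = res, pg = pg)
}
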
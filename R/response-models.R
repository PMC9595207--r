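#' @title Dose-response and kinetic model fitting
#' @description
#' All EC50 / IC50 / half-time estimates use the same least-squares engine:
#' both the 3-parameter Hill model and the one-phase association model are
#' linear in their asymptote parameters once the nonlinear parameter (EC50,
#' IC50 or rate) is fixed, so the fit profiles the residual sum of squares
#' over the nonlinear parameter on a log scale (multistart grid at the
#' observed doses/times, then 1-D minimization in the best bracket) and
#' solves for the asymptotes by linear least squares. Standard errors come
#' from the Jacobian at the optimum; AIC is `n * ln(RSS/n) + 2k` with `k`
#' mean-model parameters.
#' @name response_models
NULL

# R = a * (1 - f) + b * f for basis f in [0, 1]; returns rss and (a, b).
profile_linear <- function(f, y) {
  X <- cbind(1 - f, f)
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  list(rss = rss, coef = fit$coefficients)
}

# Profiled RSS minimization over log(theta) with a multistart grid.
profile_optimize <- function(basis_fun, x, y, grid) {
  grid <- sort(unique(grid[grid > 0 & is.finite(grid)]))
  # widen beyond the observed range so boundary optima are detectable
  grid <- c(min(grid) / 64, grid, max(grid) * 64)
  obj <- function(lt) profile_linear(basis_fun(exp(lt), x), y)$rss
  vals <- vapply(log(grid), obj, numeric(1))
  k <- which.min(vals)
  lo <- log(grid[max(1L, k - 1L)])
  hi <- log(grid[min(length(grid), k + 1L)])
  opt <- stats::optimize(obj, c(lo, hi), tol = 1e-10)
  theta <- exp(opt$minimum)
  # at-boundary optimum = the profile never turned: flag as non-converged
  at_edge <- k %in% c(1L, length(grid)) &&
    abs(opt$minimum - log(grid[k])) < 1e-6
  lin <- profile_linear(basis_fun(theta, x), y)
  list(theta = theta, coef = lin$coef, rss = lin$rss, converged = !at_edge)
}

aic_from_rss <- function(rss, n, k) {
  n * log(max(rss / n, .Machine$double.eps)) + 2 * k
}

# Numerical Jacobian-based SEs for parameters (a, b, theta).
fit_se <- function(model_fun, x, y, pars, rss) {
  n <- length(y)
  p <- length(pars)
  if (n <= p) return(rep(NA_real_, p))
  J <- vapply(seq_len(p), function(j) {
    h <- max(abs(pars[j]), 1e-8) * 1e-6
    up <- dn <- pars
    up[j] <- up[j] + h
    dn[j] <- dn[j] - h
    (model_fun(up, x) - model_fun(dn, x)) / (2 * h)
  }, numeric(n))
  s2 <- rss / (n - p)
  cov <- tryCatch(s2 * solve(crossprod(J)), error = function(e) NULL)
  if (is.null(cov)) rep(NA_real_, p) else sqrt(pmax(diag(cov), 0))
}

new_fit_result <- function(model, coefficients, se, rss, n, k, converged,
                           extra = list()) {
  structure(c(list(model = model, coefficients = coefficients, se = se,
                   rss = rss, n = n, aic = aic_from_rss(rss, n, k),
                   converged = converged), extra),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result: %s>%s\n", x$model,
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  est <- data.frame(estimate = x$coefficients,
                    se = x$se[names(x$coefficients)])
  print(signif(est, 4))
  cat(sprintf("  RSS %.4g on n=%d, AIC %.2f\n", x$rss, x$n, x$aic))
  invisible(x)
}

#' @export
coef.fit_result <- function(object, ...) object$coefficients

#' Fit a 3-parameter Hill dose-response
#'
#' Least-squares fit of `R(d) = Bottom + (Top - Bottom) * d / (EC50 + d)`
#' (stimulation) or `R(c) = Bottom + (Top - Bottom) * IC50 / (IC50 + c)`
#' (inhibition, reported as IC50). The Hill slope is fixed at 1, the
#' standard three-parameter agonist model; `slope_free = TRUE` adds a free
#' slope (4-parameter logistic). Zero doses are handled natively
#' (`R(0) = Bottom` for stimulation, `Top` for inhibition). Responses should
#' be per-dose summaries (well or replicate means), not single cells.
#'
#' @param dose dose vector (may include 0); >= 4 distinct values.
#' @param response finite response summaries, same length.
#' @param direction `"stimulation"` or `"inhibition"`.
#' @param slope_free fit a free Hill slope (default `FALSE`).
#' @return a `fit_result` with coefficients `Bottom`, `Top`, `EC50` (or
#'   `IC50`), standard errors, `rss`, `n`, `aic`, `converged`.
#' @export
fit_hill3 <- function(dose, response,
                      direction = c("stimulation", "inhibition"),
                      slope_free = FALSE) {
  direction <- match.arg(direction)
  stopifnot(length(dose) == length(response), all(is.finite(dose)),
            all(dose >= 0))
  if (!all(is.finite(response))) stop("responses must be finite")
  if (length(unique(dose)) < 4L) stop("need >= 4 distinct doses")
  pname <- if (direction == "stimulation") "EC50" else "IC50"

  if (stats::sd(response) == 0) {
    co <- stats::setNames(c(response[1], response[1], NA_real_),
                          c("Bottom", "Top", pname))
    return(new_fit_result(paste0("hill3_", direction), co,
                          stats::setNames(rep(NA_real_, 3), names(co)),
                          rss = 0, n = length(response), k = 3,
                          converged = FALSE))
  }

  basis <- function(theta, d) {
    f <- d / (theta + d)                 # occupancy at dose d
    if (direction == "inhibition") 1 - f else f
  }
  if (!slope_free) {
    fit <- profile_optimize(basis, dose, response, grid = dose)
    co <- stats::setNames(c(fit$coef[1], fit$coef[2], fit$theta),
                          c("Bottom", "Top", pname))
    model_fun <- function(p, d) {
      p[1] + (p[2] - p[1]) * basis(p[3], d)
    }
    se <- fit_se(model_fun, dose, response, unname(co), fit$rss)
    new_fit_result(paste0("hill3_", direction), co,
                   stats::setNames(se, names(co)), fit$rss,
                   length(response), k = 3, converged = fit$converged,
                   extra = list(direction = direction,
                                fitted = model_fun(unname(co), dose)))
  } else {
    basis_h <- function(theta, d) {
      f <- ifelse(d > 0, d^theta[2] / (theta[1]^theta[2] + d^theta[2]), 0)
      if (direction == "inhibition") 1 - f else f
    }
    obj <- function(par) {                  # par = (log ec50, log slope)
      profile_linear(basis_h(exp(par), dose), response)$rss
    }
    nz <- sort(unique(dose[dose > 0]))
    starts <- expand.grid(le = log(nz), lh = log(c(0.5, 1, 2)))
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      o <- stats::optim(as.numeric(starts[i, ]), obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-12))
      if (is.null(best) || o$value < best$value) best <- o
    }
    theta <- exp(best$par)
    lin <- profile_linear(basis_h(theta, dose), response)
    co <- stats::setNames(c(lin$coef[1], lin$coef[2], theta[1], theta[2]),
                          c("Bottom", "Top", pname, "HillSlope"))
    model_fun <- function(p, d) p[1] + (p[2] - p[1]) * basis_h(p[3:4], d)
    se <- fit_se(model_fun, dose, response, unname(co), lin$rss)
    new_fit_result(paste0("hill4_", direction), co,
                   stats::setNames(se, names(co)), lin$rss,
                   length(response), k = 4,
                   converged = best$convergence == 0,
                   extra = list(direction = direction,
                                fitted = model_fun(unname(co), dose)))
  }
}

#' Fit a one-phase association time-course
#'
#' Least-squares fit of `S(t) = S0 + (Splateau - S0) * (1 - exp(-k t))`,
#' reported in the half-time parameterization `t1/2 = ln 2 / k` (the SE of
#' the half-time follows by the delta method).
#'
#' @param time times in minutes; >= 4 distinct values including one near 0.
#' @param response finite response summaries.
#' @return a `fit_result` with coefficients `S0`, `Splateau`, `t_half`
#'   (plus `k` in `$rate`).
#' @export
fit_one_phase <- function(time, response) {
  stopifnot(length(time) == length(response), all(is.finite(time)),
            all(time >= 0))
  if (!all(is.finite(response))) stop("responses must be finite")
  if (length(unique(time)) < 4L) stop("need >= 4 distinct time points")
  if (stats::sd(response) == 0) {
    co <- stats::setNames(c(response[1], response[1], NA_real_),
                          c("S0", "Splateau", "t_half"))
    return(new_fit_result("one_phase", co,
                          stats::setNames(rep(NA_real_, 3), names(co)),
                          rss = 0, n = length(response), k = 3,
                          converged = FALSE))
  }
  basis <- function(k, t) 1 - exp(-k * t)
  tpos <- time[time > 0]
  fit <- profile_optimize(basis, time, response, grid = log(2) / tpos)
  k_rate <- fit$theta
  co <- stats::setNames(c(fit$coef[1], fit$coef[2], log(2) / k_rate),
                        c("S0", "Splateau", "t_half"))
  model_fun <- function(p, t) p[1] + (p[2] - p[1]) * basis(p[3], t)
  se_k <- fit_se(model_fun, time, response,
                 c(unname(co[1:2]), k_rate), fit$rss)
  se <- c(se_k[1], se_k[2], log(2) / k_rate^2 * se_k[3])  # delta method
  new_fit_result("one_phase", co, stats::setNames(se, names(co)), fit$rss,
                 length(response), k = 3, converged = fit$converged,
                 extra = list(rate = k_rate,
                              fitted = model_fun(c(unname(co[1:2]), k_rate),
                                                 time)))
}

#' Compare shared vs independent dose-response fits by AIC
#'
#' Fits each dataset independently (3 parameters each) and globally with the
#' named parameter shared across datasets (per-dataset Bottom/Top, one
#' common EC50/IC50), and compares by Akaike's Information Criterion:
#' `AIC = n ln(RSS/n) + 2k`, summed over datasets for the independent fits
#' and computed on the pooled residuals for the shared fit. A lower AIC is
#' preferred; a single curve is deemed inadequate when the independent model
#' wins. `use_aicc = TRUE` applies the small-sample correction
#' `+ 2k(k+1)/(n-k-1)`.
#'
#' @param datasets list of datasets, each a list/data.frame with elements
#'   `dose` and `response`.
#' @param shared name of the shared parameter: `"ec50"` (stimulation fits)
#'   or `"ic50"` (inhibition fits).
#' @param use_aicc small-sample corrected AIC (default `FALSE`).
#' @return an object of class `aic_comparison`: `aic_independent`,
#'   `aic_shared`, `delta_aic` (= shared - independent), `preferred`,
#'   `shared_estimate`, and the per-dataset `fits`.
#' @export
compare_shared_vs_independent <- function(datasets, shared = c("ec50", "ic50"),
                                          use_aicc = FALSE) {
  shared <- match.arg(shared)
  direction <- if (shared == "ec50") "stimulation" else "inhibition"
  if (length(datasets) < 2L) stop("need >= 2 datasets")

  fits <- vector("list", length(datasets))
  for (j in seq_along(datasets)) {
    d <- datasets[[j]]
    fits[[j]] <- fit_hill3(d$dose, d$response, direction = direction)
    if (!fits[[j]]$converged) {
      stop("independent fit failed for dataset ", j, "; comparison aborted")
    }
  }
  pen <- function(n, k) if (use_aicc) 2 * k * (k + 1) / max(n - k - 1, 1) else 0
  aic_indep <- sum(vapply(fits, function(f) f$aic + pen(f$n, 3), numeric(1)))

  basis <- function(theta, d) {
    f <- d / (theta + d)
    if (direction == "inhibition") 1 - f else f
  }
  shared_rss <- function(theta) {
    sum(vapply(datasets, function(d) {
      profile_linear(basis(theta, d$dose), d$response)$rss
    }, numeric(1)))
  }
  all_doses <- unlist(lapply(datasets, `[[`, "dose"))
  grid <- sort(unique(all_doses[all_doses > 0]))
  grid <- c(min(grid) / 64, grid, max(grid) * 64)
  vals <- vapply(grid, shared_rss, numeric(1))
  k0 <- which.min(vals)
  opt <- stats::optimize(function(lt) shared_rss(exp(lt)),
                         log(c(grid[max(1L, k0 - 1L)],
                               grid[min(length(grid), k0 + 1L)])),
                         tol = 1e-10)
  theta_sh <- exp(opt$minimum)
  rss_sh <- shared_rss(theta_sh)
  n_tot <- sum(vapply(datasets, function(d) length(d$response), numeric(1)))
  k_sh <- 2 * length(datasets) + 1
  aic_sh <- aic_from_rss(rss_sh, n_tot, k_sh) + pen(n_tot, k_sh)

  structure(list(
    aic_independent = aic_indep,
    aic_shared = aic_sh,
    delta_aic = aic_sh - aic_indep,
    preferred = if (aic_sh < aic_indep) "shared" else "independent",
    shared_parameter = shared,
    shared_estimate = theta_sh,
    fits = fits
  ), class = "aic_comparison")
}

#' @export
print.aic_comparison <- function(x, ...) {
  cat(sprintf("<aic_comparison> shared %s = %.4g\n", x$shared_parameter,
              x$shared_estimate))
  cat(sprintf("  AIC shared %.2f vs independent %.2f (delta %.2f) -> %s model preferred\n",
              x$aic_shared, x$aic_independent, x$delta_aic, x$preferred))
  invisible(x)
}
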
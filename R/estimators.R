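# Univariable two-sample MR estimators.
#
# All methods operate on a harmonized_set and return one row of the tidy
# estimates table (method, nsnp, beta, se, ci_low, ci_high, pval).
# Throughout, bx/sx are instrument-exposure effects/SEs and by/sy the
# instrument-outcome ones; the outcome follows the time-to-event sign
# convention (negative beta = shorter time to event = higher risk).

#' Estimator configuration
#'
#' @param ivw_mode `"multiplicative_random"` (default; the fixed-effect
#'   SE is inflated by sqrt(Q/(J-1)) when that factor exceeds 1) or
#'   `"fixed"`.
#' @param n_boot parametric-bootstrap replicates for the weighted-median
#'   and weighted-mode SEs (>= 100).
#' @param mode_bandwidth_factor multiplier phi on the weighted-mode
#'   kernel bandwidth (> 0).
#' @param seed integer seed for all estimator randomness.
#' @return object of class `mr_config`.
#' @export
mr_config <- function(ivw_mode = c("multiplicative_random", "fixed"),
                      n_boot = 1000, mode_bandwidth_factor = 1, seed = 1L) {
  ivw_mode <- match.arg(ivw_mode)
  if (n_boot < 100) mr_error("mr_validation_error", "n_boot must be >= 100")
  if (mode_bandwidth_factor <= 0) mr_error("mr_validation_error", "mode_bandwidth_factor must be > 0")
  structure(list(ivw_mode = ivw_mode, n_boot = as.integer(n_boot),
                 mode_bandwidth_factor = mode_bandwidth_factor,
                 seed = as.integer(seed)),
            class = "mr_config")
}

#' Wald ratio estimate from a single instrument
#'
#' `beta_out / beta_exp` with the first-order delta-method SE
#' `se_out / |beta_exp|`; with `second_order = TRUE` the SE additionally
#' carries the exposure-uncertainty term.
#'
#' @param beta_exp,se_exp instrument-exposure effect and SE.
#' @param beta_out,se_out instrument-outcome effect and SE.
#' @param second_order include the second delta-method term in the SE.
#' @return one estimate row (data.frame).
#' @export
#' @examples
#' wald_ratio(0.1, 0.02, 0.05, 0.03)
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out, second_order = FALSE) {
  if (beta_exp == 0) mr_error("mr_degenerate_instrument", "beta_exp must be nonzero")
  b <- beta_out / beta_exp
  se <- if (second_order) {
    sqrt(se_out^2 / beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4)
  } else {
    se_out / abs(beta_exp)
  }
  mr_estimate("wald_ratio", b, se, 1L)
}

# Fixed-effect IVW core: weighted LS of by on bx through the origin,
# weights 1/sy^2. Returns beta, fixed SE and Cochran's Q.
#' @noRd
ivw_core <- function(bx, by, sy) {
  w <- 1 / sy^2
  sxx <- sum(w * bx^2)
  beta <- sum(w * bx * by) / sxx
  se_fixed <- sqrt(1 / sxx)
  q <- sum(w * (by - beta * bx)^2)
  list(beta = beta, se_fixed = se_fixed, Q = q)
}

#' Inverse-variance-weighted estimate
#'
#' Weighted least squares of outcome effects on exposure effects through
#' the origin with weights `1/se_out^2` — the maximum-power estimator
#' when every instrument is valid. In the default multiplicative
#' random-effects mode the fixed-effect SE is inflated by
#' `sqrt(Q/(J-1))` whenever that factor exceeds 1 (J >= 2).
#'
#' @param h a [harmonized_set()].
#' @param config an [mr_config()].
#' @return one estimate row.
#' @export
mr_ivw <- function(h, config = mr_config()) {
  J <- nsnp(h)
  if (J < 1) mr_error("mr_empty_set", "IVW needs at least one instrument")
  core <- ivw_core(h$beta_exp, h$beta_out, h$se_out)
  se <- core$se_fixed
  if (config$ivw_mode == "multiplicative_random" && J >= 2) {
    infl <- sqrt(core$Q / (J - 1))
    if (infl > 1) se <- se * infl
  }
  mr_estimate("ivw", core$beta, se, J)
}

# Joint normal negative log-likelihood (constants dropped) of the
# errors-in-variables MR model: bx_j ~ N(g_j, sx_j^2), by_j ~ N(theta g_j, sy_j^2).
#' @noRd
ml_nll <- function(par, bx, by, sx, sy) {
  theta <- par[1]; g <- par[-1]
  sum((bx - g)^2 / (2 * sx^2)) + sum((by - theta * g)^2 / (2 * sy^2))
}

#' @noRd
ml_grad <- function(par, bx, by, sx, sy) {
  theta <- par[1]; g <- par[-1]
  ry <- by - theta * g
  c(-sum(g * ry / sy^2),
    -(bx - g) / sx^2 - theta * ry / sy^2)
}

#' Maximum-likelihood estimate
#'
#' Maximizes the joint normal likelihood of the observed exposure and
#' outcome effects over the causal effect and the per-instrument true
#' exposure effects, so exposure-side measurement error is modelled
#' (unlike IVW, which it reduces to when the exposure SEs vanish). SE
#' from the observed Fisher information at the optimum; started from the
#' IVW estimate.
#'
#' @inheritParams mr_ivw
#' @param max_iter optimizer iteration budget.
#' @return one estimate row.
#' @export
mr_maximum_likelihood <- function(h, config = mr_config(), max_iter = 500) {
  J <- nsnp(h)
  if (J < 2) mr_error("mr_insufficient_instruments", "ML needs >= 2 instruments")
  bx <- h$beta_exp; by <- h$beta_out; sx <- h$se_exp; sy <- h$se_out
  start <- c(ivw_core(bx, by, sy)$beta, bx)
  fit <- stats::optim(start, ml_nll, ml_grad, bx = bx, by = by, sx = sx, sy = sy,
                      method = "BFGS", hessian = TRUE,
                      control = list(maxit = max_iter, reltol = 1e-14))
  if (fit$convergence != 0) {
    mr_error("mr_convergence_error",
             sprintf("ML optimizer did not converge (code %d, value %g)",
                     fit$convergence, fit$value))
  }
  v <- tryCatch(solve(fit$hessian)[1, 1], error = function(e)
    mr_error("mr_convergence_error", "singular information matrix in ML fit"))
  mr_estimate("maximum_likelihood", fit$par[1], sqrt(v), J)
}

#' MR-Egger regression
#'
#' Re-orients every instrument so the exposure effect is non-negative,
#' then fits weighted least squares of outcome effects on exposure
#' effects *with* an intercept (weights `1/se_out^2`). The slope is the
#' pleiotropy-adjusted causal estimate; a nonzero intercept indicates
#' directional pleiotropy. SEs use the multiplicative random-effects
#' model with no underdispersion (residual scale floored at 1); p-values
#' from the t distribution with J - 2 df.
#'
#' @inheritParams mr_ivw
#' @return list of class `mr_egger_fit`: `slope` (estimate row) and
#'   `intercept` (list with `estimate`, `se`, `pval`, `df`).
#' @export
mr_egger <- function(h, config = mr_config()) {
  J <- nsnp(h)
  if (J < 3) mr_error("mr_insufficient_instruments", "MR-Egger needs >= 3 instruments")
  flip <- sign(h$beta_exp)
  flip[flip == 0] <- 1
  bx <- h$beta_exp * flip
  by <- h$beta_out * flip
  w <- 1 / h$se_out^2
  X <- cbind(1, bx)
  XtWX <- crossprod(X, w * X)
  coefs <- drop(solve(XtWX, crossprod(X, w * by)))
  names(coefs) <- NULL
  resid <- by - X %*% coefs
  sigma2 <- sum(w * resid^2) / (J - 2)
  vc <- solve(XtWX) * max(1, sigma2)
  se <- unname(sqrt(diag(vc)))
  tval <- coefs / se
  pvals <- 2 * stats::pt(-abs(tval), df = J - 2)
  tq <- stats::qt(0.975, df = J - 2)
  slope <- mr_estimate("egger", coefs[2], se[2], J, pval = pvals[2],
                       ci = c(coefs[2] - tq * se[2], coefs[2] + tq * se[2]))
  structure(
    list(slope = slope,
         intercept = list(estimate = coefs[1], se = se[1],
                          pval = pvals[1], df = J - 2)),
    class = "mr_egger_fit"
  )
}

#' @export
print.mr_egger_fit <- function(x, ...) {
  cat("MR-Egger regression\n")
  print(x$slope, row.names = FALSE)
  cat(sprintf("intercept %.4g (se %.4g, p %.3g, %d df)\n",
              x$intercept$estimate, x$intercept$se, x$intercept$pval, x$intercept$df))
  invisible(x)
}

# Weighted-median point estimate on precomputed ratios/weights.
# Linear interpolation of the ordered ratios at standardized cumulative
# weight (S_j - w_j/2)/S_J crossing one half.
#' @noRd
weighted_median_point <- function(ratio, weight) {
  o <- order(ratio)
  r <- ratio[o]; w <- weight[o] / sum(weight)
  cs <- cumsum(w) - w / 2
  if (cs[1] >= 0.5) return(r[1])
  if (cs[length(cs)] <= 0.5) return(r[length(r)])
  i <- max(which(cs < 0.5))
  r[i] + (r[i + 1] - r[i]) * (0.5 - cs[i]) / (cs[i + 1] - cs[i])
}

# Weighted-mode point estimate: Gaussian-kernel weighted density of the
# ratios on a 512-point grid, modified Silverman bandwidth.
#' @noRd
weighted_mode_point <- function(ratio, weight, phi = 1) {
  s <- stats::sd(ratio)
  iqr <- stats::IQR(ratio) / 1.34
  cand <- c(s, iqr)
  cand <- cand[is.finite(cand) & cand > 0]
  if (!length(cand)) return(ratio[1])  # all ratios identical
  h <- phi * 0.9 * min(cand) * length(ratio)^(-1 / 5)
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = 512)
  dens <- colSums(weight / sum(weight) * stats::dnorm(outer(ratio, grid, "-") / h)) / h
  grid[which.max(dens)]
}

# Seeded parametric bootstrap SE: redraw both effect vectors from their
# sampling normals and recompute the point estimate.
#' @noRd
boot_se <- function(h, point_fun, n_boot, seed) {
  J <- nsnp(h)
  with_seed(seed, {
    bxs <- matrix(stats::rnorm(J * n_boot, h$beta_exp, h$se_exp), nrow = J)
    bys <- matrix(stats::rnorm(J * n_boot, h$beta_out, h$se_out), nrow = J)
    est <- vapply(seq_len(n_boot), function(i) {
      bx <- bxs[, i]
      ratio <- bys[, i] / bx
      weight <- bx^2 / h$se_out^2
      point_fun(ratio, weight)
    }, numeric(1))
    stats::sd(est)
  })
}

#' Weighted-median estimate
#'
#' Median of the per-instrument Wald ratios under inverse-variance
#' weights (`beta_exp^2/se_out^2`), consistent when valid instruments
#' carry more than half of the total weight. SE from a seeded parametric
#' bootstrap.
#'
#' @inheritParams mr_ivw
#' @return one estimate row.
#' @export
mr_weighted_median <- function(h, config = mr_config()) {
  J <- nsnp(h)
  if (J < 3) mr_error("mr_insufficient_instruments", "weighted median needs >= 3 instruments")
  ratio <- h$beta_out / h$beta_exp
  weight <- h$beta_exp^2 / h$se_out^2
  b <- weighted_median_point(ratio, weight)
  se <- boot_se(h, weighted_median_point, config$n_boot, config$seed)
  mr_estimate("weighted_median", b, se, J)
}

#' Weighted-mode estimate
#'
#' Mode of the Gaussian-kernel-smoothed weighted density of the Wald
#' ratios: the causal effect is taken from the largest cluster of
#' agreeing instruments, so it is consistent when that cluster is valid
#' even if most instruments are not. Bandwidth is
#' `phi * 0.9 * min(sd, IQR/1.34) * J^(-1/5)`; density evaluated on a
#' 512-point grid spanning the ratios plus/minus three bandwidths. SE
#' from a seeded parametric bootstrap.
#'
#' @inheritParams mr_ivw
#' @return one estimate row.
#' @export
mr_weighted_mode <- function(h, config = mr_config()) {
  J <- nsnp(h)
  if (J < 3) mr_error("mr_insufficient_instruments", "weighted mode needs >= 3 instruments")
  ratio <- h$beta_out / h$beta_exp
  weight <- h$beta_exp^2 / h$se_out^2
  phi <- config$mode_bandwidth_factor
  b <- weighted_mode_point(ratio, weight, phi)
  se <- boot_se(h, function(r, w) weighted_mode_point(r, w, phi),
                config$n_boot, config$seed)
  mr_estimate("weighted_mode", b, se, J)
}

ESTIMATOR_REGISTRY <- list(
  ivw = mr_ivw,
  maximum_likelihood = mr_maximum_likelihood,
  weighted_median = mr_weighted_median,
  weighted_mode = mr_weighted_mode
)

#' Fit a battery of MR estimators
#'
#' The central fitting function: runs the requested estimators on one
#' harmonized exposure/outcome instrument set and returns a classed
#' model object with `print`, `summary`, `coef`, `confint`, `plot` and
#' `residuals` methods. Estimators whose instrument-count precondition
#' is not met (e.g. Egger with J < 3) are silently skipped.
#'
#' @param h a [harmonized_set()].
#' @param methods subset of `"ivw"`, `"maximum_likelihood"`, `"egger"`,
#'   `"weighted_median"`, `"weighted_mode"`, `"wald_ratio"`.
#' @param config an [mr_config()].
#' @return object of class `mr_fit` with elements `estimates` (tidy
#'   data.frame of exposure, outcome, method, nsnp, beta, se, ci_low,
#'   ci_high, pval), `egger_intercept`, `data`, `config`.
#' @export
#' @examples
#' h <- harmonized_set(paste0("rs", 1:4),
#'                     beta_exp = c(0.10, 0.20, 0.15, 0.12),
#'                     se_exp = rep(0.01, 4),
#'                     beta_out = c(0.05, 0.11, 0.06, 0.07),
#'                     se_out = c(0.05, 0.05, 0.10, 0.06))
#' fit <- mr_fit(h, methods = c("ivw", "egger"), config = mr_config(n_boot = 100))
#' coef(fit)
mr_fit <- function(h,
                   methods = c("ivw", "maximum_likelihood", "egger",
                               "weighted_median", "weighted_mode"),
                   config = mr_config()) {
  stopifnot(inherits(h, "harmonized_set"))
  known <- c(names(ESTIMATOR_REGISTRY), "egger", "wald_ratio")
  bad <- setdiff(methods, known)
  if (length(bad)) mr_error("mr_config_error", paste("unknown method(s):", paste(bad, collapse = ", ")))
  J <- nsnp(h)
  rows <- list()
  intercept <- NULL
  for (m in methods) {
    if (m == "egger") {
      if (J < 3) next
      ef <- mr_egger(h, config)
      rows[[m]] <- ef$slope
      intercept <- ef$intercept
    } else if (m == "wald_ratio") {
      if (J != 1) next
      rows[[m]] <- wald_ratio(h$beta_exp, h$se_exp, h$beta_out, h$se_out)
    } else {
      need <- switch(m, ivw = 1L, maximum_likelihood = 2L, 3L)
      if (J < need) next
      rows[[m]] <- ESTIMATOR_REGISTRY[[m]](h, config)
    }
  }
  if (!length(rows)) mr_error("mr_insufficient_instruments", "no requested method is estimable")
  est <- do.call(rbind, rows)
  est <- cbind(data.frame(exposure = h$exposure_name, outcome = h$outcome_name,
                          stringsAsFactors = FALSE),
               est)
  rownames(est) <- NULL
  structure(list(estimates = est, egger_intercept = intercept,
                 data = h, config = config),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Two-sample MR fit: %s -> %s (%d instruments)\n",
              x$data$exposure_name, x$data$outcome_name, nsnp(x$data)))
  print(format(x$estimates[, c("method", "nsnp", "beta", "se", "ci_low", "ci_high", "pval")],
               digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  q <- cochran_q(object$data)
  structure(list(fit = object, q = q), class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("Cochran's Q = %.4g on %d df (p = %.3g)\n", x$q$Q, x$q$df, x$q$pval))
  ic <- x$fit$egger_intercept
  if (!is.null(ic)) {
    cat(sprintf("Egger intercept = %.4g (se %.4g, p = %.3g)\n",
                ic$estimate, ic$se, ic$pval))
  }
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$estimates$beta, object$estimates$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  est <- object$estimates
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(est$beta - z * est$se, est$beta + z * est$se)
  dimnames(out) <- list(est$method,
                        sprintf("%g %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2)))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
residuals.mr_fit <- function(object, method = "ivw", ...) {
  est <- object$estimates
  if (!method %in% est$method) mr_error("mr_config_error", paste("method not fitted:", method))
  b <- est$beta[est$method == method]
  h <- object$data
  stats::setNames((h$beta_out - b * h$beta_exp) / h$se_out, h$snp)
}

#' @export
as.data.frame.mr_fit <- function(x, ...) x$estimates

#' Scatter plot of instrument effects with fitted causal slopes
#'
#' @param x an `mr_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mr_fit <- function(x, ...) {
  h <- x$data
  graphics::plot(h$beta_exp, h$beta_out,
                 xlab = sprintf("SNP effect on %s", h$exposure_name),
                 ylab = sprintf("SNP effect on %s", h$outcome_name),
                 pch = 19, ...)
  graphics::segments(h$beta_exp, h$beta_out - 1.96 * h$se_out,
                     h$beta_exp, h$beta_out + 1.96 * h$se_out, col = "grey60")
  graphics::segments(h$beta_exp - 1.96 * h$se_exp, h$beta_out,
                     h$beta_exp + 1.96 * h$se_exp, h$beta_out, col = "grey60")
  est <- x$estimates
  cols <- seq_len(nrow(est)) + 1
  for (i in seq_len(nrow(est))) {
    ic <- if (est$method[i] == "egger") x$egger_intercept$estimate else 0
    graphics::abline(ic, est$beta[i], col = cols[i], lwd = 1.5)
  }
  graphics::legend("topleft", legend = est$method, col = cols, lwd = 1.5, bty = "n")
  invisible(x)
}

#' Write the tidy estimates table
#'
#' Forest-table shape: exposure, outcome, method, nsnp, beta, se,
#' ci_low, ci_high, pval.
#'
#' @param x an `mr_fit` or `mr_screen` object, or the estimates data.frame.
#' @param path output TSV path.
#' @export
write_estimates <- function(x, path) {
  est <- if (is.data.frame(x)) x else if (inherits(x, "mr_screen")) x$estimates else x$estimates
  utils::write.table(est, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
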
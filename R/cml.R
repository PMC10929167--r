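# Constrained maximum likelihood with BIC model averaging (cML-MA-BIC).
#
# The model extends the ML errors-in-variables likelihood with a
# per-instrument pleiotropy term r_j on the outcome equation:
#   bx_j ~ N(g_j, sx_j^2),  by_j ~ N(theta g_j + r_j, sy_j^2),
# constrained so that at most K of the r_j are nonzero. Because invalid
# instruments are selected by the data rather than assumed, the
# estimator remains consistent under both uncorrelated and correlated
# (InSIDE-violating) pleiotropy, provided enough instruments are valid.

# Exact profile negative log-likelihood in theta on a fixed valid set
# (per-instrument effects profiled out in closed form).
#' @noRd
cml_profile_nll <- function(theta, bx, by, sx, sy) {
  g <- (bx / sx^2 + theta * by / sy^2) / (1 / sx^2 + theta^2 / sy^2)
  sum((bx - g)^2 / (2 * sx^2)) + sum((by - theta * g)^2 / (2 * sy^2))
}

# Minimize the profile NLL over theta on the valid set. The profile can
# be multimodal when pleiotropic instruments are present, so the
# bracket is scanned on a grid first and golden-section refinement is
# confined to the best grid cell; the bracket widens until the optimum
# is interior.
#' @noRd
cml_theta_step <- function(bx, by, sx, sy, theta0, tol) {
  w <- 5 * (abs(theta0) + 1)
  for (i in 1:6) {
    grid <- seq(theta0 - w, theta0 + w, length.out = 101)
    vals <- vapply(grid, cml_profile_nll, numeric(1),
                   bx = bx, by = by, sx = sx, sy = sy)
    k <- which.min(vals)
    lo <- grid[max(1, k - 1)]
    hi <- grid[min(length(grid), k + 1)]
    opt <- stats::optimize(cml_profile_nll, c(lo, hi),
                           bx = bx, by = by, sx = sx, sy = sy,
                           tol = tol / 10)
    if (k > 1 && k < length(grid)) return(opt$minimum)
    w <- 4 * w
  }
  mr_error("mr_convergence_error", "cML profile optimum did not stabilize")
}

# Support-selection iteration for a fixed number K of invalid
# instruments: given theta, the K instruments with the largest
# standardized outcome residuals become invalid; theta is then
# re-fitted exactly on the remaining valid set. Converged when the
# invalid set is stable and theta moves less than tol.
#' @noRd
cml_iterate <- function(bx, by, sx, sy, K, theta0, tol, max_iter) {
  J <- length(bx)
  # the starting value seeds the first support selection directly: a
  # start near the causal effect of the valid instruments lets the
  # selection step separate the invalid ones before theta is refitted
  theta <- theta0
  invalid <- integer(0)
  history <- list()
  for (it in seq_len(max_iter)) {
    g_valid <- (bx / sx^2 + theta * by / sy^2) / (1 / sx^2 + theta^2 / sy^2)
    if (K > 0) {
      score <- (by - theta * g_valid)^2 / sy^2
      invalid_new <- sort(order(score, decreasing = TRUE)[seq_len(K)])
    } else {
      invalid_new <- integer(0)
    }
    valid <- setdiff(seq_len(J), invalid_new)
    theta_new <- cml_theta_step(bx[valid], by[valid], sx[valid], sy[valid],
                                theta, tol)
    conv <- abs(theta_new - theta) < tol && identical(invalid_new, invalid)
    theta <- theta_new
    invalid <- invalid_new
    if (conv) {
      return(list(theta = theta, invalid = invalid, iter = it, converged = TRUE))
    }
    # support cycling: the discrete support search revisits a set it has
    # seen before without stabilizing; the constrained optimum over the
    # cycle is the member with the smallest exactly-refitted NLL
    seen <- vapply(history, function(hh) identical(hh, invalid), logical(1))
    if (any(seen) && it > 1) {
      cycle <- unique(history[seq(from = max(which(seen)), to = length(history))])
      cycle <- c(cycle, list(invalid))
      cycle <- unique(cycle)
      best <- NULL
      for (s in cycle) {
        v <- setdiff(seq_len(J), s)
        th <- cml_theta_step(bx[v], by[v], sx[v], sy[v], theta, tol)
        nl <- cml_profile_nll(th, bx[v], by[v], sx[v], sy[v])
        if (is.null(best) || nl < best$nll) {
          best <- list(theta = th, invalid = s, nll = nl)
        }
      }
      return(list(theta = best$theta, invalid = best$invalid, iter = it,
                  converged = TRUE))
    }
    history[[length(history) + 1]] <- invalid
  }
  cycle <- unique(history[max(1, length(history) - 4):length(history)])
  mr_error("mr_convergence_error",
           sprintf("cML invalid set oscillated beyond %d iterations (K=%d; recent sets: %s)",
                   max_iter, K,
                   paste(vapply(cycle, function(s) paste(s, collapse = ","), ""),
                         collapse = " | ")),
           cycle = cycle)
}

# Negative log-likelihood (constants dropped) at a constrained solution;
# invalid instruments contribute zero (g_j = bx_j, r_j exact).
#' @noRd
cml_nll <- function(bx, by, sx, sy, theta, invalid) {
  valid <- setdiff(seq_along(bx), invalid)
  g <- (bx[valid] / sx[valid]^2 + theta * by[valid] / sy[valid]^2) /
    (1 / sx[valid]^2 + theta^2 / sy[valid]^2)
  sum((bx[valid] - g)^2 / (2 * sx[valid]^2)) +
    sum((by[valid] - theta * g)^2 / (2 * sy[valid]^2))
}

# Profile SE for theta from the observed information of (theta, g_valid).
#' @noRd
cml_se <- function(bx, by, sx, sy, theta, invalid) {
  valid <- setdiff(seq_along(bx), invalid)
  g <- (bx[valid] / sx[valid]^2 + theta * by[valid] / sy[valid]^2) /
    (1 / sx[valid]^2 + theta^2 / sy[valid]^2)
  i_tt <- sum(g^2 / sy[valid]^2)
  i_tg <- (2 * theta * g - by[valid]) / sy[valid]^2
  i_gg <- 1 / sx[valid]^2 + theta^2 / sy[valid]^2
  info <- i_tt - sum(i_tg^2 / i_gg)
  if (info <= 0) mr_error("mr_convergence_error", "non-positive information in cML fit")
  sqrt(1 / info)
}

#' Constrained ML fit with a fixed number of invalid instruments
#'
#' Maximizes the pleiotropy-extended likelihood under the constraint
#' that exactly `K` instruments carry a nonzero pleiotropy term, by
#' block-coordinate iteration: given the causal effect, the K
#' instruments with the largest standardized outcome residuals are
#' declared invalid (their residual is absorbed by a free pleiotropy
#' term); the causal effect is then re-estimated from the valid set;
#' repeated to tolerance. SE from the observed Fisher information
#' restricted to the valid instruments.
#'
#' @param h a [harmonized_set()].
#' @param K number of invalid instruments, `0 <= K <= J - 2`.
#' @param n_eff effective sample size used by the BIC (e.g. the smaller
#'   of the exposure and outcome GWAS sizes).
#' @param tol convergence tolerance on the causal effect.
#' @param max_iter iteration budget; an invalid set still oscillating at
#'   the budget raises a convergence error reporting the cycle.
#' @param theta_init optional starting value (default: IVW).
#' @return list with `K`, `theta`, `se`, `invalid` (snp ids), `nll`,
#'   `bic`, `iter`.
#' @export
cml_fixed_k <- function(h, K, n_eff, tol = 1e-7, max_iter = 200, theta_init = NULL) {
  J <- nsnp(h)
  if (K < 0 || K > J - 2) {
    mr_error("mr_validation_error", sprintf("K must lie in [0, %d]", J - 2))
  }
  bx <- h$beta_exp; by <- h$beta_out; sx <- h$se_exp; sy <- h$se_out
  theta0 <- theta_init %||% ivw_core(bx, by, sy)$beta
  fit <- cml_iterate(bx, by, sx, sy, K, theta0, tol, max_iter)
  # polish theta to machine precision on the stabilized valid set by
  # closed-form gamma-profile / weighted-LS alternation
  valid <- setdiff(seq_len(J), fit$invalid)
  th <- fit$theta
  for (i in 1:100) {
    g <- (bx[valid] / sx[valid]^2 + th * by[valid] / sy[valid]^2) /
      (1 / sx[valid]^2 + th^2 / sy[valid]^2)
    th_new <- sum(g * by[valid] / sy[valid]^2) / sum(g^2 / sy[valid]^2)
    if (abs(th_new - th) < 1e-13 * (1 + abs(th))) { th <- th_new; break }
    th <- th_new
  }
  if (cml_profile_nll(th, bx[valid], by[valid], sx[valid], sy[valid]) <=
      cml_profile_nll(fit$theta, bx[valid], by[valid], sx[valid], sy[valid])) {
    fit$theta <- th
  }
  nll <- cml_nll(bx, by, sx, sy, fit$theta, fit$invalid)
  list(K = as.integer(K), theta = fit$theta,
       se = cml_se(bx, by, sx, sy, fit$theta, fit$invalid),
       invalid = h$snp[fit$invalid], invalid_idx = fit$invalid,
       nll = nll, bic = 2 * nll + K * log(n_eff), iter = fit$iter)
}

#' cML with BIC model averaging (cML-MA-BIC)
#'
#' Fits [cml_fixed_k()] for every plausible number of invalid
#' instruments `K = 0..K_max`, scores each by
#' `BIC_K = 2 * NLL_K + K * log(n_eff)`, and averages the causal
#' estimates with weights proportional to `exp(-(BIC_K - min BIC)/2)`.
#' The averaged variance combines within-model variance and
#' between-model spread:
#' `se_ma^2 = sum_K w_K (se_K^2 + (theta_K - theta_ma)^2)`.
#' Each K is fitted from several seeded random restarts of the starting
#' value to escape local optima of the invalid-set support; the best
#' likelihood is kept.
#'
#' @inheritParams cml_fixed_k
#' @param K_max largest K considered (default `J - 2`, the identifiable
#'   maximum).
#' @param n_restart random restarts per K (default 5).
#' @param seed integer seed for the restarts.
#' @return object of class `cml_ma`: `theta`, `se`, `pval`
#'   (model-averaged, normal-based), `per_k` (data.frame of K, theta,
#'   se, nll, bic, weight, n_invalid), `invalid_best` (snp ids at the
#'   BIC-minimal K), `n_eff`.
#' @export
cml_ma_bic <- function(h, n_eff, K_max = NULL, n_restart = 5, seed = 1L,
                       tol = 1e-7, max_iter = 200) {
  J <- nsnp(h)
  if (J < 3) mr_error("mr_insufficient_instruments", "cML-MA-BIC needs >= 3 instruments")
  if (is.null(n_eff) || is.na(n_eff) || n_eff <= 1) {
    mr_error("mr_validation_error", "n_eff must exceed 1")
  }
  K_max <- K_max %||% (J - 2)
  K_max <- min(K_max, J - 2)
  ivw0 <- ivw_core(h$beta_exp, h$beta_out, h$se_out)
  # restart the discrete support search from diverse causal-effect
  # hypotheses: the IVW fit, the null, and randomly chosen single-
  # instrument Wald ratios (at least one of which tracks the valid
  # instruments when a majority is valid)
  ratios <- h$beta_out / h$beta_exp
  starts <- with_seed(seed, {
    extra <- if (n_restart > 2) {
      sample(ratios, min(n_restart - 2, length(ratios)))
    } else {
      numeric(0)
    }
    unique(c(ivw0$beta, 0, extra))
  })
  fits <- vector("list", K_max + 1)
  for (K in 0:K_max) {
    best <- NULL
    errs <- character(0)
    for (s in starts) {
      f <- tryCatch(
        cml_fixed_k(h, K, n_eff, tol, max_iter, theta_init = s),
        mr_convergence_error = function(e) e
      )
      if (inherits(f, "error")) {
        errs <- c(errs, conditionMessage(f))
      } else if (is.null(best) || f$nll < best$nll) {
        best <- f
      }
    }
    if (is.null(best)) {
      mr_error("mr_convergence_error",
               sprintf("no cML restart converged at K=%d: %s", K, errs[1]))
    }
    fits[[K + 1]] <- best
  }
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  theta_k <- vapply(fits, `[[`, numeric(1), "theta")
  se_k <- vapply(fits, `[[`, numeric(1), "se")
  wt <- exp(-(bic - min(bic)) / 2)
  wt <- wt / sum(wt)
  theta_ma <- sum(wt * theta_k)
  se_ma <- sqrt(sum(wt * (se_k^2 + (theta_k - theta_ma)^2)))
  per_k <- data.frame(
    K = vapply(fits, `[[`, integer(1), "K"),
    theta = theta_k, se = se_k,
    nll = vapply(fits, `[[`, numeric(1), "nll"),
    bic = bic, weight = wt,
    n_invalid = vapply(fits, function(f) length(f$invalid), integer(1))
  )
  structure(
    list(exposure = h$exposure_name, outcome = h$outcome_name,
         theta = theta_ma, se = se_ma, pval = norm_p(theta_ma, se_ma),
         per_k = per_k,
         invalid_best = fits[[which.min(bic)]]$invalid,
         n_eff = n_eff, nsnp = J),
    class = "cml_ma"
  )
}

#' @export
print.cml_ma <- function(x, ...) {
  cat(sprintf("cML-MA-BIC: theta = %.4g (se %.4g, p = %.3g), %d instruments, n_eff = %g\n",
              x$theta, x$se, x$pval, x$nsnp, x$n_eff))
  best <- x$per_k[which.min(x$per_k$bic), ]
  cat(sprintf("  BIC-minimal K = %d (weight %.3f)", best$K, best$weight))
  if (length(x$invalid_best)) {
    cat(":", paste(x$invalid_best, collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.cml_ma <- function(x, ...) {
  cbind(data.frame(exposure = x$exposure, outcome = x$outcome,
                   stringsAsFactors = FALSE),
        mr_estimate("cml_ma_bic", x$theta, x$se, x$nsnp, pval = x$pval))
}
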
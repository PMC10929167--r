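# Univariable estimators against closed-form values and oracles.

test_that("Wald ratio follows the delta-method formulas", {
  w <- wald_ratio(0.1, 0.02, 0.05, 0.03)
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 0.3)
  expect_equal(wald_ratio(0.1, 0.02, 0, 0.03)$beta, 0)
  expect_equal(wald_ratio(0.2, 0.04, 0.05, 0.03)$beta, 0.25)
  expect_error(wald_ratio(0, 0.02, 0.05, 0.03), class = "mr_degenerate_instrument")
  # second-order SE is never smaller
  expect_gte(wald_ratio(0.1, 0.02, 0.05, 0.03, second_order = TRUE)$se, w$se)
  # normal CI at 1.96 SEs
  expect_equal(w$ci_high - w$beta, 1.96 * w$se, tolerance = 1e-3)
})

test_that("IVW reproduces the hand-worked weighted-least-squares example", {
  h <- make_h(c(0.1, 0.2, 0.15), c(0.05, 0.11, 0.06), sy = c(0.05, 0.05, 0.1))
  est <- mr_ivw(h, mr_config(ivw_mode = "fixed"))
  # closed-form: weights bx^2/sy^2 = (4, 16, 2.25) on ratios (0.5, 0.55, 0.4)
  expect_equal(est$beta, 11.7 / 22.25, tolerance = 1e-12)
  expect_equal(est$beta, 0.5258, tolerance = 1e-4)
  expect_equal(est$se, 1 / sqrt(22.25), tolerance = 1e-12)
  expect_equal(est$se, 0.2120, tolerance = 1e-4)

  # single instrument reduces to the Wald ratio
  h1 <- make_h(0.1, 0.05, 0.02, 0.03)
  expect_equal(mr_ivw(h1)$beta, wald_ratio(0.1, 0.02, 0.05, 0.03)$beta)
  expect_equal(mr_ivw(h1)$se, wald_ratio(0.1, 0.02, 0.05, 0.03)$se)

  # degenerate homogeneity: all ratios equal c
  hc <- make_h(c(0.1, 0.2, 0.4), c(0.1, 0.2, 0.4) * -0.7)
  expect_equal(mr_ivw(hc)$beta, -0.7, tolerance = 1e-12)
  expect_equal(cochran_q(hc)$Q, 0, tolerance = 1e-20)
})

test_that("IVW and Egger agree with the generic weighted-regression oracle", {
  for (seed in 1:10) {
    h <- rand_h(J = 10, theta = runif(1, -2, 2), seed = seed)
    o <- oracle_ivw(h)
    est <- mr_ivw(h, mr_config(ivw_mode = "fixed"))
    expect_equal(est$beta, o$beta, tolerance = 1e-10)
    expect_equal(est$se, o$se_fixed, tolerance = 1e-10)

    oe <- oracle_egger(h)
    ef <- mr_egger(h)
    expect_equal(ef$slope$beta, oe$slope, tolerance = 1e-10)
    expect_equal(ef$slope$se, oe$se_slope, tolerance = 1e-10)
    expect_equal(ef$intercept$estimate, oe$intercept, tolerance = 1e-10)
    expect_equal(ef$intercept$se, oe$se_intercept, tolerance = 1e-10)

    # random-effects SE never undercuts the fixed-effect SE
    expect_gte(mr_ivw(h)$se, est$se)
  }
})

test_that("Egger recovers an exact linear law and a null intercept", {
  bx <- c(0.08, 0.12, 0.2, 0.25, 0.3)
  h <- make_h(bx, 0.04 - 1.2 * bx)
  ef <- mr_egger(h)
  expect_equal(ef$slope$beta, -1.2, tolerance = 1e-12)
  expect_equal(ef$intercept$estimate, 0.04, tolerance = 1e-12)
  expect_equal(ef$intercept$df, 3)

  hc <- make_h(bx, 0.8 * bx)
  efc <- mr_egger(hc)
  expect_equal(efc$slope$beta, 0.8, tolerance = 1e-10)
  expect_equal(efc$intercept$estimate, 0, tolerance = 1e-10)
  expect_error(mr_egger(make_h(bx[1:2], bx[1:2])),
               class = "mr_insufficient_instruments")
})

test_that("maximum likelihood matches IVW when exposure noise vanishes", {
  h <- rand_h(J = 12, theta = -0.8, seed = 3, sx_scale = 1e-6)
  ml <- mr_maximum_likelihood(h)
  ivw <- mr_ivw(h, mr_config(ivw_mode = "fixed"))
  expect_equal(ml$beta, ivw$beta, tolerance = 1e-4)
  expect_equal(ml$se, ivw$se, tolerance = 1e-4)
  expect_error(mr_maximum_likelihood(make_h(0.1, 0.05)),
               class = "mr_insufficient_instruments")
})

test_that("the ML optimum improves on its IVW start and covers the null", {
  nll <- function(theta, g, h) {
    sum((h$beta_exp - g)^2 / (2 * h$se_exp^2)) +
      sum((h$beta_out - theta * g)^2 / (2 * h$se_out^2))
  }
  for (seed in 1:5) {
    h <- rand_h(J = 15, theta = 1, seed = seed, sx_scale = 5)
    ml <- mr_maximum_likelihood(h)
    start <- mr_ivw(h, mr_config(ivw_mode = "fixed"))$beta
    g_at <- function(th) (h$beta_exp / h$se_exp^2 + th * h$beta_out / h$se_out^2) /
      (1 / h$se_exp^2 + th^2 / h$se_out^2)
    expect_lte(nll(ml$beta, g_at(ml$beta), h), nll(start, g_at(start), h) + 1e-8)
  }

  # under the null the standardized estimate stays within 3 SE
  cover <- vapply(1:150, function(s) {
    sim <- simulate_mr_pair(sim_config(instruments_per_taxon = 50, theta = 0,
                                       seed = 5000 + s))
    h <- harmonize(sim$exposures[[1]], sim$outcome)
    ml <- mr_maximum_likelihood(h)
    abs(ml$beta) < 3 * ml$se
  }, logical(1))
  expect_gte(mean(cover), 0.99)
})

test_that("weighted median interpolates the weighted ratio distribution", {
  # equal weights: plain median
  h <- make_h(c(0.1, 0.1, 0.1), c(0.01, 0.05, 0.09))
  cfg <- mr_config(n_boot = 100, seed = 7)
  expect_equal(mr_weighted_median(h, cfg)$beta, 0.5)

  # dominant weight drags the estimate past the unweighted median
  bx <- c(0.1, 0.1, 0.1 * sqrt(6))
  by <- c(0.1, 0.5, 0.9) * bx
  h2 <- make_h(bx, by)
  est <- mr_weighted_median(h2, cfg)
  expect_equal(est$beta, oracle_wmedian(by / bx, bx^2 / h2$se_out^2),
               tolerance = 1e-10)
  expect_gt(est$beta, 0.5)
  expect_lte(est$beta, 0.9)

  # seeding contract for the bootstrap SE
  big <- mr_config(n_boot = 1000, seed = 11)
  h3 <- rand_h(J = 12, theta = 0.4, seed = 9)
  se1 <- mr_weighted_median(h3, big)$se
  se2 <- mr_weighted_median(h3, big)$se
  se3 <- mr_weighted_median(h3, mr_config(n_boot = 1000, seed = 12))$se
  expect_identical(se1, se2)
  expect_false(identical(se1, se3))
  expect_lt(abs(se1 - se3) / se1, 0.10)
})

test_that("weighted mode finds the majority cluster", {
  cfg <- mr_config(n_boot = 100, seed = 2)
  # all ratios identical: the common ratio, bootstrap SE still finite
  h <- make_h(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3) * 1.5)
  est <- mr_weighted_mode(h, cfg)
  expect_equal(est$beta, 1.5, tolerance = 1e-12)
  expect_true(is.finite(est$se))

  # 7 ratios near -2 vs 3 near +1 with comparable weights
  set.seed(21)
  ratios <- c(rnorm(7, -2, 0.05), rnorm(3, 1, 0.05))
  bx <- rep(0.15, 10)
  h2 <- make_h(bx, ratios * bx)
  est2 <- mr_weighted_mode(h2, cfg)
  expect_lt(abs(est2$beta - (-2)), 0.3)

  # doubling the bandwidth factor is stable when the clusters sit many
  # bandwidths apart (majority cluster tight enough to pin the IQR)
  set.seed(22)
  ratios3 <- c(rnorm(8, -2, 0.01), rnorm(2, 1, 0.01))
  h3 <- make_h(rep(0.15, 10), ratios3 * 0.15)
  m1 <- mr_weighted_mode(h3, cfg)$beta
  m2 <- mr_weighted_mode(h3, mr_config(n_boot = 100, seed = 2,
                                       mode_bandwidth_factor = 2))$beta
  expect_lt(abs(m1 - m2), 0.05)
  expect_lt(abs(m1 - (-2)), 0.05)
})

test_that("estimators are sign-anti-symmetric and scale-equivariant", {
  cfg <- mr_config(n_boot = 100, seed = 5)
  fits <- function(h) {
    c(ivw = mr_ivw(h, cfg)$beta,
      ml = mr_maximum_likelihood(h, cfg)$beta,
      egger = mr_egger(h, cfg)$slope$beta,
      median = mr_weighted_median(h, cfg)$beta,
      mode = mr_weighted_mode(h, cfg)$beta)
  }
  ses <- function(h) {
    c(ivw = mr_ivw(h, cfg)$se,
      ml = mr_maximum_likelihood(h, cfg)$se,
      egger = mr_egger(h, cfg)$slope$se)
  }
  for (seed in 1:4) {
    h <- rand_h(J = 10, theta = 0.7, seed = 40 + seed)
    base <- fits(h)

    hneg <- make_h(h$beta_exp, -h$beta_out, h$se_exp, h$se_out)
    expect_equal(fits(hneg), -base, tolerance = 1e-8)
    expect_equal(ses(hneg), ses(h), tolerance = 1e-8)

    hsc <- make_h(2 * h$beta_exp, h$beta_out, 2 * h$se_exp, h$se_out)
    expect_equal(fits(hsc), base / 2, tolerance = 1e-6)
  }
})

test_that("mr_fit bundles methods with working S3 accessors", {
  h <- rand_h(J = 10, theta = -1, seed = 2)
  fit <- mr_fit(h, config = mr_config(n_boot = 100, seed = 3))
  expect_s3_class(fit, "mr_fit")
  expect_setequal(fit$estimates$method,
                  c("ivw", "maximum_likelihood", "egger",
                    "weighted_median", "weighted_mode"))
  expect_equal(unname(coef(fit)["ivw"]), mr_ivw(h, fit$config)$beta)
  ci <- confint(fit)
  expect_true(all(ci[, 1] <= coef(fit) & coef(fit) <= ci[, 2]))
  expect_equal(length(residuals(fit)), 10)
  expect_output(print(fit), "ivw")
  expect_output(print(summary(fit)), "Cochran")
  expect_error(mr_fit(h, methods = "nope"), class = "mr_config_error")

  p <- tempfile(fileext = ".tsv")
  write_estimates(fit, p)
  expect_equal(nrow(read.delim(p)), nrow(fit$estimates))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
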
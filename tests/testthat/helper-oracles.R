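# Shared builders and independent oracles used across the suite.

# Harmonized set straight from effect vectors.
make_h <- function(bx, by, sx = rep(0.01, length(bx)), sy = rep(0.05, length(bx)),
                   ...) {
  harmonized_set(paste0("rs", seq_along(bx)), beta_exp = bx, se_exp = sx,
                 beta_out = by, se_out = sy, ...)
}

# Random small instance under a fixed seed.
rand_h <- function(J = 8, theta = 0.5, seed = 1, sx_scale = 1) {
  set.seed(seed)
  bx <- runif(J, 0.05, 0.3) * sample(c(-1, 1), J, replace = TRUE)
  sx <- runif(J, 0.005, 0.02) * sx_scale
  sy <- runif(J, 0.02, 0.1)
  by <- theta * bx + rnorm(J, 0, sy)
  make_h(bx, by, sx, sy)
}

# Generic weighted-least-squares oracle via lm(): IVW is the
# no-intercept fit, fixed-effect SE is the lm SE divided by the
# residual scale.
oracle_ivw <- function(h) {
  d <- as.data.frame(h)
  fit <- lm(beta_out ~ 0 + beta_exp, data = d, weights = 1 / d$se_out^2)
  s <- summary(fit)
  list(beta = unname(coef(fit)), se_fixed = unname(s$coefficients[1, 2] / s$sigma))
}

# Egger oracle: same lm route after re-orienting to beta_exp >= 0,
# with the no-underdispersion SE adjustment.
oracle_egger <- function(h) {
  flip <- ifelse(h$beta_exp < 0, -1, 1)
  d <- data.frame(bx = h$beta_exp * flip, by = h$beta_out * flip)
  fit <- lm(by ~ bx, data = d, weights = 1 / h$se_out^2)
  s <- summary(fit)
  adj <- sqrt(max(1, s$sigma^2)) / s$sigma
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       se_intercept = unname(s$coefficients[1, 2]) * adj,
       se_slope = unname(s$coefficients[2, 2]) * adj)
}

# Weighted-median oracle: interpolate the ordered ratios at
# standardized cumulative weight 0.5 via approx().
oracle_wmedian <- function(ratio, weight) {
  o <- order(ratio)
  r <- ratio[o]
  w <- weight[o] / sum(weight)
  p <- cumsum(w) - w / 2
  approx(p, r, xout = 0.5, rule = 2)$y
}

# Greedy clump oracle: direct recursion, one survivor at a time.
oracle_clump <- function(records, ld, r2_threshold, window) {
  if (nrow(records) == 0) return(character(0))
  d <- records[order(records$pval, records$snp), , drop = FALSE]
  best <- d[1, ]
  rest <- d[-1, , drop = FALSE]
  if (nrow(rest)) {
    r2 <- ld_r2(ld, best$snp, rest$snp)
    kill <- rest$chrom == best$chrom &
      abs(rest$pos - best$pos) <= window & r2 >= r2_threshold
    rest <- rest[!kill, , drop = FALSE]
  }
  c(best$snp, oracle_clump(rest, ld, r2_threshold, window))
}

# Minimal instrument record table.
make_records <- function(snp, pval, chrom = "1", pos = seq_along(snp) * 1e3,
                         beta = 0.1, se = 0.01, ea = "A", oa = "G", eaf = 0.3,
                         n = 10000) {
  data.frame(snp = snp, chrom = chrom, pos = pos,
             effect_allele = ea, other_allele = oa,
             beta = beta, se = se, pval = pval, eaf = eaf, n = n,
             stringsAsFactors = FALSE)
}
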
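# The synthetic summary-statistic generator.

test_that("configs are validated", {
  expect_error(sim_config(n_taxa = 0), class = "mr_validation_error")
  expect_error(sim_config(instruments_per_taxon = 0), class = "mr_validation_error")
  expect_error(sim_config(pleiotropy_frac = 1.2), class = "mr_validation_error")
  expect_error(sim_config(n_x = 50), class = "mr_validation_error")
  expect_error(sim_config(maf_range = c(0, 0.5)), class = "mr_validation_error")
  expect_error(sim_config(swapped_frac = -0.1), class = "mr_validation_error")
})

test_that("the same seed reproduces the dataset byte for byte", {
  cfg <- sim_config(n_taxa = 3, instruments_per_taxon = 6, theta = c(-1, 0, 1),
                    pleiotropy_frac = 0.3, swapped_frac = 0.2,
                    palindromic_frac = 0.2, ld_block_size = 2,
                    outcome_instruments = 4, cross_effects = TRUE, seed = 42)
  a <- simulate_mr_pair(cfg)
  b <- simulate_mr_pair(cfg)
  expect_identical(a$exposures, b$exposures)
  expect_identical(a$outcome, b$outcome)
  expect_identical(a$truth$instruments, b$truth$instruments)
  d1 <- tempfile(); d2 <- tempfile()
  write_sim(a, d1); write_sim(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  c2 <- simulate_mr_pair(sim_config(n_taxa = 3, instruments_per_taxon = 6,
                                    theta = c(-1, 0, 1), seed = 43))
  expect_false(identical(a$exposures[[1]]$beta, c2$exposures[[1]]$beta))
})

test_that("emitted tables satisfy the reader invariants with zero rejects", {
  sim <- simulate_mr_pair(sim_config(n_taxa = 2, instruments_per_taxon = 8,
                                     palindromic_frac = 0.25, swapped_frac = 0.25,
                                     outcome_instruments = 3, seed = 8))
  d <- tempfile()
  write_sim(sim, d)
  for (f in grep("taxon|outcome", list.files(d, full.names = TRUE), value = TRUE)) {
    if (grepl("\\.tsv$", f) && !grepl("ld", f)) {
      got <- read_summary_stats(f)
      expect_equal(nrow(attr(got, "rejects")), 0)
      expect_gt(nrow(got), 0)
    }
  }
  tr <- jsonlite::read_json(file.path(d, "truth.json"))
  expect_equal(length(tr$theta), 2)
})

test_that("standard errors follow the 1/sqrt(2p(1-p)n) law", {
  s1 <- simulate_mr_pair(sim_config(instruments_per_taxon = 200, seed = 5))
  s2 <- simulate_mr_pair(sim_config(instruments_per_taxon = 200, n_x = 2 * 18340,
                                    seed = 5))
  ratio <- median(s1$exposures[[1]]$se) / median(s2$exposures[[1]]$se)
  expect_lt(abs(ratio - sqrt(2)), 0.01 * sqrt(2))
})

test_that("large samples let IVW recover the planted causal effect", {
  est <- vapply(1:5, function(s) {
    sim <- simulate_mr_pair(sim_config(instruments_per_taxon = 50, theta = -1,
                                       n_x = 1e6, n_y = 1e6, seed = s))
    h <- harmonize(sim$exposures[[1]], sim$outcome)
    mr_ivw(h)$beta
  }, numeric(1))
  expect_lt(abs(mean(est) - (-1)), 0.05)
})

test_that("harmonization undoes planted allele swaps exactly", {
  base <- sim_config(instruments_per_taxon = 20, theta = -0.8,
                     palindromic_frac = 0.2, seed = 23)
  corrupt <- base; corrupt$swapped_frac <- 0.3
  clean <- simulate_mr_pair(base)
  swapped <- simulate_mr_pair(corrupt)
  # identical generation apart from the outcome coding
  expect_identical(clean$exposures, swapped$exposures)

  h_clean <- harmonize(clean$exposures[[1]], clean$outcome)
  h_swap <- harmonize(swapped$exposures[[1]], swapped$outcome)
  expect_equal(h_swap$beta_out, h_clean$beta_out, tolerance = 1e-10)
  expect_equal(mr_ivw(h_swap)$beta, mr_ivw(h_clean)$beta, tolerance = 1e-10)

  # skipping harmonization (raw join) gives different answers
  raw <- clean$exposures[[1]]
  raw$beta <- swapped$outcome$beta[match(raw$snp, swapped$outcome$snp)]
  raw_beta <- mrscreen:::ivw_core(h_clean$beta_exp,
                                  raw$beta[match(h_clean$snp, raw$snp)],
                                  h_clean$se_out)$beta
  expect_gt(abs(raw_beta - mr_ivw(h_clean)$beta), 1e-3)
})

test_that("pleiotropy types shape the planted effects as documented", {
  bal <- simulate_mr_pair(sim_config(instruments_per_taxon = 40,
                                     pleiotropy_frac = 0.5,
                                     pleiotropy_type = "balanced", seed = 3))
  dir <- simulate_mr_pair(sim_config(instruments_per_taxon = 40,
                                     pleiotropy_frac = 0.5,
                                     pleiotropy_type = "directional", seed = 3))
  cor_ <- simulate_mr_pair(sim_config(instruments_per_taxon = 200,
                                      pleiotropy_frac = 1,
                                      pleiotropy_type = "correlated", seed = 3))
  r_bal <- bal$truth$instruments$r
  r_dir <- dir$truth$instruments$r
  expect_equal(sum(r_bal != 0), 20)
  expect_true(any(r_bal < 0))
  expect_true(all(r_dir >= 0))
  tr <- cor_$truth$instruments
  expect_gt(abs(cor(tr$r, tr$gamma)), 0.5)  # InSIDE violated by design
})

test_that("null panels force every causal effect to zero", {
  panel <- make_null_panel(sim_config(n_taxa = 5, theta = c(1, -1, 2, 0, 3),
                                      seed = 12))
  expect_equal(unname(panel$truth$theta), rep(0, 5))
  expect_equal(length(panel$exposures), 5)
})
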
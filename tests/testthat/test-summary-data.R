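# Readers, writers, palindrome detection, and harmonization.

write_fixture <- function(d, path, headers = default_dialect()) {
  names(d) <- unname(headers[names(d)])
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

fixture_df <- function() {
  data.frame(snp = c("rs1", "rs2", "rs3"), chrom = "1", pos = c(100, 200, 300),
             effect_allele = c("A", "C", "T"), other_allele = c("G", "T", "C"),
             beta = c(0.10, -0.05, 0.20), se = c(0.01, 0.02, 0.04),
             pval = c(1e-8, 1e-3, 5e-7), eaf = c(0.30, 0.45, 0.10),
             n = 18340, stringsAsFactors = FALSE)
}

test_that("reading round-trips through writing and honors dialects", {
  d <- fixture_df()
  p1 <- tempfile(fileext = ".tsv")
  write_fixture(d, p1)
  got <- read_summary_stats(p1)
  expect_equal(nrow(got), 3)
  expect_equal(nrow(attr(got, "rejects")), 0)
  expect_equal(got$beta, d$beta)

  # re-serialization is byte-identical
  p2 <- tempfile(fileext = ".tsv")
  p3 <- tempfile(fileext = ".tsv")
  write_summary_stats(got, p2)
  write_summary_stats(read_summary_stats(p2), p3)
  expect_identical(readLines(p2), readLines(p3))

  # remapped headers give identical records
  p4 <- tempfile(fileext = ".tsv")
  write_fixture(d, p4, default_dialect(beta = "ES", se = "SE"))
  got2 <- read_summary_stats(p4, default_dialect(beta = "ES", se = "SE"))
  attr(got2, "rejects") <- attr(got, "rejects")
  expect_equal(got2, got)

  # csv dialect inferred from extension
  p5 <- tempfile(fileext = ".csv")
  write_summary_stats(got, p5)
  expect_equal(read_summary_stats(p5)$beta, d$beta)
})

test_that("invalid rows are rejected with line numbers and reasons", {
  d <- fixture_df()
  d$se[2] <- 0
  d$pval[3] <- 0
  d <- rbind(d, within(d[1, ], { snp <- "rs4"; effect_allele <- "AT" }))
  p <- tempfile(fileext = ".tsv")
  write_fixture(d, p)
  got <- read_summary_stats(p)
  rej <- attr(got, "rejects")
  expect_equal(nrow(got), 1)
  expect_equal(rej$line, c(3L, 4L, 5L))
  expect_match(rej$reason[rej$snp == "rs2"], "se")
  expect_match(rej$reason[rej$snp == "rs3"], "pval")
  expect_match(rej$reason[rej$snp == "rs4"], "allele")
  rp <- tempfile()
  write_rejects(got, rp)
  expect_equal(nrow(read.delim(rp)), 3)
})

test_that("missing required columns and unreadable files raise typed errors", {
  d <- fixture_df()
  d$se <- NULL
  p <- tempfile(fileext = ".tsv")
  write_fixture(d, p, default_dialect()[names(default_dialect()) != "se"])
  expect_error(read_summary_stats(p), class = "mr_config_error")
  expect_error(read_summary_stats(tempfile()), class = "mr_io_error")
})

test_that("palindrome detection follows the strand-ambiguity definition", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("C", "G"))
  expect_true(is_palindromic("G", "C"))
  expect_false(is_palindromic("A", "G"))
  expect_equal(is_palindromic(c("a", "t"), c("t", "C")), c(TRUE, FALSE))
  expect_error(is_palindromic("A", "U"), class = "mr_validation_error")
})

test_that("harmonization aligns, flips, proxies and removes as specified", {
  exp <- make_records(c("rs1", "rs2", "rs3", "rs4", "rs5"), pval = 1e-8)
  exp$effect_allele <- c("A", "A", "A", "A", "A")
  exp$other_allele <- c("G", "T", "C", "G", "G")
  out <- make_records(c("rs1", "rs2", "rs3", "rs6"), pval = 0.5)
  out$effect_allele <- c("G", "A", "A", "A")
  out$other_allele <- c("A", "T", "C", "G")
  out$beta <- c(0.05, 0.02, 0.03, 0.07)
  out$eaf <- c(0.25, 0.5, 0.3, 0.3)

  proxies <- data.frame(target_id = "rs5", proxy_id = "rs6", r2 = 0.9)
  h <- harmonize(exp, out, proxy_map = proxies)
  aud <- setNames(h$audit$disposition, h$audit$snp)
  expect_equal(unname(aud[c("rs1", "rs2", "rs3", "rs4", "rs5")]),
               c("sign_flipped", "removed_palindromic", "kept",
                 "removed_missing_in_outcome", "proxied"))
  # swapped coding: beta negated, eaf complemented
  expect_equal(h$beta_out[h$snp == "rs1"], -0.05)
  expect_equal(h$eaf_out[h$snp == "rs1"], 0.75)
  expect_equal(h$beta_out[h$snp == "rs5"], 0.07)

  # audit conservation
  expect_setequal(h$audit$snp, exp$snp)
  expect_equal(sum(aud %in% c("kept", "sign_flipped", "proxied")), length(h$snp))

  # incompatible alleles
  out2 <- out
  out2$effect_allele[3] <- "A"; out2$other_allele[3] <- "G"
  h2 <- harmonize(exp, out2, proxy_map = proxies)
  expect_equal(h2$audit$disposition[h2$audit$snp == "rs3"], "removed_mismatch")

  # proxy below the r2 threshold is not used
  h3 <- harmonize(exp, out, proxy_map = transform(proxies, r2 = 0.5))
  expect_equal(h3$audit$disposition[h3$audit$snp == "rs5"],
               "removed_missing_in_outcome")

  # empty intersection names the pair
  expect_error(harmonize(exp[4, ], out, exposure_name = "tax", outcome_name = "irae"),
               "tax", class = "mr_empty_set")
})

test_that("EAF rescue resolves palindromes only when frequencies are informative", {
  exp <- make_records("rs1", 1e-8, ea = "A", oa = "T", eaf = 0.1)
  out <- make_records("rs1", 0.5, ea = "A", oa = "T", eaf = 0.85)
  out$beta <- 0.04
  # default: removed regardless of EAF
  expect_error(harmonize(exp, out), class = "mr_empty_set")
  # rescue: opposite minor sides -> orientation flip
  h <- harmonize(exp, out, eaf_rescue = TRUE)
  expect_equal(h$beta_out, -0.04)
  expect_equal(h$audit$disposition, "sign_flipped")
  # uninformative frequency: still removed
  out$eaf <- 0.5
  expect_error(harmonize(exp, out, eaf_rescue = TRUE), class = "mr_empty_set")
})

test_that("harmonization is idempotent and sign-anti-symmetric", {
  for (seed in 1:5) {
    sim <- simulate_mr_pair(sim_config(instruments_per_taxon = 12,
                                       swapped_frac = 0.3, palindromic_frac = 0.2,
                                       seed = seed))
    exp <- sim$exposures[[1]]
    h1 <- harmonize(exp, sim$outcome)

    # audit conservation over all dispositions
    expect_equal(nrow(h1$audit), nrow(exp))
    expect_equal(sum(h1$audit$disposition %in% c("kept", "sign_flipped", "proxied")),
                 length(h1$snp))

    # idempotence: feed the harmonized outcome back in
    out2 <- exp[match(h1$snp, exp$snp), ]
    out2$beta <- h1$beta_out; out2$se <- h1$se_out; out2$eaf <- h1$eaf_out
    h2 <- harmonize(exp[match(h1$snp, exp$snp), ], out2)
    expect_equal(h2$beta_out, h1$beta_out)
    expect_equal(h2$snp, h1$snp)
    expect_true(all(h2$audit$disposition == "kept"))

    # negating outcome betas negates beta_out, everything else equal
    outneg <- sim$outcome
    outneg$beta <- -outneg$beta
    h3 <- harmonize(exp, outneg)
    expect_equal(h3$snp, h1$snp)
    expect_equal(h3$beta_out, -h1$beta_out)
    expect_equal(h3$se_out, h1$se_out)
  }
})
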
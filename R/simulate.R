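# Synthetic paired exposure/outcome GWAS summary statistics with known
# truth, LD structure, and harmonization hazards.
#
# The generator emulates the statistical structure of a microbiome-GWAS
# to immunotherapy-toxicity MR study: per-taxon instrument effects on
# relative abundance with consortium-scale standard errors, an outcome
# generated as causal effect x instrument effect + pleiotropy + noise on
# a time-to-event scale (negative beta = shorter time to event = higher
# risk), block LD for clumping, and optional palindromic or
# allele-swapped records to exercise harmonization.

#' Simulation configuration
#'
#' Defaults encode the study conditions the package targets: an
#' 18,340-participant exposure consortium and a 1,751-patient outcome
#' cohort, 7 instruments per taxon (the published screen retained
#' 870 SNPs over 132 taxa), and per-instrument F statistics drawn
#' uniformly on (17, 37), spanning the published instrument-strength
#' range 16.91-36.57.
#'
#' @param n_taxa number of exposure taxa (>= 1).
#' @param instruments_per_taxon instruments simulated per taxon (>= 1).
#' @param theta true causal effect(s), recycled over taxa; 0 = null.
#' @param pleiotropy_frac fraction of instruments with a pleiotropic
#'   outcome effect, in \[0, 1\].
#' @param pleiotropy_scale magnitude (SD) of pleiotropic effects, on the
#'   outcome-beta scale.
#' @param pleiotropy_type `"balanced"` (zero-mean), `"directional"`
#'   (one-signed), or `"correlated"` (proportional to the instrument's
#'   exposure effect plus noise, violating InSIDE).
#' @param pleiotropy_cor proportionality constant for correlated
#'   pleiotropy.
#' @param n_x,n_y exposure and outcome GWAS sample sizes (>= 100).
#' @param maf_range range of minor-allele frequencies, within (0, 0.5].
#' @param f_range range of true per-instrument F statistics.
#' @param ld_block_size instruments per LD block (1 = independent).
#' @param ld_block_r2 within-block r2.
#' @param palindromic_frac fraction of instruments given A/T or C/G
#'   alleles.
#' @param swapped_frac fraction of outcome records emitted with swapped
#'   allele labels (and correspondingly negated beta) to exercise
#'   harmonization.
#' @param outcome_instruments extra variants affecting only the outcome
#'   (instruments for reverse MR).
#' @param cross_effects if TRUE each exposure table also reports (null)
#'   effects for every other taxon's instruments, as a genome-wide
#'   consortium release would; needed for multivariable and reverse MR.
#' @param seed master integer seed; one deterministic sub-stream per
#'   taxon.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 1, instruments_per_taxon = 7, theta = 0,
                       pleiotropy_frac = 0, pleiotropy_scale = 0.1,
                       pleiotropy_type = c("balanced", "directional", "correlated"),
                       pleiotropy_cor = 0.5,
                       n_x = 18340, n_y = 1751,
                       maf_range = c(0.05, 0.5), f_range = c(17, 37),
                       ld_block_size = 1, ld_block_r2 = 0.8,
                       palindromic_frac = 0, swapped_frac = 0,
                       outcome_instruments = 0, cross_effects = FALSE,
                       seed = 1L) {
  pleiotropy_type <- match.arg(pleiotropy_type)
  if (n_taxa < 1) mr_error("mr_validation_error", "n_taxa must be >= 1")
  if (instruments_per_taxon < 1) mr_error("mr_validation_error", "instruments_per_taxon must be >= 1")
  if (pleiotropy_frac < 0 || pleiotropy_frac > 1) {
    mr_error("mr_validation_error", "pleiotropy_frac must lie in [0, 1]")
  }
  if (n_x < 100 || n_y < 100) mr_error("mr_validation_error", "sample sizes must be >= 100")
  if (min(maf_range) <= 0 || max(maf_range) > 0.5) {
    mr_error("mr_validation_error", "maf_range must lie within (0, 0.5]")
  }
  if (any(c(palindromic_frac, swapped_frac) < 0) ||
      any(c(palindromic_frac, swapped_frac) > 1)) {
    mr_error("mr_validation_error", "fractions must lie in [0, 1]")
  }
  structure(
    list(n_taxa = as.integer(n_taxa),
         instruments_per_taxon = as.integer(instruments_per_taxon),
         theta = rep_len(theta, n_taxa),
         pleiotropy_frac = pleiotropy_frac, pleiotropy_scale = pleiotropy_scale,
         pleiotropy_type = pleiotropy_type, pleiotropy_cor = pleiotropy_cor,
         n_x = n_x, n_y = n_y, maf_range = maf_range, f_range = f_range,
         ld_block_size = as.integer(ld_block_size), ld_block_r2 = ld_block_r2,
         palindromic_frac = palindromic_frac, swapped_frac = swapped_frac,
         outcome_instruments = as.integer(outcome_instruments),
         cross_effects = isTRUE(cross_effects), seed = as.integer(seed)),
    class = "sim_config"
  )
}

NONPAL_PAIRS <- rbind(
  c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
  c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G")
)
PAL_PAIRS <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

# se of a per-allele effect on a standardized trait: 1/sqrt(2 p (1-p) n)
#' @noRd
gwas_se <- function(maf, n) 1 / sqrt(2 * maf * (1 - maf) * n)

#' Simulate a paired exposure/outcome summary-statistic dataset
#'
#' Per instrument j of taxon t: a MAF is drawn in `maf_range`; the
#' exposure SE is `1/sqrt(2 p (1-p) n_x)` (standardized-abundance
#' approximation) and the true effect `gamma_j` is `+-sqrt(F) * se`
#' with F drawn in `f_range`, so instruments clear the 1e-5 screen at
#' their nominal strength; the observed exposure effect is
#' `N(gamma_j, se_x^2)` and the observed outcome effect is
#' `N(theta_t * gamma_j + r_j, se_y^2)` with pleiotropy `r_j` nonzero
#' for a `pleiotropy_frac` fraction. Negative theta encodes a
#' risk-increasing taxon (shorter time to the adverse event).
#'
#' @param cfg a [sim_config()].
#' @return list with `exposures` (named list of summary-stat
#'   data.frames), `outcome` (data.frame), `truth` (per-taxon `theta`,
#'   per-instrument `gamma`/`r`/outlier flags, swapped/palindromic ids,
#'   seed), and `ld` (an [ld_reference()]).
#' @export
simulate_mr_pair <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  J <- cfg$instruments_per_taxon
  seeds <- with_seed(cfg$seed,
                     sample.int(2147483646L, cfg$n_taxa + 2L))
  taxa <- sprintf("taxon_%03d", seq_len(cfg$n_taxa))

  per_taxon <- vector("list", cfg$n_taxa)
  ld_rows <- list()
  idx0 <- 0L
  for (t in seq_len(cfg$n_taxa)) {
    per_taxon[[t]] <- with_seed(seeds[t], {
      maf <- stats::runif(J, cfg$maf_range[1], cfg$maf_range[2])
      se_x <- gwas_se(maf, cfg$n_x)
      se_y <- gwas_se(maf, cfg$n_y)
      f_true <- stats::runif(J, cfg$f_range[1], cfg$f_range[2])
      gamma <- sample(c(-1, 1), J, replace = TRUE) * sqrt(f_true) * se_x
      n_pleio <- round(cfg$pleiotropy_frac * J)
      pleio_idx <- if (n_pleio > 0) sample.int(J, n_pleio) else integer(0)
      r <- numeric(J)
      if (n_pleio > 0) {
        r[pleio_idx] <- switch(
          cfg$pleiotropy_type,
          balanced = stats::rnorm(n_pleio, 0, cfg$pleiotropy_scale),
          directional = abs(stats::rnorm(n_pleio, 0, cfg$pleiotropy_scale)),
          correlated = cfg$pleiotropy_cor * gamma[pleio_idx] /
            stats::sd(gamma) * cfg$pleiotropy_scale +
            stats::rnorm(n_pleio, 0, cfg$pleiotropy_scale / 2)
        )
      }
      beta_x <- stats::rnorm(J, gamma, se_x)
      beta_y <- stats::rnorm(J, cfg$theta[t] * gamma + r, se_y)
      n_pal <- round(cfg$palindromic_frac * J)
      pal_idx <- if (n_pal > 0) sample.int(J, n_pal) else integer(0)
      alleles <- NONPAL_PAIRS[sample.int(nrow(NONPAL_PAIRS), J, replace = TRUE), , drop = FALSE]
      if (n_pal > 0) {
        alleles[pal_idx, ] <- PAL_PAIRS[sample.int(nrow(PAL_PAIRS), n_pal, replace = TRUE), , drop = FALSE]
      }
      n_swap <- round(cfg$swapped_frac * J)
      swap_idx <- if (n_swap > 0) sample.int(J, n_swap) else integer(0)
      list(maf = maf, se_x = se_x, se_y = se_y, gamma = gamma, r = r,
           pleio_idx = pleio_idx, beta_x = beta_x, beta_y = beta_y,
           alleles = alleles, pal_idx = pal_idx, swap_idx = swap_idx)
    })
    idx0 <- idx0 + J
  }

  # genomic coordinates: taxa cycle over chromosomes; LD blocks sit
  # >10 Mb apart so only within-block pairs interact with clumping
  snp_id <- chrom <- character(0)
  pos <- numeric(0)
  for (t in seq_len(cfg$n_taxa)) {
    ids <- sprintf("rs%03d%04d", t, seq_len(J))
    block <- (seq_len(J) - 1) %/% cfg$ld_block_size
    within <- (seq_len(J) - 1) %% cfg$ld_block_size
    p <- 1e6 + block * 1.2e7 + within * 1e5
    per_taxon[[t]]$snp <- ids
    per_taxon[[t]]$chrom <- rep(as.character((t - 1) %% 22 + 1), J)
    per_taxon[[t]]$pos <- p
    if (cfg$ld_block_size > 1) {
      for (b in unique(block)) {
        members <- ids[block == b]
        if (length(members) > 1) {
          cmb <- utils::combn(members, 2)
          ld_rows[[length(ld_rows) + 1]] <- data.frame(
            snp_a = cmb[1, ], snp_b = cmb[2, ], r2 = cfg$ld_block_r2,
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  # outcome-only instruments (for reverse MR)
  outcome_extra <- NULL
  if (cfg$outcome_instruments > 0) {
    outcome_extra <- with_seed(seeds[cfg$n_taxa + 1L], {
      m <- cfg$outcome_instruments
      maf <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
      se_y <- gwas_se(maf, cfg$n_y)
      f_true <- stats::runif(m, cfg$f_range[1], cfg$f_range[2])
      gamma_out <- sample(c(-1, 1), m, replace = TRUE) * sqrt(f_true) * se_y
      list(snp = sprintf("rs900%04d", seq_len(m)),
           chrom = rep("22", m), pos = 2e8 + seq_len(m) * 1.2e7,
           maf = maf, se_y = se_y, gamma = gamma_out,
           beta_y = stats::rnorm(m, gamma_out, se_y),
           se_x = gwas_se(maf, cfg$n_x),
           alleles = NONPAL_PAIRS[((seq_len(m) - 1) %% nrow(NONPAL_PAIRS)) + 1, , drop = FALSE])
    })
  }

  all_snp <- unlist(lapply(per_taxon, `[[`, "snp"))
  mk_table <- function(snp, chrom, pos, ea, oa, beta, se, eaf, n) {
    data.frame(snp = snp, chrom = chrom, pos = pos,
               effect_allele = ea, other_allele = oa,
               beta = beta, se = se, pval = 2 * stats::pnorm(-abs(beta / se)),
               eaf = eaf, n = n, stringsAsFactors = FALSE)
  }

  # exposure tables: own instruments, plus (optionally) null effects for
  # every other taxon's instruments and the outcome-only variants
  exposures <- stats::setNames(vector("list", cfg$n_taxa), taxa)
  for (t in seq_len(cfg$n_taxa)) {
    pt <- per_taxon[[t]]
    tab <- mk_table(pt$snp, pt$chrom, pt$pos,
                    pt$alleles[, 1], pt$alleles[, 2],
                    pt$beta_x, pt$se_x, pt$maf, cfg$n_x)
    if (cfg$cross_effects) {
      cross <- with_seed(seed_for(seeds[cfg$n_taxa + 2L], taxa[t]), {
        rows <- list()
        for (u in seq_len(cfg$n_taxa)) {
          if (u == t) next
          pu <- per_taxon[[u]]
          rows[[length(rows) + 1]] <- mk_table(
            pu$snp, pu$chrom, pu$pos, pu$alleles[, 1], pu$alleles[, 2],
            stats::rnorm(J, 0, pu$se_x), pu$se_x, pu$maf, cfg$n_x)
        }
        if (!is.null(outcome_extra)) {
          oe <- outcome_extra
          rows[[length(rows) + 1]] <- mk_table(
            oe$snp, oe$chrom, oe$pos, oe$alleles[, 1], oe$alleles[, 2],
            stats::rnorm(length(oe$snp), 0, oe$se_x), oe$se_x, oe$maf, cfg$n_x)
        }
        do.call(rbind, rows)
      })
      tab <- rbind(tab, cross)
    }
    rownames(tab) <- NULL
    exposures[[t]] <- tab
  }

  # outcome table covers every taxon's instruments (plus its own)
  orows <- lapply(per_taxon, function(pt) {
    ea <- pt$alleles[, 1]; oa <- pt$alleles[, 2]
    beta <- pt$beta_y; eaf <- pt$maf
    if (length(pt$swap_idx)) {
      i <- pt$swap_idx
      tmp <- ea[i]; ea[i] <- oa[i]; oa[i] <- tmp
      beta[i] <- -beta[i]; eaf[i] <- 1 - eaf[i]
    }
    mk_table(pt$snp, pt$chrom, pt$pos, ea, oa, beta, pt$se_y, eaf, cfg$n_y)
  })
  if (!is.null(outcome_extra)) {
    oe <- outcome_extra
    orows[[length(orows) + 1]] <- mk_table(oe$snp, oe$chrom, oe$pos,
                                           oe$alleles[, 1], oe$alleles[, 2],
                                           oe$beta_y, oe$se_y, oe$maf, cfg$n_y)
  }
  outcome <- do.call(rbind, orows)
  rownames(outcome) <- NULL
  attr(outcome, "trait") <- "outcome"

  truth <- list(
    theta = stats::setNames(cfg$theta, taxa),
    instruments = do.call(rbind, lapply(seq_len(cfg$n_taxa), function(t) {
      pt <- per_taxon[[t]]
      data.frame(exposure = taxa[t], snp = pt$snp, gamma = pt$gamma,
                 r = pt$r, outlier = pt$r != 0,
                 palindromic = seq_len(J) %in% pt$pal_idx,
                 swapped_in_outcome = seq_len(J) %in% pt$swap_idx,
                 stringsAsFactors = FALSE)
    })),
    outcome_instruments = if (is.null(outcome_extra)) character(0) else outcome_extra$snp,
    seed = cfg$seed, config = cfg
  )
  ld <- ld_reference(if (length(ld_rows)) do.call(rbind, ld_rows) else NULL)
  list(exposures = exposures, outcome = outcome, truth = truth, ld = ld)
}

#' Simulate an all-null multi-taxon panel
#'
#' Convenience wrapper for screening-calibration studies: every taxon's
#' true causal effect is forced to zero.
#'
#' @param cfg a [sim_config()].
#' @return as [simulate_mr_pair()], with all-zero `truth$theta`.
#' @export
make_null_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  cfg$theta <- rep(0, cfg$n_taxa)
  simulate_mr_pair(cfg)
}

#' Write a simulated dataset to a directory
#'
#' Emits the same TSV dialect the readers consume (one file per
#' exposure, one outcome file), the LD reference in long format, and the
#' generating truth as JSON.
#'
#' @param sim result of [simulate_mr_pair()].
#' @param dir output directory (created if needed).
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(sim$exposures)) {
    write_summary_stats(sim$exposures[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  write_summary_stats(sim$outcome, file.path(dir, "outcome.tsv"))
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  env <- sim$ld$env
  keys <- ls(env)
  if (length(keys)) {
    parts <- strsplit(keys, "\r", fixed = TRUE)
    ld_tab <- data.frame(snp_a = vapply(parts, `[[`, "", 1),
                         snp_b = vapply(parts, `[[`, "", 2),
                         r2 = vapply(keys, get0, numeric(1), envir = env),
                         stringsAsFactors = FALSE)
  } else {
    ld_tab <- data.frame(snp_a = character(), snp_b = character(), r2 = numeric())
  }
  utils::write.table(ld_tab, file.path(dir, "ld.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
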
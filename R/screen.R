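# Orchestration: forward screen across many exposures, sensitivity
# battery, reverse MR, multiple-testing flags, reports.

#' Screen configuration
#'
#' All thresholds of the analysis pipeline in one place, at their
#' study defaults: instrument p-value 1e-5, clumping r2 0.001 within a
#' 10 Mb window, proxy r2 0.8, at least 3 instruments with F > 10 per
#' exposure, suggestive significance 0.05. The Bonferroni threshold is
#' always computed as `alpha / m` from the number of exposures actually
#' analyzed, never hard-coded.
#'
#' @param iv_pvalue instrument selection p-value threshold.
#' @param clump_r2,clump_window LD clumping parameters.
#' @param proxy_r2 minimum r2 for outcome-side proxy substitution.
#' @param min_snps minimum valid instruments per exposure.
#' @param f_min minimum instrument F statistic.
#' @param alpha suggestive significance level.
#' @param methods estimators run per pair, see [mr_fit()].
#' @param run_presso run MR-PRESSO where J >= `presso_min_snps`.
#' @param presso_n_sim MR-PRESSO null simulations.
#' @param presso_min_snps smallest instrument count at which MR-PRESSO
#'   is defined; below it the dual significance gate falls back to the
#'   IVW p-value alone (logged per pair).
#' @param run_cml run cML-MA-BIC per pair.
#' @param cml_restarts random restarts per cML fit.
#' @param n_eff BIC sample size for cML; default: smaller median GWAS
#'   sample size of the pair, if `n` columns are present.
#' @param drop_palindromic,proxy_map,trait_table harmonization and
#'   annotation inputs, see [harmonize()] and [annotate_confounders()].
#' @param ivw_mode,n_boot,mode_bandwidth_factor estimator settings, see
#'   [mr_config()].
#' @param store_loo keep the leave-one-out table per pair.
#' @param seed master seed; per-pair seeds are derived from it and the
#'   exposure name, so results are exposure-order invariant.
#' @return list of class `screen_config`.
#' @export
screen_config <- function(iv_pvalue = 1e-5, clump_r2 = 0.001, clump_window = 1e7,
                          proxy_r2 = 0.8, min_snps = 3, f_min = 10, alpha = 0.05,
                          methods = c("ivw", "maximum_likelihood", "egger",
                                      "weighted_median", "weighted_mode"),
                          run_presso = TRUE, presso_n_sim = 1000,
                          presso_min_snps = 4,
                          run_cml = TRUE, cml_restarts = 5, n_eff = NULL,
                          drop_palindromic = TRUE, proxy_map = NULL,
                          trait_table = NULL,
                          ivw_mode = "multiplicative_random", n_boot = 1000,
                          mode_bandwidth_factor = 1,
                          store_loo = FALSE, seed = 1L) {
  structure(as.list(environment()), class = "screen_config")
}

# Run the full battery on one already-selected exposure/outcome pair.
#' @noRd
screen_pair <- function(instruments, outcome, exposure_name, outcome_name, cfg) {
  pair_seed <- seed_for(cfg$seed, paste(exposure_name, outcome_name))
  mcfg <- mr_config(ivw_mode = cfg$ivw_mode, n_boot = cfg$n_boot,
                    mode_bandwidth_factor = cfg$mode_bandwidth_factor,
                    seed = pair_seed)
  h <- harmonize(instruments, outcome, proxy_map = cfg$proxy_map,
                 drop_palindromic = cfg$drop_palindromic, proxy_r2 = cfg$proxy_r2,
                 exposure_name = exposure_name, outcome_name = outcome_name)
  f <- f_statistic(h$beta_exp, h$se_exp)
  if (sum(f > cfg$f_min) < cfg$min_snps) {
    mr_error("mr_insufficient_instruments",
             sprintf("%s: only %d instrument(s) with F > %g after harmonization",
                     exposure_name, sum(f > cfg$f_min), cfg$f_min))
  }
  h <- subset_harmonized(h, f > cfg$f_min, "removed_weak")
  J <- nsnp(h)

  methods <- cfg$methods
  if (J == 1) methods <- "wald_ratio"
  fit <- mr_fit(h, methods = methods, config = mcfg)

  diag <- if (J >= 2) mr_diagnostics(h, mcfg, cfg$trait_table) else NULL
  if (!is.null(diag) && !cfg$store_loo) diag$loo <- diag$loo[0, ]

  presso <- NULL
  if (cfg$run_presso && J >= cfg$presso_min_snps) {
    presso <- run_presso(h, n_sim = cfg$presso_n_sim, seed = pair_seed,
                         config = mcfg)
  }

  cml <- NULL
  if (cfg$run_cml && J >= 3) {
    n_eff <- cfg$n_eff
    if (is.null(n_eff)) {
      cand <- c(stats::median(h$n_exp %||% NA_real_, na.rm = TRUE),
                stats::median(h$n_out %||% NA_real_, na.rm = TRUE))
      cand <- cand[is.finite(cand)]
      n_eff <- if (length(cand)) min(cand) else 1000
    }
    cml <- cml_ma_bic(h, n_eff = n_eff, n_restart = cfg$cml_restarts,
                      seed = pair_seed)
  }
  list(h = h, fit = fit, diagnostics = diag, presso = presso, cml = cml)
}

# Significance gate for one screened pair: primary IVW p plus the
# MR-PRESSO causal-estimate p (outlier-corrected when outliers were
# found); for pairs too small for PRESSO the gate is IVW-only.
#' @noRd
pair_flags <- function(res, alpha) {
  est <- res$fit$estimates
  ivw_p <- est$pval[est$method %in% c("ivw", "wald_ratio")][1]
  presso_p <- NA_real_
  if (!is.null(res$presso)) {
    pe <- res$presso$estimate_after %||% res$presso$estimate_before
    presso_p <- pe$pval
  }
  suggestive <- ivw_p < alpha && (is.na(presso_p) || presso_p < alpha)
  list(ivw_p = ivw_p, presso_p = presso_p, suggestive = suggestive)
}

#' @noRd
assemble_screen <- function(results, dropped, cfg, direction) {
  m <- length(results)
  if (m == 0) {
    mr_error("mr_empty_screen",
             paste("no pair could be analyzed;",
                   paste(dropped$reason, collapse = "; ")))
  }
  bonf <- cfg$alpha / m
  est <- do.call(rbind, lapply(results, function(r) {
    e <- r$fit$estimates
    if (!is.null(r$cml)) e <- rbind(e, as.data.frame(r$cml))
    e
  }))
  rownames(est) <- NULL
  flags <- do.call(rbind, lapply(results, function(r) {
    fl <- pair_flags(r, cfg$alpha)
    data.frame(exposure = r$h$exposure_name, outcome = r$h$outcome_name,
               nsnp = nsnp(r$h), ivw_p = fl$ivw_p, presso_p = fl$presso_p,
               suggestive = fl$suggestive,
               bonferroni = fl$ivw_p < bonf,
               stringsAsFactors = FALSE)
  }))
  rownames(flags) <- NULL
  structure(
    list(estimates = est, flags = flags,
         diagnostics = lapply(results, `[[`, "diagnostics"),
         presso = lapply(results, `[[`, "presso"),
         cml = lapply(results, `[[`, "cml"),
         harmonized = lapply(results, `[[`, "h"),
         dropped = dropped, m = m, bonferroni_threshold = bonf,
         direction = direction, config = cfg),
    class = "mr_screen"
  )
}

#' Forward MR screen over many exposures
#'
#' For each exposure: p-value selection, LD clumping, harmonization to
#' the outcome, instrument-strength filtering, the full estimator
#' battery, heterogeneity/pleiotropy diagnostics, MR-PRESSO and
#' cML-MA-BIC. Pairs passing the dual primary gate (IVW p < alpha and
#' MR-PRESSO estimate p < alpha) are flagged as suggestive; the
#' Bonferroni flag uses `alpha / m` with m the number of exposures
#' actually analyzed.
#'
#' @param exposures named list of exposure summary-statistic data.frames.
#' @param outcome outcome summary-statistic data.frame.
#' @param ld optional [ld_reference()] for clumping.
#' @param config a [screen_config()].
#' @param outcome_name label for the outcome trait.
#' @return object of class `mr_screen`: tidy `estimates`, `flags` (per
#'   pair: ivw_p, presso_p, suggestive, bonferroni), `diagnostics`,
#'   `presso`, `cml`, `harmonized` sets (full provenance), `dropped`
#'   exposures with reasons, `m`, `bonferroni_threshold`.
#' @export
run_forward_screen <- function(exposures, outcome, ld = NULL,
                               config = screen_config(),
                               outcome_name = "outcome") {
  stopifnot(is.list(exposures), length(exposures) >= 1)
  if (is.null(names(exposures))) {
    mr_error("mr_validation_error", "exposures must be a named list")
  }
  results <- list()
  dropped <- data.frame(exposure = character(), reason = character(),
                        stringsAsFactors = FALSE)
  for (nm in names(exposures)) {
    res <- tryCatch({
      sel <- select_by_pvalue(exposures[[nm]], config$iv_pvalue)
      if (nrow(sel) == 0) {
        mr_error("mr_insufficient_instruments",
                 sprintf("%s: no instrument at p < %g", nm, config$iv_pvalue))
      }
      cl <- clump(sel, ld, config$clump_r2, config$clump_window)
      screen_pair(cl, outcome, nm, outcome_name, config)
    }, mrscreen_error = function(e) e)
    if (inherits(res, "error")) {
      dropped <- rbind(dropped, data.frame(exposure = nm,
                                           reason = conditionMessage(res),
                                           stringsAsFactors = FALSE))
    } else {
      results[[nm]] <- res
    }
  }
  assemble_screen(results, dropped, config, direction = "forward")
}

#' Reverse MR screen
#'
#' Runs the identical machinery with the roles swapped: instruments are
#' selected from the outcome GWAS (e.g. the adverse-event phenotype) and
#' tested against each taxon as outcome, to probe reverse causation.
#'
#' @param outcome_stats summary statistics of the original outcome, now
#'   used as the exposure.
#' @param taxa named list of taxon summary-statistic data.frames, now
#'   used as outcomes.
#' @param ld optional [ld_reference()].
#' @param config a [screen_config()]; `iv_pvalue` is applied to the
#'   outcome-as-exposure GWAS.
#' @param exposure_name label for the outcome-as-exposure trait.
#' @return `mr_screen` object (one row per taxon).
#' @export
run_reverse_mr <- function(outcome_stats, taxa, ld = NULL,
                           config = screen_config(),
                           exposure_name = "outcome") {
  stopifnot(is.list(taxa), length(taxa) >= 1)
  sel <- select_by_pvalue(outcome_stats, config$iv_pvalue)
  if (nrow(sel) == 0) {
    mr_error("mr_empty_screen",
             sprintf("no reverse instrument at p < %g for %s",
                     config$iv_pvalue, exposure_name))
  }
  cl <- clump(sel, ld, config$clump_r2, config$clump_window)
  results <- list()
  dropped <- data.frame(exposure = character(), reason = character(),
                        stringsAsFactors = FALSE)
  for (nm in names(taxa)) {
    res <- tryCatch(
      screen_pair(cl, taxa[[nm]], exposure_name, nm, config),
      mrscreen_error = function(e) e
    )
    if (inherits(res, "error")) {
      dropped <- rbind(dropped, data.frame(exposure = nm,
                                           reason = conditionMessage(res),
                                           stringsAsFactors = FALSE))
    } else {
      results[[nm]] <- res
    }
  }
  assemble_screen(results, dropped, config, direction = "reverse")
}

#' @export
print.mr_screen <- function(x, ...) {
  cat(sprintf("MR %s screen: %d pair(s) analyzed, %d dropped\n",
              x$direction, x$m, nrow(x$dropped)))
  cat(sprintf("  suggestive (dual gate, alpha = %g): %d\n",
              x$config$alpha, sum(x$flags$suggestive)))
  cat(sprintf("  Bonferroni (p < %.3g = alpha/%d): %d\n",
              x$bonferroni_threshold, x$m, sum(x$flags$bonferroni)))
  invisible(x)
}

#' @export
as.data.frame.mr_screen <- function(x, ...) x$estimates

#' Write all screen outputs to a directory
#'
#' Emits the tidy estimates TSV, the flags table, the diagnostics and
#' MR-PRESSO tables, per-pair scatter-plot data, and a JSON run manifest
#' recording thresholds and seeds so every number is recomputable.
#'
#' @param x an `mr_screen`.
#' @param dir output directory (created if needed).
#' @export
write_screen <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_estimates(x$estimates, file.path(dir, "estimates.tsv"))
  utils::write.table(x$flags, file.path(dir, "flags.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  dg <- Filter(Negate(is.null), x$diagnostics)
  if (length(dg)) write_diagnostics(dg, file.path(dir, "diagnostics.tsv"))
  pr <- Filter(Negate(is.null), x$presso)
  if (length(pr)) write_presso(pr, file.path(dir, "presso.tsv"))
  scatter <- do.call(rbind, lapply(x$harmonized, function(h) {
    cbind(data.frame(exposure = h$exposure_name, outcome = h$outcome_name,
                     stringsAsFactors = FALSE),
          as.data.frame(h))
  }))
  utils::write.table(scatter, file.path(dir, "scatter.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- x$config
  cfg$proxy_map <- NULL; cfg$trait_table <- NULL
  manifest <- list(direction = x$direction, m = x$m,
                   bonferroni_threshold = x$bonferroni_threshold,
                   config = unclass(cfg),
                   package_version = as.character(utils::packageVersion("mrscreen")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
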
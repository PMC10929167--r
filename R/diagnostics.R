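# Heterogeneity, pleiotropy and sensitivity diagnostics.

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum_j w_j (theta_j - theta_IVW)^2` over the per-instrument Wald
#' ratios `theta_j`, with weights `w_j = beta_exp_j^2 / se_out_j^2` and
#' the fixed-effect IVW estimate as centre (the standard definition,
#' regardless of the variance mode used for reporting). The p-value is
#' the upper chi-square tail with J - 1 df.
#'
#' @param h a [harmonized_set()] with at least 2 instruments.
#' @return list with `Q`, `df`, `pval`.
#' @export
cochran_q <- function(h) {
  J <- nsnp(h)
  if (J < 2) mr_error("mr_insufficient_instruments", "Cochran's Q needs >= 2 instruments")
  core <- ivw_core(h$beta_exp, h$beta_out, h$se_out)
  list(Q = core$Q, df = J - 1L,
       pval = stats::pchisq(core$Q, df = J - 1, lower.tail = FALSE))
}

#' Leave-one-out IVW analysis
#'
#' Re-estimates the IVW causal effect J times, dropping one instrument
#' each time, to expose reliance on any single variant.
#'
#' @param h a [harmonized_set()] with at least 2 instruments.
#' @param config an [mr_config()].
#' @return data.frame with one row per dropped instrument: `snp`
#'   (the instrument left out), `nsnp`, `beta`, `se`, `ci_low`,
#'   `ci_high`, `pval`.
#' @export
leave_one_out <- function(h, config = mr_config()) {
  J <- nsnp(h)
  if (J < 2) mr_error("mr_insufficient_instruments", "leave-one-out needs >= 2 instruments")
  rows <- lapply(seq_len(J), function(j) {
    hj <- subset_harmonized(h, -j, "removed_loo")
    est <- if (J - 1 == 1) {
      wald_ratio(hj$beta_exp, hj$se_exp, hj$beta_out, hj$se_out)
    } else {
      mr_ivw(hj, config)
    }
    cbind(data.frame(snp = h$snp[j], stringsAsFactors = FALSE),
          est[, c("nsnp", "beta", "se", "ci_low", "ci_high", "pval")])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Annotate instruments against a SNP-trait table
#'
#' Left-joins the instruments with a user-supplied SNP-to-trait
#' annotation table (e.g. an offline PhenoScanner export) and flags
#' instruments matching any secondary trait for analyst review. This is
#' an annotation step only: nothing is excluded automatically, but
#' the leave-one-out table shows the effect of removing any flagged
#' instrument.
#'
#' @param instruments character vector of snp ids, or a data.frame /
#'   [harmonized_set()] with a `snp` field.
#' @param trait_table data.frame with columns `snp` and `trait`.
#' @return data.frame of hits: `snp`, `trait`.
#' @export
annotate_confounders <- function(instruments, trait_table) {
  snps <- if (is.character(instruments)) instruments else instruments$snp
  if (is.null(trait_table) || !nrow(trait_table)) {
    return(data.frame(snp = character(), trait = character(),
                      stringsAsFactors = FALSE))
  }
  hits <- trait_table[trait_table$snp %in% snps, c("snp", "trait"), drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Full diagnostics report for one exposure-outcome pair
#'
#' Bundles Cochran's Q, the MR-Egger intercept test, the leave-one-out
#' table and (optionally) confounder-annotation hits.
#'
#' @param h a [harmonized_set()].
#' @param config an [mr_config()].
#' @param trait_table optional SNP-trait annotation table, see
#'   [annotate_confounders()].
#' @return object of class `mr_diagnostics`.
#' @export
mr_diagnostics <- function(h, config = mr_config(), trait_table = NULL) {
  q <- cochran_q(h)
  egger_int <- if (nsnp(h) >= 3) mr_egger(h, config)$intercept else NULL
  structure(
    list(exposure = h$exposure_name, outcome = h$outcome_name,
         Q = q$Q, df = q$df, p_Q = q$pval,
         egger_intercept = egger_int,
         loo = leave_one_out(h, config),
         annotation_hits = annotate_confounders(h, trait_table %||% data.frame())),
    class = "mr_diagnostics"
  )
}

#' @export
print.mr_diagnostics <- function(x, ...) {
  cat(sprintf("Diagnostics: %s -> %s\n", x$exposure, x$outcome))
  cat(sprintf("  Cochran's Q = %.4g on %d df (p = %.3g)\n", x$Q, x$df, x$p_Q))
  if (!is.null(x$egger_intercept)) {
    ic <- x$egger_intercept
    cat(sprintf("  Egger intercept = %.4g (se %.4g, p = %.3g)\n",
                ic$estimate, ic$se, ic$pval))
  }
  dmax <- x$loo$snp[which.max(abs(x$loo$beta - mean(x$loo$beta)))]
  cat(sprintf("  leave-one-out over %d instruments (largest shift: %s)\n",
              nrow(x$loo), dmax))
  if (nrow(x$annotation_hits)) {
    cat(sprintf("  %d instrument(s) annotated to secondary traits - review\n",
                length(unique(x$annotation_hits$snp))))
  }
  invisible(x)
}

#' Serialize diagnostics for one or more pairs
#'
#' Heterogeneity/pleiotropy table shape: exposure, outcome, Q, df, p_Q,
#' egger_intercept, intercept_se, intercept_p.
#'
#' @param x an `mr_diagnostics` or list of them.
#' @param path output TSV path.
#' @export
write_diagnostics <- function(x, path) {
  if (inherits(x, "mr_diagnostics")) x <- list(x)
  rows <- lapply(x, function(d) {
    ic <- d$egger_intercept
    data.frame(exposure = d$exposure, outcome = d$outcome,
               Q = d$Q, df = d$df, p_Q = d$p_Q,
               egger_intercept = if (is.null(ic)) NA_real_ else ic$estimate,
               intercept_se = if (is.null(ic)) NA_real_ else ic$se,
               intercept_p = if (is.null(ic)) NA_real_ else ic$pval,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
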
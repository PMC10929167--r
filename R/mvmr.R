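# Multivariable MR: joint estimation of several exposures' direct
# effects on one outcome by weighted multiple regression of the
# instrument-outcome effects on the instrument-exposure effect matrix.

#' Build a multivariable MR instrument set
#'
#' Takes the union of each exposure's p-value-selected instruments,
#' clumps them jointly (each variant scored by its best p-value across
#' exposures), and aligns the effect of every exposure and of the
#' outcome to a single reference allele coding per instrument.
#' Instruments missing an effect estimate for any exposure (or with
#' incompatible alleles) are dropped and logged; palindromic instruments
#' are removed when `drop_palindromic`.
#'
#' @param exposures named list (length >= 2) of summary-statistic
#'   data.frames, one per exposure, each covering at least its own
#'   instruments.
#' @param outcome outcome summary-statistic data.frame.
#' @param ld optional [ld_reference()] for the joint clumping.
#' @param iv_pvalue per-exposure instrument selection threshold.
#' @param r2_threshold,window joint clumping parameters, as in [clump()].
#' @param drop_palindromic remove A/T and C/G instruments.
#' @param instrument_source `"union"` (default) uses every exposure's
#'   instruments; `"first"` restricts to the first exposure's.
#' @return object of class `mv_harmonized_set`: `outcome_name`,
#'   `exposure_names`, `snp`, `beta_exp` / `se_exp` (J x k matrices),
#'   `beta_out`, `se_out`, `dropped` (data.frame snp, reason).
#' @export
build_mv_set <- function(exposures, outcome, ld = NULL,
                         iv_pvalue = 1e-5, r2_threshold = 0.001, window = 1e7,
                         drop_palindromic = TRUE,
                         instrument_source = c("union", "first")) {
  instrument_source <- match.arg(instrument_source)
  if (length(exposures) < 2) {
    mr_error("mr_validation_error", "multivariable MR needs >= 2 exposures")
  }
  if (is.null(names(exposures)) || any(names(exposures) == "")) {
    mr_error("mr_validation_error", "exposures must be a named list")
  }
  k <- length(exposures)
  nms <- names(exposures)

  src <- if (instrument_source == "first") exposures[1] else exposures
  selected <- lapply(src, select_by_pvalue, threshold = iv_pvalue)
  pool <- do.call(rbind, selected)
  if (is.null(pool) || !nrow(pool)) {
    mr_error("mr_insufficient_instruments", "no instrument passes the p-value screen")
  }
  # best p-value per variant across exposures, keeping that record as
  # the reference allele coding
  pool <- pool[order(pool$pval), , drop = FALSE]
  pool <- pool[!duplicated(pool$snp), , drop = FALSE]
  clumped <- clump(pool, ld, r2_threshold, window)

  dropped <- data.frame(snp = character(), reason = character(),
                        stringsAsFactors = FALSE)
  keep_rows <- list()
  for (i in seq_len(nrow(clumped))) {
    ref <- clumped[i, ]
    if (drop_palindromic && is_palindromic(ref$effect_allele, ref$other_allele)) {
      dropped <- rbind(dropped, data.frame(snp = ref$snp, reason = "palindromic"))
      next
    }
    be <- se <- numeric(k)
    ok <- TRUE
    for (e in seq_len(k)) {
      row <- exposures[[e]][match(ref$snp, exposures[[e]]$snp), ]
      if (is.na(row$snp[1])) {
        dropped <- rbind(dropped, data.frame(
          snp = ref$snp, reason = paste0("missing_in_exposure:", nms[e])))
        ok <- FALSE; break
      }
      al <- align_alleles(ref$effect_allele, ref$other_allele,
                          row$effect_allele, row$other_allele, row$beta)
      if (al$status == "mismatch") {
        dropped <- rbind(dropped, data.frame(
          snp = ref$snp, reason = paste0("allele_mismatch:", nms[e])))
        ok <- FALSE; break
      }
      be[e] <- al$beta; se[e] <- row$se
    }
    if (!ok) next
    orow <- outcome[match(ref$snp, outcome$snp), ]
    if (is.na(orow$snp[1])) {
      dropped <- rbind(dropped, data.frame(snp = ref$snp, reason = "missing_in_outcome"))
      next
    }
    al <- align_alleles(ref$effect_allele, ref$other_allele,
                        orow$effect_allele, orow$other_allele, orow$beta)
    if (al$status == "mismatch") {
      dropped <- rbind(dropped, data.frame(snp = ref$snp, reason = "allele_mismatch:outcome"))
      next
    }
    keep_rows[[length(keep_rows) + 1]] <-
      list(snp = ref$snp, be = be, se = se, bo = al$beta, so = orow$se)
  }
  J <- length(keep_rows)
  if (J < k + 2) {
    mr_error("mr_insufficient_instruments",
             sprintf("only %d instrument(s) survive joint harmonization (need > %d)",
                     J, k + 1))
  }
  structure(
    list(outcome_name = attr(outcome, "trait") %||% "outcome",
         exposure_names = nms,
         snp = vapply(keep_rows, `[[`, character(1), "snp"),
         beta_exp = matrix(unlist(lapply(keep_rows, `[[`, "be")), nrow = J,
                           byrow = TRUE, dimnames = list(NULL, nms)),
         se_exp = matrix(unlist(lapply(keep_rows, `[[`, "se")), nrow = J,
                         byrow = TRUE, dimnames = list(NULL, nms)),
         beta_out = vapply(keep_rows, `[[`, numeric(1), "bo"),
         se_out = vapply(keep_rows, `[[`, numeric(1), "so"),
         dropped = dropped),
    class = "mv_harmonized_set"
  )
}

#' @export
print.mv_harmonized_set <- function(x, ...) {
  cat(sprintf("Multivariable MR set: {%s} -> %s, %d instruments\n",
              paste(x$exposure_names, collapse = ", "), x$outcome_name,
              length(x$snp)))
  if (nrow(x$dropped)) cat(sprintf("  %d variant(s) dropped during joint harmonization\n",
                                   nrow(x$dropped)))
  invisible(x)
}

#' Multivariable IVW regression
#'
#' Weighted least squares of the instrument-outcome effects on the
#' instrument-by-exposure effect matrix without intercept, weights
#' `1/se_out^2` (fixed-effect). Each coefficient is the direct effect of
#' that exposure on the outcome conditional on the others. Residual
#' heterogeneity is summarized by the weighted residual sum of squares
#' (chi-square with J - k df), and a per-exposure conditional
#' instrument-strength statistic (mean weighted squared residual of that
#' exposure's effects regressed on the others') is reported as a
#' diagnostic — never as an automatic exclusion.
#'
#' @param mv an [build_mv_set()] result.
#' @return object of class `mvmr_fit`: `estimates` (tidy data.frame, one
#'   row per exposure), `Q`, `Q_df`, `Q_pval`, `conditional_F`.
#' @export
mvmr_ivw <- function(mv) {
  X <- mv$beta_exp
  y <- mv$beta_out
  J <- nrow(X); k <- ncol(X)
  if (J <= k + 1) {
    mr_error("mr_insufficient_instruments",
             sprintf("need more instruments (%d) than exposures + 1 (%d)", J, k + 1))
  }
  w <- 1 / mv$se_out^2
  Xw <- X * sqrt(w)
  qr_x <- qr(Xw)
  if (qr_x$rank < k) {
    bad <- mv$exposure_names[qr_x$pivot[(qr_x$rank + 1):k]]
    mr_error("mr_collinearity_error",
             paste("collinear exposure effect(s):", paste(bad, collapse = ", ")))
  }
  XtWX <- crossprod(X, w * X)
  beta <- drop(solve(XtWX, crossprod(X, w * y)))
  se <- sqrt(diag(solve(XtWX)))
  resid <- y - drop(X %*% beta)
  Q <- sum(w * resid^2)
  est <- do.call(rbind, lapply(seq_len(k), function(e) {
    cbind(data.frame(exposure = mv$exposure_names[e], outcome = mv$outcome_name,
                     stringsAsFactors = FALSE),
          mr_estimate("mvmr_ivw", beta[e], se[e], J))
  }))
  rownames(est) <- NULL
  cond_f <- vapply(seq_len(k), function(e) {
    if (k == 1) return(mean(X[, 1]^2 / mv$se_exp[, 1]^2))
    wx <- 1 / mv$se_exp[, e]^2
    Xo <- X[, -e, drop = FALSE]
    bfit <- solve(crossprod(Xo, wx * Xo), crossprod(Xo, wx * X[, e]))
    r <- X[, e] - drop(Xo %*% bfit)
    mean(r^2 / mv$se_exp[, e]^2)
  }, numeric(1))
  structure(
    list(estimates = est, Q = Q, Q_df = J - k,
         Q_pval = stats::pchisq(Q, J - k, lower.tail = FALSE),
         conditional_F = stats::setNames(cond_f, mv$exposure_names),
         data = mv),
    class = "mvmr_fit"
  )
}

#' @export
print.mvmr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Multivariable MR (IVW): %d instruments, %d exposures\n",
              nrow(x$data$beta_exp), ncol(x$data$beta_exp)))
  print(format(x$estimates[, c("exposure", "beta", "se", "ci_low", "ci_high", "pval")],
               digits = digits), row.names = FALSE)
  cat(sprintf("residual Q = %.4g on %d df (p = %.3g); conditional F: %s\n",
              x$Q, x$Q_df, x$Q_pval,
              paste(sprintf("%s=%.1f", names(x$conditional_F), x$conditional_F),
                    collapse = ", ")))
  invisible(x)
}

#' @export
coef.mvmr_fit <- function(object, ...) {
  stats::setNames(object$estimates$beta, object$estimates$exposure)
}

#' @export
as.data.frame.mvmr_fit <- function(x, ...) x$estimates
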
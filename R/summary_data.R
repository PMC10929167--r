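# Data model and harmonization of GWAS summary statistics.
#
# A summary-statistic table is an ordinary data.frame with canonical
# columns: snp, chrom, pos, effect_allele, other_allele, beta, se, pval,
# eaf, n. Only snp, the two alleles, beta, se and pval are required;
# eaf and n may be missing (consortium-style inputs often omit them).

#' Default column mapping for summary-statistic files
#'
#' Maps the canonical field names used throughout the package to the
#' column headers found in a delimited file. Override individual entries
#' to read files with other headers (e.g. `dialect(beta = "ES")`).
#'
#' @param ... named overrides, `canonical = "file column"`.
#' @return named character vector, canonical name -> file header.
#' @export
#' @examples
#' default_dialect()
#' default_dialect(beta = "ES", se = "SE")
default_dialect <- function(...) {
  d <- c(
    snp = "SNP", chrom = "chr", pos = "pos",
    effect_allele = "effect_allele", other_allele = "other_allele",
    beta = "beta", se = "se", pval = "pval", eaf = "eaf", n = "samplesize"
  )
  ov <- c(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(d))
    if (length(bad)) mr_error("mr_config_error", paste("unknown dialect field(s):", paste(bad, collapse = ", ")))
    d[names(ov)] <- ov
  }
  d
}

REQUIRED_FIELDS <- c("snp", "effect_allele", "other_allele", "beta", "se", "pval")
CANONICAL_FIELDS <- c("snp", "chrom", "pos", "effect_allele", "other_allele",
                      "beta", "se", "pval", "eaf", "n")

# Per-row invariant checks; returns character reason or NA if valid.
#' @noRd
row_problem <- function(d) {
  reason <- rep(NA_character_, nrow(d))
  bad_allele <- !grepl("^[ACGT]$", d$effect_allele) | !grepl("^[ACGT]$", d$other_allele)
  same_allele <- !bad_allele & d$effect_allele == d$other_allele
  reason[is.na(d$beta)] <- "missing beta"
  reason[is.na(d$se) | d$se <= 0] <- "se not positive"
  reason[is.na(d$pval) | d$pval <= 0 | d$pval > 1] <- "pval outside (0,1]"
  reason[!is.na(d$eaf) & (d$eaf < 0 | d$eaf > 1)] <- "eaf outside [0,1]"
  reason[bad_allele] <- "allele not a single A/C/G/T base"
  reason[same_allele] <- "identical alleles"
  reason[is.na(d$snp) | d$snp == ""] <- "missing snp id"
  reason
}

#' Read a GWAS summary-statistic table
#'
#' Reads a tab- or comma-delimited per-variant association table, applies
#' the column mapping in `dialect`, upper-cases alleles, and validates
#' every row (positive SE, p in (0,1], single-base distinct alleles,
#' EAF in \[0,1\] when present). Rows violating an invariant are dropped
#' and reported, with their file line numbers, in the `rejects`
#' attribute of the returned data.frame.
#'
#' @param path file path.
#' @param dialect column mapping, see [default_dialect()].
#' @param sep field separator; `NULL` picks `,` for `.csv`, tab otherwise.
#' @return data.frame with canonical columns and attribute `"rejects"`
#'   (data.frame of `line`, `snp`, `reason`).
#' @export
read_summary_stats <- function(path, dialect = default_dialect(), sep = NULL) {
  if (!file.exists(path)) mr_error("mr_io_error", paste("file not found:", path))
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                      check.names = FALSE, comment.char = "", quote = "\""),
    error = function(e) mr_error("mr_io_error", paste("unreadable file:", conditionMessage(e)))
  )
  missing_req <- REQUIRED_FIELDS[!dialect[REQUIRED_FIELDS] %in% names(raw)]
  if (length(missing_req)) {
    mr_error("mr_config_error",
             paste0("required column(s) not found: ",
                    paste(dialect[missing_req], collapse = ", ")))
  }
  d <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                  snp = as.character(raw[[dialect[["snp"]]]]))
  for (f in setdiff(CANONICAL_FIELDS, "snp")) {
    col <- dialect[[f]]
    if (!is.null(col) && col %in% names(raw)) {
      d[[f]] <- raw[[col]]
    } else {
      d[[f]] <- if (f %in% c("chrom", "effect_allele", "other_allele")) NA_character_ else NA_real_
    }
  }
  d$effect_allele <- toupper(as.character(d$effect_allele))
  d$other_allele <- toupper(as.character(d$other_allele))
  d$chrom <- as.character(d$chrom)
  for (f in c("pos", "beta", "se", "pval", "eaf", "n")) d[[f]] <- as.numeric(d[[f]])
  reason <- row_problem(d)
  bad <- !is.na(reason)
  rejects <- data.frame(line = which(bad) + 1L, snp = d$snp[bad],
                        reason = reason[bad], stringsAsFactors = FALSE)
  out <- d[!bad, CANONICAL_FIELDS, drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejects") <- rejects
  out
}

#' Write a summary-statistic table
#'
#' Inverse of [read_summary_stats()]: serializes canonical columns under
#' the headers given by `dialect`, so a read/write cycle round-trips.
#'
#' @inheritParams read_summary_stats
#' @param x data.frame with canonical columns.
#' @export
write_summary_stats <- function(x, path, dialect = default_dialect(), sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  keep <- CANONICAL_FIELDS[CANONICAL_FIELDS %in% names(x)]
  out <- x[, keep, drop = FALSE]
  names(out) <- unname(dialect[keep])
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the rejects report of a read
#'
#' @param x data.frame returned by [read_summary_stats()].
#' @param path output TSV path.
#' @export
write_rejects <- function(x, path) {
  utils::write.table(attr(x, "rejects") %||% data.frame(), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Is an allele pair palindromic?
#'
#' A/T and C/G variants read the same on both strands, so their coding
#' cannot be resolved from alleles alone; the default pipeline removes
#' them before analysis.
#'
#' @param effect_allele,other_allele single-base A/C/G/T vectors.
#' @return logical vector.
#' @export
#' @examples
#' is_palindromic("A", "T")
#' is_palindromic(c("A", "C"), c("G", "G"))
is_palindromic <- function(effect_allele, other_allele) {
  ea <- toupper(effect_allele)
  oa <- toupper(other_allele)
  ok <- grepl("^[ACGT]$", ea) & grepl("^[ACGT]$", oa)
  if (!all(ok)) mr_error("mr_validation_error", "alleles must be single A/C/G/T bases")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  unname(comp[ea] == oa)
}

#' Construct a harmonized exposure/outcome instrument set
#'
#' Low-level constructor; most users get one from [harmonize()]. All
#' four effect vectors must be aligned, equal length and keyed by `snp`.
#'
#' @param snp instrument identifiers.
#' @param beta_exp,se_exp instrument-exposure effects and SEs.
#' @param beta_out,se_out instrument-outcome effects and SEs.
#' @param exposure_name,outcome_name trait labels.
#' @param audit optional data.frame (`snp`, `disposition`) recording the
#'   fate of every input instrument.
#' @param eaf_exp,eaf_out optional effect-allele frequencies.
#' @param n_exp,n_out optional sample sizes.
#' @return object of class `harmonized_set`.
#' @export
harmonized_set <- function(snp, beta_exp, se_exp, beta_out, se_out,
                           exposure_name = "exposure", outcome_name = "outcome",
                           audit = NULL, eaf_exp = NULL, eaf_out = NULL,
                           n_exp = NULL, n_out = NULL) {
  J <- length(snp)
  lens <- c(length(beta_exp), length(se_exp), length(beta_out), length(se_out))
  if (J < 1 || any(lens != J)) {
    mr_error("mr_validation_error", "harmonized vectors must share one length >= 1")
  }
  if (any(se_exp <= 0) || any(se_out <= 0)) {
    mr_error("mr_validation_error", "standard errors must be strictly positive")
  }
  if (anyDuplicated(snp)) mr_error("mr_validation_error", "duplicate instrument ids")
  if (is.null(audit)) {
    audit <- data.frame(snp = as.character(snp), disposition = "kept",
                        stringsAsFactors = FALSE)
  }
  structure(
    list(exposure_name = exposure_name, outcome_name = outcome_name,
         snp = as.character(snp),
         beta_exp = as.numeric(beta_exp), se_exp = as.numeric(se_exp),
         beta_out = as.numeric(beta_out), se_out = as.numeric(se_out),
         eaf_exp = eaf_exp, eaf_out = eaf_out,
         n_exp = n_exp, n_out = n_out, audit = audit),
    class = "harmonized_set"
  )
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized set: %s -> %s\n", x$exposure_name, x$outcome_name))
  cat(sprintf("  %d instrument(s)\n", length(x$snp)))
  tab <- table(x$audit$disposition)
  cat("  audit:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.harmonized_set <- function(x, ...) {
  data.frame(snp = x$snp, beta_exp = x$beta_exp, se_exp = x$se_exp,
             beta_out = x$beta_out, se_out = x$se_out,
             stringsAsFactors = FALSE)
}

#' @noRd
nsnp <- function(h) length(h$snp)

#' Subset a harmonized set, preserving the audit trail
#'
#' Keeps the instruments selected by `keep` (logical, positive or
#' negative index vector); dropped instruments are recorded in the audit
#' with `reason`. Useful for sensitivity re-runs excluding flagged
#' instruments.
#'
#' @param h a [harmonized_set()].
#' @param keep index vector over instruments.
#' @param reason audit disposition recorded for dropped instruments.
#' @return [harmonized_set()].
#' @export
subset_harmonized <- function(h, keep, reason = "removed_filtered") {
  keep_ids <- h$snp[keep]
  audit <- h$audit
  dropped <- setdiff(h$snp, keep_ids)
  audit$disposition[audit$snp %in% dropped & audit$disposition %in% c("kept", "sign_flipped", "proxied")] <- reason
  if (length(keep_ids) < 1) mr_error("mr_empty_set", "no instruments left after filtering")
  harmonized_set(
    snp = keep_ids,
    beta_exp = h$beta_exp[keep], se_exp = h$se_exp[keep],
    beta_out = h$beta_out[keep], se_out = h$se_out[keep],
    exposure_name = h$exposure_name, outcome_name = h$outcome_name,
    audit = audit,
    eaf_exp = h$eaf_exp[keep], eaf_out = h$eaf_out[keep],
    n_exp = h$n_exp[keep], n_out = h$n_out[keep]
  )
}

# Align one record (alleles ea/oa, effect b, frequency f) to a reference
# coding (rea/roa). Returns list(status, beta, eaf).
#' @noRd
align_alleles <- function(rea, roa, ea, oa, b, f = NA_real_) {
  if (identical(ea, rea) && identical(oa, roa)) {
    list(status = "same", beta = b, eaf = f)
  } else if (identical(ea, roa) && identical(oa, rea)) {
    list(status = "swapped", beta = -b, eaf = if (is.na(f)) NA_real_ else 1 - f)
  } else {
    list(status = "mismatch", beta = NA_real_, eaf = NA_real_)
  }
}

#' Harmonize exposure instruments against an outcome GWAS
#'
#' Matches each selected instrument to the outcome table by `snp`,
#' aligns effect alleles (flipping the outcome beta and EAF when the
#' outcome lists the alleles in swapped order), removes palindromic
#' (A/T, C/G) instruments by default, substitutes user-supplied LD
#' proxies for instruments absent from the outcome, and keeps a complete
#' per-instrument audit trail.
#'
#' @param exposure data.frame of selected instruments (canonical columns).
#' @param outcome data.frame of outcome associations keyed by `snp`.
#' @param proxy_map optional data.frame (`target_id`, `proxy_id`, `r2`):
#'   outcome-side stand-ins for instruments missing from the outcome.
#' @param drop_palindromic remove A/T and C/G instruments (default TRUE).
#' @param proxy_r2 minimum LD r-squared for a proxy to be used.
#' @param eaf_rescue attempt to resolve palindromic instruments from
#'   allele frequencies instead of removing them (both EAFs must fall
#'   outside (0.42, 0.58)); off by default.
#' @param exposure_name,outcome_name trait labels carried into results.
#' @return [harmonized_set()] object.
#' @export
harmonize <- function(exposure, outcome, proxy_map = NULL,
                      drop_palindromic = TRUE, proxy_r2 = 0.8,
                      eaf_rescue = FALSE,
                      exposure_name = "exposure", outcome_name = "outcome") {
  stopifnot(is.data.frame(exposure), is.data.frame(outcome))
  out_idx <- match(exposure$snp, outcome$snp)
  J <- nrow(exposure)
  disposition <- character(J)
  bo <- so <- eo <- no <- rep(NA_real_, J)

  for (j in seq_len(J)) {
    ex <- exposure[j, ]
    oi <- out_idx[j]
    pal <- is_palindromic(ex$effect_allele, ex$other_allele)

    if (is.na(oi) && !is.null(proxy_map)) {
      cand <- proxy_map[proxy_map$target_id == ex$snp & proxy_map$r2 > proxy_r2, , drop = FALSE]
      cand <- cand[cand$proxy_id %in% outcome$snp, , drop = FALSE]
      if (nrow(cand)) {
        cand <- cand[order(-cand$r2), , drop = FALSE]
        oi <- match(cand$proxy_id[1], outcome$snp)
        or <- outcome[oi, ]
        disposition[j] <- "proxied"
        bo[j] <- or$beta; so[j] <- or$se
        eo[j] <- or$eaf %||% NA_real_; no[j] <- or$n %||% NA_real_
        next
      }
    }
    if (is.na(oi)) {
      disposition[j] <- "removed_missing_in_outcome"
      next
    }
    or <- outcome[oi, ]

    if (pal) {
      rescued <- FALSE
      if (!drop_palindromic) {
        rescued <- TRUE
        al <- align_alleles(ex$effect_allele, ex$other_allele,
                            or$effect_allele, or$other_allele, or$beta, or$eaf)
      } else if (eaf_rescue &&
                 !is.na(ex$eaf) && !is.na(or$eaf) &&
                 abs(ex$eaf - 0.5) > 0.08 && abs(or$eaf - 0.5) > 0.08) {
        # frequencies are informative: align by matching the minor side
        rescued <- TRUE
        if ((ex$eaf - 0.5) * (or$eaf - 0.5) > 0) {
          al <- list(status = "same", beta = or$beta, eaf = or$eaf)
        } else {
          al <- list(status = "swapped", beta = -or$beta, eaf = 1 - or$eaf)
        }
      }
      if (!rescued) {
        disposition[j] <- "removed_palindromic"
        next
      }
    } else {
      al <- align_alleles(ex$effect_allele, ex$other_allele,
                          or$effect_allele, or$other_allele, or$beta, or$eaf)
    }
    if (al$status == "mismatch") {
      disposition[j] <- "removed_mismatch"
      next
    }
    disposition[j] <- if (al$status == "swapped") "sign_flipped" else "kept"
    bo[j] <- al$beta; so[j] <- or$se
    eo[j] <- al$eaf; no[j] <- or$n %||% NA_real_
  }

  audit <- data.frame(snp = exposure$snp, disposition = disposition,
                      stringsAsFactors = FALSE)
  keep <- disposition %in% c("kept", "sign_flipped", "proxied")
  if (!any(keep)) {
    mr_error("mr_empty_set",
             sprintf("no instruments survived harmonization for %s -> %s",
                     exposure_name, outcome_name))
  }
  harmonized_set(
    snp = exposure$snp[keep],
    beta_exp = exposure$beta[keep], se_exp = exposure$se[keep],
    beta_out = bo[keep], se_out = so[keep],
    exposure_name = exposure_name, outcome_name = outcome_name,
    audit = audit,
    eaf_exp = exposure$eaf[keep], eaf_out = eo[keep],
    n_exp = exposure$n[keep], n_out = no[keep]
  )
}

#' Write the harmonization audit trail
#'
#' @param h a [harmonized_set()].
#' @param path output path; `.json` writes JSON, anything else TSV.
#' @export
write_audit <- function(h, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(h$audit, path, auto_unbox = TRUE)
  } else {
    utils::write.table(h$audit, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
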
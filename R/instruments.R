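# Instrument selection: p-value screen, greedy LD clumping, F statistics.

#' Pairwise LD reference
#'
#' Sparse symmetric r-squared lookup over variants. Pairs absent from
#' the table are treated as independent (r2 = 0); the diagonal is 1.
#' Stands in for a genotype reference panel: r2 values are accepted as
#' precomputed input, never computed from genotypes here.
#'
#' @param pairs data.frame with columns `snp_a`, `snp_b`, `r2`.
#' @return object of class `ld_reference`.
#' @export
ld_reference <- function(pairs = NULL) {
  env <- new.env(parent = emptyenv(), hash = TRUE)
  if (!is.null(pairs) && nrow(pairs)) {
    if (any(pairs$r2 < 0 | pairs$r2 > 1)) {
      mr_error("mr_validation_error", "r2 must lie in [0, 1]")
    }
    a <- as.character(pairs$snp_a); b <- as.character(pairs$snp_b)
    key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
    for (i in seq_along(key)) assign(key[i], pairs$r2[i], envir = env)
  }
  structure(list(env = env), class = "ld_reference")
}

#' Look up pairwise r-squared
#'
#' @param ld an [ld_reference()] (or NULL, meaning all-independent).
#' @param a,b variant id vectors (recycled to common length).
#' @return numeric vector of r2 values (0 where the pair is absent).
#' @export
ld_r2 <- function(ld, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n); b <- rep_len(as.character(b), n)
  out <- ifelse(a == b, 1, 0)
  if (is.null(ld)) return(out)
  key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  for (i in seq_len(n)) {
    if (a[i] != b[i]) {
      v <- get0(key[i], envir = ld$env, ifnotfound = NA_real_)
      if (!is.na(v)) out[i] <- v
    }
  }
  out
}

#' Load an LD reference from disk
#'
#' `format = "long"` expects a TSV with columns `snp_a`, `snp_b`, `r2`.
#' `format = "matrix"` expects a dense numeric matrix file plus a
#' one-column variant index sidecar giving row/column order.
#'
#' @param path main file.
#' @param format `"long"` or `"matrix"`.
#' @param index_path variant index sidecar (matrix format only).
#' @return [ld_reference()].
#' @export
read_ld_reference <- function(path, format = c("long", "matrix"), index_path = NULL) {
  format <- match.arg(format)
  if (format == "long") {
    d <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    return(ld_reference(d))
  }
  if (is.null(index_path)) mr_error("mr_config_error", "matrix format needs index_path")
  ids <- utils::read.table(index_path, header = FALSE, stringsAsFactors = FALSE)[[1]]
  m <- as.matrix(utils::read.table(path, header = FALSE, sep = "\t"))
  if (nrow(m) != length(ids) || ncol(m) != length(ids)) {
    mr_error("mr_validation_error", "LD matrix dimensions do not match index")
  }
  ij <- which(upper.tri(m) & m != 0, arr.ind = TRUE)
  ld_reference(data.frame(snp_a = ids[ij[, 1]], snp_b = ids[ij[, 2]],
                          r2 = m[ij], stringsAsFactors = FALSE))
}

#' Genome-wide significance screen for instruments
#'
#' Keeps records with `pval` strictly below `threshold`, preserving the
#' input order. The conventional microbiome-GWAS instrument threshold
#' 1e-5 is the default.
#'
#' @param records summary-statistic data.frame.
#' @param threshold p-value cutoff in (0, 1).
#' @return filtered data.frame.
#' @export
select_by_pvalue <- function(records, threshold = 1e-5) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    mr_error("mr_validation_error", "threshold must lie in (0, 1)")
  }
  out <- records[!is.na(records$pval) & records$pval < threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy LD clumping of summary statistics
#'
#' PLINK-style best-p-first pruning: repeatedly keep the record with the
#' smallest p-value (ties broken lexicographically by `snp`) and discard
#' every remaining record on the same chromosome within `window` base
#' pairs whose r2 with it is at or above `r2_threshold`. Pairs absent
#' from `ld` count as independent.
#'
#' @param records data.frame with `chrom` and `pos` filled in.
#' @param ld [ld_reference()] or NULL.
#' @param r2_threshold LD pruning threshold (default 0.001).
#' @param window two-sided window in base pairs (default 10 Mb).
#' @return the kept records, in the order they were kept.
#' @export
clump <- function(records, ld = NULL, r2_threshold = 0.001, window = 1e7) {
  if (nrow(records) == 0) return(records)
  if (any(is.na(records$pos)) || any(is.na(records$chrom))) {
    mr_error("mr_validation_error", "clumping needs chrom and pos for every record")
  }
  ord <- order(records$pval, records$snp)
  d <- records[ord, , drop = FALSE]
  keep <- integer(0)
  alive <- rep(TRUE, nrow(d))
  for (i in seq_len(nrow(d))) {
    if (!alive[i]) next
    keep <- c(keep, i)
    later <- which(alive & seq_len(nrow(d)) > i)
    if (!length(later)) next
    near <- later[d$chrom[later] == d$chrom[i] &
                    abs(d$pos[later] - d$pos[i]) <= window]
    if (length(near)) {
      r2 <- ld_r2(ld, d$snp[i], d$snp[near])
      alive[near[r2 >= r2_threshold]] <- FALSE
    }
  }
  out <- d[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Instrument-strength F statistic
#'
#' Per-variant strength `(beta/se)^2`; values above 10 conventionally
#' indicate the instrument is strong enough to avoid weak-instrument
#' bias.
#'
#' @param beta,se per-variant effect and standard error (vectorized).
#' @return numeric vector of F statistics.
#' @export
#' @examples
#' f_statistic(0.05, 0.012)
f_statistic <- function(beta, se) {
  if (any(is.na(se)) || any(se <= 0)) {
    mr_error("mr_validation_error", "se must be strictly positive")
  }
  (beta / se)^2
}

#' Filter exposures by instrument count and strength
#'
#' Keeps an exposure only if at least `min_snps` of its instruments have
#' F above `f_min`; weak instruments are removed from retained sets.
#' Dropped exposures are reported with the reason in the `"dropped"`
#' attribute.
#'
#' @param sets named list of instrument data.frames.
#' @param min_snps minimum number of valid instruments (default 3).
#' @param f_min minimum F statistic (default 10).
#' @return named list of filtered instrument sets, with attribute
#'   `"dropped"` (data.frame `exposure`, `reason`).
#' @export
filter_exposures <- function(sets, min_snps = 3, f_min = 10) {
  kept <- list()
  dropped <- data.frame(exposure = character(), reason = character(),
                        stringsAsFactors = FALSE)
  for (nm in names(sets)) {
    s <- sets[[nm]]
    f <- f_statistic(s$beta, s$se)
    valid <- f > f_min
    if (sum(valid) >= min_snps) {
      out <- s[valid, , drop = FALSE]
      out$f_stat <- f[valid]
      rownames(out) <- NULL
      kept[[nm]] <- out
    } else {
      dropped <- rbind(dropped, data.frame(
        exposure = nm,
        reason = sprintf("only %d instrument(s) with F > %g (need %d)",
                         sum(valid), f_min, min_snps),
        stringsAsFactors = FALSE
      ))
    }
  }
  attr(kept, "dropped") <- dropped
  kept
}
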
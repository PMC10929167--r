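# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
mr_error <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "mrscreen_error", "error", "condition")))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded internals
#' (bootstraps, null simulations) do not perturb the caller's stream.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed tied to a character key (not to loop position),
# so that screens are exposure-order invariant. Kept below 2^31 - 1.
#' @noRd
seed_for <- function(seed, key) {
  h <- sum(utf8ToInt(key) * (seq_len(nchar(key)) %% 97 + 1))
  as.integer((as.numeric(seed) + 1000003 * (h %% 1000003)) %% 2147483629) + 1L
}

#' @noRd
norm_ci <- function(beta, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(beta - z * se, beta + z * se)
}

#' @noRd
norm_p <- function(beta, se) 2 * stats::pnorm(-abs(beta / se))

# One row of the tidy estimates table shared by every method.
#' @noRd
mr_estimate <- function(method, beta, se, nsnp, pval = NULL, ci = NULL) {
  if (is.null(ci)) ci <- norm_ci(beta, se)
  if (is.null(pval)) pval <- norm_p(beta, se)
  data.frame(
    method = method, nsnp = as.integer(nsnp), beta = beta, se = se,
    ci_low = ci[1], ci_high = ci[2], pval = pval,
    stringsAsFactors = FALSE
  )
}
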
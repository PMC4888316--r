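#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `code`, and
#' restores the previous state on exit, so seeded generators never perturb
#' the session's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Percentage of markers retained, at printed precision
#'
#' @param retained,total marker counts.
#' @param digits decimal places (default 2, the precision such reports use).
#' @return `round(100 * retained / total, digits)`.
#' @export
retention_percentage <- function(retained, total, digits = 2) {
  stopifnot(total > 0, retained >= 0, retained <= total)
  round(100 * retained / total, digits)
}

#' Carrier-count threshold expressed as a percentage of the cohort
#'
#' A minimum-carrier filter of `min_samples` out of `n_samples` animals,
#' as the frequency it corresponds to (e.g. 10 of 2230 is 0.45%).
#'
#' @param min_samples carrier-count threshold.
#' @param n_samples cohort size.
#' @param digits decimal places (default 2).
#' @return percentage as a number.
#' @export
carrier_threshold_pct <- function(min_samples, n_samples, digits = 2) {
  stopifnot(min_samples >= 1, n_samples >= min_samples)
  round(100 * min_samples / n_samples, digits)
}

# Order chromosome labels numerically where possible ("1" < "2" < ... < "10"),
# alphabetically otherwise; numeric labels sort before non-numeric.
chromosome_order <- function(chrom) {
  u <- unique(as.character(chrom))
  num <- suppressWarnings(as.numeric(sub("^chr", "", u)))
  ord <- order(is.na(num), num, u)
  factor(as.character(chrom), levels = u[ord])
}

# half-up rounding to the nearest integer (round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)
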
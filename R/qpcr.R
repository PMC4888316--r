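#' Relative quantification by the 2^-ddCT method
#'
#' Replicate CTs are averaged per (sample, target) first; then
#' `dCT(sample) = mean CT(target) - mean CT(control)` within the sample,
#' `ddCT = dCT(sample) - dCT(reference sample)`, and the relative quantity
#' is `2^-ddCT` (amplification efficiency fixed at perfect doubling).
#' Adding a constant to every CT of a sample cancels in dCT, so
#' plate/pipetting offsets do not bias the result.
#'
#' @param ct CT table: data.frame `sample_id`, `target_id`, `assay_type`,
#'   `replicate`, `ct`.
#' @param target target id to quantify.
#' @param sample sample id to quantify.
#' @param reference_sample calibrator sample id; defaults to the table's
#'   `reference_sample` attribute.
#' @param control_target internal control target id (e.g. BTF3 for DNA,
#'   GAPDH for RNA); defaults to the table's `control_target` attribute.
#' @return the relative quantity 2^-ddCT (unitless).
#' @export
ddct <- function(ct, target, sample,
                 reference_sample = attr(ct, "reference_sample"),
                 control_target = attr(ct, "control_target")) {
  if (is.null(reference_sample) || is.null(control_target))
    stop("reference_sample and control_target must be given or attached to the table")
  mean_ct <- function(s, tg) {
    v <- ct$ct[ct$sample_id == s & ct$target_id == tg]
    if (length(v) == 0) {
      if (tg == control_target)
        stop("no control-target CTs for sample ", s)
      stop(sprintf("no CTs for sample %s, target %s", s, tg))
    }
    mean(v)
  }
  dct_s <- mean_ct(sample, target) - mean_ct(sample, control_target)
  dct_r <- mean_ct(reference_sample, target) - mean_ct(reference_sample,
                                                       control_target)
  2^(-(dct_s - dct_r))
}

#' Relative quantities for every (sample, target) pair in a CT table
#'
#' @inheritParams ddct
#' @return data.frame `sample_id`, `target_id`, `rq`, `copies`
#'   (see [copy_call_from_rq()]).
#' @export
ddct_table <- function(ct, reference_sample = attr(ct, "reference_sample"),
                       control_target = attr(ct, "control_target")) {
  targets <- setdiff(unique(ct$target_id), control_target)
  samples <- unique(ct$sample_id)
  grid <- expand.grid(sample_id = samples, target_id = targets,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$rq <- mapply(function(s, tg)
    ddct(ct, tg, s, reference_sample, control_target),
    grid$sample_id, grid$target_id)
  grid$copies <- copy_call_from_rq(grid$rq)
  grid
}

#' Integer copy-number call from a relative quantity
#'
#' `round(rq * reference_copies)` to the nearest integer (ties round half
#' up), floored at 0. With a diploid calibrator, rq 1.5 is 3 copies and
#' rq 0.48 is 1 copy.
#'
#' @param rq relative quantity (> 0).
#' @param reference_copies copy number of the calibrator sample (default 2).
#' @return integer copy number(s).
#' @export
copy_call_from_rq <- function(rq, reference_copies = 2) {
  if (any(rq <= 0)) stop("rq must be positive")
  pmax(0L, as.integer(round_half_up(rq * reference_copies)))
}

#' Concordance between array CNV states and qPCR copy calls
#'
#' qPCR calls are mapped to three states (< 2 copies loss, 2 neutral,
#' > 2 gain) and compared with the array states over the shared
#' (sample, cnv) keys; both tables must cover exactly the same keys.
#'
#' @param array_states data.frame `sample_id`, `cnv`, `state`
#'   ("loss"/"neutral"/"gain").
#' @param qpcr_calls data.frame `sample_id`, `cnv`, `copies` (integer).
#' @return fraction of agreeing pairs, in [0, 1].
#' @export
concordance <- function(array_states, qpcr_calls) {
  ka <- paste(array_states$sample_id, array_states$cnv, sep = "\r")
  kq <- paste(qpcr_calls$sample_id, qpcr_calls$cnv, sep = "\r")
  miss <- c(setdiff(ka, kq), setdiff(kq, ka))
  if (length(miss))
    stop("mismatched (sample, cnv) keys: ",
         paste(gsub("\r", "/", utils::head(miss, 10)), collapse = ", "))
  q_state <- with(qpcr_calls,
                  ifelse(copies < 2, "loss", ifelse(copies > 2, "gain",
                                                    "neutral")))
  mean(array_states$state == q_state[match(ka, kq)])
}

#' One-way ANOVA between copy-number groups
#'
#' Fixed-effects one-way ANOVA of (typically) expression relative
#' quantities across copy-number groups, the standard test for a gene-dose
#' effect on transcription.
#'
#' @param groups named list of numeric vectors, one per copy-number group.
#' @return list with `f` and `p`.
#' @export
anova_copy_groups <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  n <- lengths(groups)
  if (sum(n) - length(groups) < 1)
    stop("no error degrees of freedom (singleton groups only)")
  if (any(n == 1 & vapply(groups, function(g) length(unique(g)) == 1,
                          logical(1)) & sum(n > 1) == 0))
    stop("cannot estimate within-group variance")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), n))
  fit <- stats::aov(y ~ g)
  tab <- summary(fit)[[1]]
  list(f = tab[["F value"]][1], p = tab[["Pr(>F)"]][1])
}
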
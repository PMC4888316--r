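#' Segmentation parameters
#'
#' The three published constraints of the multivariate copy-number
#' segmentation this package reimplements, plus the three-state calling
#' threshold: a density cap of `max_segments_per_10k_markers` segments per
#' 10k-marker block of a chromosome, a minimum of `min_markers` markers per
#' segment, and a maximum pairwise p-value `max_pairwise_p` for the
#' between-segment test at each accepted breakpoint. `state_threshold` is
#' the |segment mean| at which a per-sample segment mean is called a
#' loss/gain (inclusive).
#'
#' @param max_segments_per_10k_markers segment budget per 10k markers
#'   (default 20).
#' @param min_markers minimum markers per segment (default 3).
#' @param max_pairwise_p p-value ceiling for accepting a breakpoint
#'   (default 0.005).
#' @param state_threshold three-state calling threshold (default 0.4).
#' @return list of class `segmentation_params`.
#' @export
segmentation_params <- function(max_segments_per_10k_markers = 20,
                                min_markers = 3, max_pairwise_p = 0.005,
                                state_threshold = 0.4) {
  stopifnot(max_segments_per_10k_markers >= 1, min_markers >= 1,
            max_pairwise_p > 0, max_pairwise_p < 1, state_threshold > 0)
  structure(list(max_segments_per_10k_markers = max_segments_per_10k_markers,
                 min_markers = min_markers, max_pairwise_p = max_pairwise_p,
                 state_threshold = state_threshold),
            class = "segmentation_params")
}

# Pooled within-segment sum of squares of markers a..b (1-based, inclusive)
# around per-sample segment means, from cumulative sums.
# Cs: n_samples x (m+1) row-cumsum matrix with a leading 0 column;
# q: length m+1 cumsum of per-marker total sum of squares, leading 0.
.seg_sse <- function(Cs, q, a, b) {
  len <- b - a + 1
  s <- Cs[, b + 1L] - Cs[, a]
  (q[b + 1L] - q[a]) - sum(s * s) / len
}

# Best single split of segment a..b honouring min_markers on both children.
# Returns list(k, delta, ncand) with k the last marker of the left child,
# or NULL when no candidate exists.
.best_split <- function(Cs, q, a, b, min_markers) {
  ks <- seq.int(a + min_markers - 1L, b - min_markers)
  if (length(ks) == 0 || ks[1] > ks[length(ks)]) return(NULL)
  lenL <- ks - a + 1
  lenR <- b - ks
  SL <- Cs[, ks + 1L, drop = FALSE] - Cs[, a]
  SR <- (Cs[, b + 1L] - Cs[, a]) - SL
  sseL <- (q[ks + 1L] - q[a]) - colSums(SL * SL) / lenL
  sseR <- (q[b + 1L] - q[ks + 1L]) - colSums(SR * SR) / lenR
  tot <- sseL + sseR
  i <- which.min(tot)  # leftmost on ties
  delta <- .seg_sse(Cs, q, a, b) - tot[i]
  list(k = ks[i], delta = delta, ncand = length(ks))
}

# Robust marker-level noise variance: per sample, the MAD of first
# differences along markers; squared differences double the variance, and
# the median across samples resists carriers' breakpoint jumps.
.noise_variance <- function(X) {
  if (ncol(X) < 2) return(NA_real_)
  d <- X[, -1L, drop = FALSE] - X[, -ncol(X), drop = FALSE]
  stats::median(apply(d, 1, stats::mad)^2) / 2
}

#' Jointly segment a cohort LRR matrix
#'
#' Greedy recursive binary splitting on the pooled (all-samples)
#' within-segment sum of squares, per chromosome. A candidate breakpoint —
#' always the split giving the largest pooled SSE reduction, ties broken
#' leftmost — is accepted only if (i) both children have at least
#' `min_markers` markers, (ii) the pairwise comparison of the two flanking
#' children is significant at `max_pairwise_p`, and (iii) the chromosome's
#' running segment count stays within its budget of
#' `max_segments_per_10k_markers` per started 10k-marker block. Splitting
#' proceeds in order of decreasing SSE reduction across the chromosome's
#' open segments; a segment whose best split fails the test is closed.
#' The result partitions every chromosome's marker list.
#'
#' The pairwise test pools the per-sample mean contrast between the two
#' children: for a fixed breakpoint the SSE reduction is a sum of n
#' independent scaled chi-square(1) contrasts under the no-change null, so
#' `delta_SSE / sigma^2` is compared against chi-square(n), with sigma^2
#' estimated robustly from first differences along markers (median across
#' samples of MAD^2 / 2). Because the tested breakpoint is the best of all
#' candidate positions in its segment, the p-value is Bonferroni-corrected
#' by the number of candidates before the `max_pairwise_p` gate; a
#' mean-based test without this correction over-splits pure-noise
#' chromosomes badly. A zero noise estimate (constant data) yields no
#' splits.
#'
#' @param m a GC-corrected, autosome-restricted [intensity_matrix()] with
#'   no missing values (see [impute_missing()]).
#' @param params a [segmentation_params()].
#' @return data.frame of segments: `chromosome`, `first_marker`,
#'   `last_marker` (1-based indices into the chromosome's marker order),
#'   `start_bp`, `end_bp` (positions of the boundary markers), `n_markers`.
#' @export
segment_multivariate <- function(m, params = segmentation_params()) {
  stopifnot(inherits(m, "intensity_matrix"),
            inherits(params, "segmentation_params"))
  if (!m$corrected)
    stop("segment a GC-corrected matrix (run gc_correct() first)")
  if (anyNA(m$lrr))
    stop("LRR matrix has missing values; run impute_missing() first")
  out <- list()
  for (ch in unique(m$map$chromosome)) {
    idx <- which(m$map$chromosome == ch)
    nm <- length(idx)
    pos <- m$map$position[idx]
    if (nm < params$min_markers) {
      warning(sprintf("chromosome %s has %d < %d markers; kept as one segment",
                      ch, nm, params$min_markers))
      out[[ch]] <- data.frame(chromosome = ch, first_marker = 1L,
                              last_marker = nm, start_bp = pos[1],
                              end_bp = pos[nm], n_markers = nm,
                              stringsAsFactors = FALSE)
      next
    }
    X <- m$lrr[, idx, drop = FALSE]
    Cs <- cbind(0, t(apply(X, 1, cumsum)))
    if (nrow(X) == 1) Cs <- matrix(c(0, cumsum(X[1, ])), nrow = 1)
    q <- c(0, cumsum(colSums(X * X)))
    sigma2 <- .noise_variance(X)
    n <- nrow(X)
    budget <- params$max_segments_per_10k_markers * ceiling(nm / 10000)
    open <- list(c(1L, nm))     # segments still eligible for splitting
    closed <- list()            # segments whose best split failed the test
    n_seg <- 1L
    while (length(open) > 0 && n_seg < budget) {
      cand <- lapply(open, function(seg)
        .best_split(Cs, q, seg[1], seg[2], params$min_markers))
      ok <- !vapply(cand, is.null, logical(1))
      if (!any(ok)) break
      deltas <- rep(-Inf, length(cand))
      deltas[ok] <- vapply(cand[ok], `[[`, numeric(1), "delta")
      i <- which.max(deltas)   # leftmost segment on ties (which.max)
      if (!ok[i] || !is.finite(deltas[i])) break
      sp <- cand[[i]]
      seg <- open[[i]]
      p <- if (is.na(sigma2) || sigma2 <= 0) NA_real_ else
        min(1, stats::pchisq(sp$delta / sigma2, df = n,
                             lower.tail = FALSE) * sp$ncand)
      if (is.na(p) || p > params$max_pairwise_p) {
        closed <- c(closed, list(seg))
        open[[i]] <- NULL
      } else {
        open[[i]] <- NULL
        open <- c(open, list(c(seg[1], sp$k)), list(c(sp$k + 1L, seg[2])))
        n_seg <- n_seg + 1L
      }
    }
    segs <- c(open, closed)
    segs <- segs[order(vapply(segs, `[[`, integer(1), 1L))]
    out[[ch]] <- data.frame(
      chromosome = ch,
      first_marker = vapply(segs, `[[`, integer(1), 1L),
      last_marker = vapply(segs, `[[`, integer(1), 2L),
      stringsAsFactors = FALSE)
    out[[ch]]$start_bp <- pos[out[[ch]]$first_marker]
    out[[ch]]$end_bp <- pos[out[[ch]]$last_marker]
    out[[ch]]$n_markers <- out[[ch]]$last_marker - out[[ch]]$first_marker + 1L
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call three-state copy-number status per sample and segment
#'
#' Each sample's mean corrected LRR over a segment is thresholded:
#' mean <= -threshold is a loss, mean >= +threshold a gain, otherwise
#' neutral. Thresholds are inclusive, so a mean of exactly -0.4 at the
#' default is called a loss.
#'
#' @param segments segment table from [segment_multivariate()].
#' @param m the [intensity_matrix()] that was segmented.
#' @param threshold calling threshold (default 0.4).
#' @return object of class `state_calls`: list with `segments` (the input
#'   table), `means` (samples x segments matrix of per-sample segment mean
#'   LRR) and `states` (same shape, values "loss"/"neutral"/"gain").
#' @export
call_states <- function(segments, m, threshold = 0.4) {
  stopifnot(inherits(m, "intensity_matrix"), threshold > 0)
  n_seg <- nrow(segments)
  means <- matrix(NA_real_, nrow(m$lrr), n_seg,
                  dimnames = list(rownames(m$lrr), NULL))
  for (ch in unique(segments$chromosome)) {
    idx <- which(m$map$chromosome == ch)
    rows <- which(segments$chromosome == ch)
    # segments must partition the chromosome's marker list
    fm <- segments$first_marker[rows]; lm <- segments$last_marker[rows]
    o <- order(fm)
    if (fm[o][1] != 1L || lm[o][length(o)] != length(idx) ||
        (length(o) > 1 && any(fm[o][-1] != lm[o][-length(o)] + 1L)))
      stop("segments do not partition chromosome ", ch)
    for (r in rows) {
      cols <- idx[segments$first_marker[r]:segments$last_marker[r]]
      means[, r] <- rowMeans(m$lrr[, cols, drop = FALSE])
    }
  }
  states <- matrix("neutral", nrow(means), ncol(means),
                   dimnames = dimnames(means))
  states[means <= -threshold] <- "loss"
  states[means >= threshold] <- "gain"
  structure(list(segments = segments, means = means, states = states,
                 threshold = threshold),
            class = "state_calls")
}

#' @export
print.state_calls <- function(x, ...) {
  cat(sprintf("state_calls: %d samples x %d segments (threshold %.2f); %d variant calls\n",
              nrow(x$states), ncol(x$states), x$threshold,
              sum(x$states != "neutral")))
  invisible(x)
}
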
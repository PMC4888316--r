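# Independent oracles used across the suite. These deliberately use naive,
# brute-force formulations so they share no code path with the package.

# Benjamini-Hochberg step-up, straight from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# Per-basepair interval overlap: enumerate covered positions as sets.
bp_overlap_oracle <- function(s1, e1, s2, e2) {
  length(intersect(seq.int(s1, e1), seq.int(s2, e2)))
}

# Exhaustive best segmentation of a samples x markers matrix into at most
# 3 segments (<= 2 breakpoints), minimising the pooled within-segment SSE
# around per-sample segment means.
exhaustive_sse_oracle <- function(X, min_markers = 3) {
  nm <- ncol(X)
  sse_range <- function(a, b) {
    sub <- X[, a:b, drop = FALSE]
    sum((sub - rowMeans(sub))^2)
  }
  best <- sse_range(1, nm)
  for (k1 in seq(min_markers, nm - min_markers)) {
    two <- sse_range(1, k1) + sse_range(k1 + 1, nm)
    best <- min(best, two)
    k2s <- seq.int(k1 + min_markers, nm - min_markers)
    for (k2 in k2s[k2s >= k1 + min_markers & k2s <= nm - min_markers]) {
      best <- min(best, sse_range(1, k1) + sse_range(k1 + 1, k2) +
                    sse_range(k2 + 1, nm))
    }
  }
  best
}

# Pooled within-segment SSE of an emitted segment table on one chromosome.
segmentation_sse <- function(X, segs) {
  sum(vapply(seq_len(nrow(segs)), function(i) {
    sub <- X[, segs$first_marker[i]:segs$last_marker[i], drop = FALSE]
    sum((sub - rowMeans(sub))^2)
  }, numeric(1)))
}

# Interval union by position membership (brute force).
union_span_oracle <- function(starts, ends) {
  covered <- sort(unique(unlist(mapply(seq.int, starts, ends,
                                       SIMPLIFY = FALSE))))
  c(min(covered), max(covered))
}
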
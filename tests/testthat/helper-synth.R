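# Shared synthetic fixtures. The benchmark cohort mirrors the package's
# reference segmentation conditions: 50 samples x 200 markers, one planted
# 10-marker hemizygous loss (markers 50-59, shift -1.0, 30% carriers),
# marker noise sd 0.15, no GC wave. GC-flat data is declared corrected so
# segmentation benchmarks bypass the (here vacuous) correction stage.
benchmark_cohort <- function(seed, n_samples = 50, n_markers = 200,
                             shift = -1.0, carrier_fraction = 0.3,
                             noise_sd = 0.15, event = c(50L, 59L)) {
  map <- generate_marker_map(1, n_markers, 10000, 2e6, seed = seed)
  pl <- planted_cnv("1", map$position[event[1]], map$position[event[2]],
                    if (shift < 0) "loss" else "gain",
                    carrier_fraction, shift)
  sim <- generate_lrr(map, n_samples, pl, noise_sd = noise_sd,
                      gc_wave_amplitude = 0, seed = seed + 10000)
  sim$intensity$corrected <- TRUE
  sim$map <- map
  sim$true_breakpoints <- c(event[1] - 1L, event[2])  # last marker of left piece
  sim
}

# Breakpoint recall/precision of a segment table against true breakpoints
# (matched within +/- `slack` markers).
breakpoint_scores <- function(segs, true_bps, slack = 1) {
  bps <- segs$last_marker[-nrow(segs)]
  hit <- vapply(true_bps, function(t) any(abs(bps - t) <= slack), logical(1))
  matched <- if (length(bps))
    vapply(bps, function(b) any(abs(true_bps - b) <= slack), logical(1))
  else logical(0)
  c(tp = sum(hit), fn = sum(!hit), fp = sum(!matched))
}

# A two-subpopulation cohort with allele-frequency drift at every locus and
# a per-subpopulation trait offset: the classic stratified-null confounder.
stratified_genotypes <- function(seed, n_per_pop = 250, n_events = 100,
                                 freq_a = 0.1, freq_b = 0.4) {
  with_seed(seed, {
    n <- 2 * n_per_pop
    ids <- sprintf("S%04d", seq_len(n))
    subpop <- rep(c("A", "B"), each = n_per_pop)
    g <- matrix(1L, n, n_events,
                dimnames = list(ids, paste0("CNV", seq_len(n_events))))
    for (j in seq_len(n_events)) {
      f <- ifelse(subpop == "A", freq_a, freq_b)
      carrier <- stats::runif(n) < f
      # each locus is a loss or a gain polymorphism, so the frequency
      # difference shifts the subpopulation genotype means
      g[carrier, j] <- if (j %% 2 == 0) 0L else 2L
    }
    list(g = g, ids = ids, subpop = subpop)
  })
}

# Minimal trait table wrapper around a response vector (accuracy 0.9).
as_trait_table <- function(ids, y, trait = "WG") {
  out <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  out[[paste0(trait, "_ebv")]] <- y
  out[[paste0(trait, "_acc")]] <- 0.9
  out
}
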
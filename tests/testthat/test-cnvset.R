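# Hand-built state_calls objects: a partitioned chromosome with chosen
# per-sample states, the raw material of the merge/filter/name chain.
make_calls <- function(segments, states) {
  structure(list(segments = segments, states = states,
                 means = matrix(0, nrow(states), ncol(states),
                                dimnames = dimnames(states)),
                 threshold = 0.4),
            class = "state_calls")
}

seg_row <- function(chromosome, fm, lm, start, end) {
  data.frame(chromosome = chromosome, first_marker = fm, last_marker = lm,
             start_bp = start, end_bp = end, n_markers = lm - fm + 1L,
             stringsAsFactors = FALSE)
}

test_that("adjacent variant segments union into one event (oracle check)", {
  segs <- rbind(seg_row("1", 1L, 10L, 100L, 200L),
                seg_row("1", 11L, 20L, 201L, 300L),
                seg_row("1", 21L, 30L, 301L, 400L))
  states <- matrix("neutral", 3, 3, dimnames = list(paste0("S", 1:3), NULL))
  states[1, 1] <- "loss"; states[2, 2] <- "loss"  # segments 1,2 variant
  cnvs <- merge_events(make_calls(segs, states))
  expect_equal(nrow(cnvs$events), 1)
  oracle <- union_span_oracle(c(100, 201), c(200, 300))
  expect_equal(c(cnvs$events$start_bp, cnvs$events$end_bp), oracle)
  # neutral-only segment 3 contributes no event
  expect_equal(cnvs$events$n_markers, 20L)
})

test_that("segments on different chromosomes never merge", {
  segs <- rbind(seg_row("1", 1L, 10L, 100L, 200L),
                seg_row("2", 1L, 10L, 100L, 200L))
  states <- matrix("loss", 2, 2, dimnames = list(paste0("S", 1:2), NULL))
  cnvs <- merge_events(make_calls(segs, states))
  expect_equal(nrow(cnvs$events), 2)
  expect_setequal(cnvs$events$chromosome, c("1", "2"))
})

test_that("all-neutral call sets produce an empty event set", {
  segs <- seg_row("1", 1L, 10L, 100L, 200L)
  states <- matrix("neutral", 2, 1, dimnames = list(paste0("S", 1:2), NULL))
  cnvs <- merge_events(make_calls(segs, states))
  expect_equal(nrow(cnvs$events), 0)
  expect_equal(ncol(cnvs$states), 0)
})

test_that("mixed loss/gain within one sample resolves by longer span, tie to loss", {
  segs <- rbind(seg_row("1", 1L, 5L, 100L, 150L),    # span 51
                seg_row("1", 6L, 20L, 151L, 400L))   # span 250
  states <- matrix("neutral", 2, 2, dimnames = list(paste0("S", 1:2), NULL))
  states[1, 1] <- "loss"; states[1, 2] <- "gain"
  expect_message(cnvs <- merge_events(make_calls(segs, states)), "mixed")
  expect_equal(unname(cnvs$states[1, 1]), "gain")  # longer span wins
  # exact tie in spans -> loss
  segs2 <- rbind(seg_row("1", 1L, 5L, 100L, 200L),
                 seg_row("1", 6L, 10L, 201L, 301L))
  expect_message(cnvs2 <- merge_events(make_calls(segs2, states)), "mixed")
  expect_equal(unname(cnvs2$states[1, 1]), "loss")
})

test_that("event frequencies sum to one exactly and match a recount", {
  segs <- seg_row("1", 1L, 10L, 100L, 200L)
  states <- matrix(c("loss", "loss", "gain", "neutral", "neutral"), 5, 1,
                   dimnames = list(paste0("S", 1:5), NULL))
  cnvs <- merge_events(make_calls(segs, states))
  ev <- cnvs$events
  neutral_freq <- mean(cnvs$states[, 1] == "neutral")
  expect_identical(ev$loss_freq + ev$gain_freq + neutral_freq, 1)
  expect_identical(ev$variant_freq, ev$loss_freq + ev$gain_freq)
  expect_equal(ev$loss_freq, 0.4)
  expect_equal(ev$gain_freq, 0.2)
  expect_equal(ev$carrier_count, 3L)
  # genotype-matrix recount reproduces the stored frequencies
  named <- name_by_loss_frequency(cnvs)
  g <- build_genotypes(named)
  expect_equal(unname(colMeans(g == 0)), named$events$loss_freq)
  expect_equal(unname(colMeans(g == 2)), named$events$gain_freq)
})

test_that("the two-step filter applies the carrier floor then the length cap", {
  mk_set <- function(carriers, length_bp) {
    n <- 20
    states <- matrix("neutral", n, length(carriers),
                     dimnames = list(sprintf("S%02d", 1:n), NULL))
    for (j in seq_along(carriers)) states[seq_len(carriers[j]), j] <- "loss"
    events <- data.frame(chromosome = "1",
                         start_bp = seq_along(carriers) * 10000000L,
                         end_bp = seq_along(carriers) * 10000000L + length_bp - 1L,
                         length_bp = length_bp,
                         n_markers = 5L, carrier_count = carriers,
                         loss_freq = carriers / n, gain_freq = 0,
                         variant_freq = carriers / n,
                         stringsAsFactors = FALSE)
    structure(list(events = events, states = states), class = "cnv_set")
  }
  # 9 carriers: removed at step 1; 10 carriers: kept
  s <- mk_set(c(9L, 10L), c(1000L, 4855088L))
  f <- suppressMessages(filter_events(s, 10, 5e6))
  expect_equal(nrow(f$events), 1)
  expect_equal(f$events$carrier_count, 10L)
  expect_equal(attr(f, "filter_report"),
               list(merged = 2L, after_frequency = 1L, after_length = 1L))
  # 5,000,001 bp: removed at step 2; 4,855,088 bp at 10 carriers: retained
  s2 <- mk_set(c(12L, 12L), c(5000001L, 4855088L))
  f2 <- suppressMessages(filter_events(s2, 10, 5e6))
  expect_equal(f2$events$length_bp, 4855088L)
  # raising the carrier floor is monotone in retained count
  retained <- vapply(1:15, function(k)
    nrow(suppressMessages(filter_events(mk_set(c(5L, 8L, 12L), 1000L),
                                        k, 5e6))$events), integer(1))
  expect_true(all(diff(retained) <= 0))
})

test_that("naming sorts by loss frequency with positional tie-breaks", {
  events <- data.frame(chromosome = c("1", "1", "2"),
                       start_bp = c(100L, 50L, 10L),
                       end_bp = c(199L, 149L, 109L), length_bp = 100L,
                       n_markers = 5L, carrier_count = c(4L, 9L, 5L),
                       loss_freq = c(0.2, 0.9, 0.5), gain_freq = 0,
                       variant_freq = c(0.2, 0.9, 0.5),
                       stringsAsFactors = FALSE)
  states <- matrix("neutral", 10, 3,
                   dimnames = list(sprintf("S%02d", 1:10), NULL))
  cnvs <- structure(list(events = events, states = states), class = "cnv_set")
  named <- name_by_loss_frequency(cnvs)
  expect_equal(named$events$name, c("CNV1", "CNV2", "CNV3"))
  expect_equal(named$events$loss_freq, c(0.9, 0.5, 0.2))
  # equal loss frequencies: lower start on the same chromosome first
  events$loss_freq <- c(0.5, 0.5, 0.5)
  cnvs2 <- structure(list(events = events, states = states), class = "cnv_set")
  named2 <- name_by_loss_frequency(cnvs2)
  expect_equal(named2$events$start_bp, c(50L, 100L, 10L))
  expect_equal(named2$events$name, paste0("CNV", 1:3))
})

test_that("genotype coding is loss 0, neutral 1, gain 2", {
  states <- matrix(c("neutral", "loss", "gain", "neutral"), 2, 2,
                   dimnames = list(c("S1", "S2"), c("CNV1", "CNV2")))
  cnvs <- structure(list(events = data.frame(), states = states),
                    class = "cnv_set")
  g <- build_genotypes(cnvs)
  expect_identical(g, matrix(c(1L, 0L, 2L, 1L), 2, 2,
                             dimnames = dimnames(states)))
})

test_that("BED export round-trips event coordinates", {
  events <- data.frame(name = c("CNV1", "CNV2"), chromosome = c("3", "7"),
                       start_bp = c(894L, 1000001L),
                       end_bp = c(5749L, 1500000L), stringsAsFactors = FALSE)
  bed <- events_to_bed(events)
  expect_equal(bed$chromStart, c(893L, 1000000L))
  back <- bed_to_events(bed)
  expect_equal(back$start_bp, events$start_bp)
  expect_equal(back$end_bp, events$end_bp)
})

test_that("planted common events survive the full call-merge-filter chain", {
  hits <- 0L; total <- 0L
  for (seed in 401:410) {
    map <- generate_marker_map(1, 200, 10000, 2e6, seed = seed)
    pl <- rbind(
      planted_cnv("1", map$position[50], map$position[59], "loss", 0.3, -1.0),
      planted_cnv("1", map$position[120], map$position[129], "gain", 0.2, 1.0))
    sim <- generate_lrr(map, 50, pl, noise_sd = 0.15, seed = seed + 1000)
    sim$intensity$corrected <- TRUE
    segs <- segment_multivariate(sim$intensity)
    calls <- call_states(segs, sim$intensity)
    cnvs <- suppressMessages(
      filter_events(merge_events(calls), min_carrier_samples = 5))
    for (e in seq_len(nrow(pl))) {
      total <- total + 1L
      ts <- pl$start_bp[e]; te <- pl$end_bp[e]
      ok <- any(vapply(seq_len(nrow(cnvs$events)), function(i) {
        ov <- bp_overlap_oracle(cnvs$events$start_bp[i], cnvs$events$end_bp[i],
                                ts, te)
        ov >= 0.8 * (te - ts + 1) &&
          ov >= 0.8 * cnvs$events$length_bp[i]
      }, logical(1)))
      hits <- hits + ok
    }
  }
  expect_gte(hits / total, 0.95)
})
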
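#' Merge variant segments into non-redundant CNV events
#'
#' Segments that are variant (non-neutral) in at least one sample are
#' collected per chromosome; runs of such segments that overlap or are
#' bookended (adjacent in the chromosome's marker partition) are unioned
#' into one event spanning the minimum start to the maximum end. Each
#' sample's state for the event is its most extreme state over the
#' constituent segments; a sample showing both loss and gain takes the
#' state covering the longer basepair span, with ties going to loss (a
#' message reports how often this rule fired). Merged events are pairwise
#' non-overlapping within a chromosome.
#'
#' @param calls a [call_states()] result covering all samples and segments.
#' @return object of class `cnv_set`: list with `events` (data.frame
#'   `chromosome`, `start_bp`, `end_bp`, `length_bp`, `n_markers`,
#'   `carrier_count`, `loss_freq`, `gain_freq`, `variant_freq`) and
#'   `states` (samples x events matrix).
#' @export
merge_events <- function(calls) {
  stopifnot(inherits(calls, "state_calls"))
  segs <- calls$segments
  st <- calls$states
  samples <- rownames(st)
  variant_seg <- colSums(st != "neutral") > 0
  ev_rows <- list(); ev_states <- list()
  n_mixed <- 0L
  for (ch in unique(segs$chromosome)) {
    rows <- which(segs$chromosome == ch)
    rows <- rows[order(segs$first_marker[rows])]
    vr <- variant_seg[rows]
    if (!any(vr)) next
    # runs of consecutive variant segments within the partition
    run_id <- cumsum(vr & !c(FALSE, vr[-length(vr)]))
    run_id[!vr] <- 0L
    for (g in setdiff(unique(run_id), 0L)) {
      members <- rows[run_id == g]
      sub <- st[, members, drop = FALSE]
      span <- segs$end_bp[members] - segs$start_bp[members] + 1
      state <- apply(sub, 1, function(s) {
        has_loss <- any(s == "loss"); has_gain <- any(s == "gain")
        if (has_loss && has_gain) {
          lb <- sum(span[s == "loss"]); gb <- sum(span[s == "gain"])
          if (gb > lb) "gain" else "loss"
        } else if (has_loss) "loss" else if (has_gain) "gain" else "neutral"
      })
      n_mixed <- n_mixed +
        sum(apply(sub, 1, function(s) any(s == "loss") && any(s == "gain")))
      ev_rows[[length(ev_rows) + 1L]] <- data.frame(
        chromosome = ch,
        start_bp = min(segs$start_bp[members]),
        end_bp = max(segs$end_bp[members]),
        n_markers = sum(segs$n_markers[members]),
        stringsAsFactors = FALSE)
      ev_states[[length(ev_states) + 1L]] <- state
    }
  }
  if (length(ev_rows) == 0) {
    events <- data.frame(chromosome = character(), start_bp = integer(),
                         end_bp = integer(), length_bp = integer(),
                         n_markers = integer(), carrier_count = integer(),
                         loss_freq = numeric(), gain_freq = numeric(),
                         variant_freq = numeric(), stringsAsFactors = FALSE)
    states <- matrix(character(), length(samples), 0,
                     dimnames = list(samples, NULL))
    return(structure(list(events = events, states = states), class = "cnv_set"))
  }
  if (n_mixed > 0)
    message(sprintf("resolved %d mixed loss/gain sample-event states by longer span (tie -> loss)",
                    n_mixed))
  events <- do.call(rbind, ev_rows)
  states <- do.call(cbind, ev_states)
  rownames(states) <- samples
  n <- length(samples)
  events$length_bp <- events$end_bp - events$start_bp + 1L
  events$carrier_count <- colSums(states != "neutral")
  events$loss_freq <- colSums(states == "loss") / n
  events$gain_freq <- colSums(states == "gain") / n
  events$variant_freq <- events$loss_freq + events$gain_freq
  events <- events[, c("chromosome", "start_bp", "end_bp", "length_bp",
                       "n_markers", "carrier_count", "loss_freq",
                       "gain_freq", "variant_freq")]
  rownames(events) <- NULL
  structure(list(events = events, states = states), class = "cnv_set")
}

#' @export
print.cnv_set <- function(x, ...) {
  cat(sprintf("cnv_set: %d events x %d samples\n",
              nrow(x$events), nrow(x$states)))
  invisible(x)
}

#' Two-step frequency and length filter for CNV events
#'
#' Step 1 removes events carried (any non-neutral state) by fewer than
#' `min_carrier_samples` samples; step 2 then removes events longer than
#' `max_length_bp`. The counts surviving each step are reported and
#' attached as attribute `filter_report`.
#'
#' @param cnvs a [merge_events()] result.
#' @param min_carrier_samples minimum carrier count (default 10).
#' @param max_length_bp maximum event length in bp (default 5e6, the upper
#'   bound of the accepted CNV size range).
#' @return filtered `cnv_set`.
#' @export
filter_events <- function(cnvs, min_carrier_samples = 10,
                          max_length_bp = 5e6) {
  stopifnot(inherits(cnvs, "cnv_set"), min_carrier_samples >= 1,
            max_length_bp > 0)
  n0 <- nrow(cnvs$events)
  keep1 <- cnvs$events$carrier_count >= min_carrier_samples
  n1 <- sum(keep1)
  keep2 <- keep1 & cnvs$events$length_bp <= max_length_bp
  n2 <- sum(keep2)
  message(sprintf("events: %d merged -> %d after frequency filter (>= %d carriers) -> %d after length filter (<= %d bp)",
                  n0, n1, min_carrier_samples, n2, as.integer(max_length_bp)))
  out <- structure(list(events = cnvs$events[keep2, , drop = FALSE],
                        states = cnvs$states[, keep2, drop = FALSE]),
                   class = "cnv_set")
  rownames(out$events) <- NULL
  attr(out, "filter_report") <- list(merged = n0, after_frequency = n1,
                                     after_length = n2)
  out
}

#' Name CNV events by descending loss frequency
#'
#' Events are stably sorted by loss frequency, highest first, with ties
#' broken by chromosome order then start position, and named CNV1..CNVn.
#'
#' @param cnvs a `cnv_set`.
#' @return `cnv_set` with a `name` column, reordered.
#' @export
name_by_loss_frequency <- function(cnvs) {
  stopifnot(inherits(cnvs, "cnv_set"))
  ev <- cnvs$events
  o <- order(-ev$loss_freq, chromosome_order(ev$chromosome), ev$start_bp)
  ev <- ev[o, , drop = FALSE]
  ev$name <- paste0("CNV", seq_len(nrow(ev)))
  ev <- ev[, c("name", setdiff(names(ev), "name"))]
  rownames(ev) <- NULL
  states <- cnvs$states[, o, drop = FALSE]
  colnames(states) <- ev$name
  structure(list(events = ev, states = states), class = "cnv_set")
}

#' Build the CNV genotype matrix
#'
#' Copy-number dose coding for the additive association model: loss -> 0,
#' neutral -> 1, gain -> 2.
#'
#' @param cnvs a named `cnv_set` (see [name_by_loss_frequency()]).
#' @return samples x events integer matrix with values in {0, 1, 2}.
#' @export
build_genotypes <- function(cnvs) {
  stopifnot(inherits(cnvs, "cnv_set"))
  g <- matrix(1L, nrow(cnvs$states), ncol(cnvs$states),
              dimnames = dimnames(cnvs$states))
  g[cnvs$states == "loss"] <- 0L
  g[cnvs$states == "gain"] <- 2L
  g
}

#' Convert CNV events to BED (0-based, half-open)
#'
#' @param events event data.frame with `chromosome`, `start_bp`, `end_bp`
#'   (1-based inclusive) and optionally `name`.
#' @return data.frame `chrom`, `chromStart`, `chromEnd`, `name`.
#' @export
events_to_bed <- function(events) {
  data.frame(chrom = events$chromosome,
             chromStart = events$start_bp - 1L,
             chromEnd = events$end_bp,
             name = if (!is.null(events$name)) events$name
                    else paste0("CNV", seq_len(nrow(events))),
             stringsAsFactors = FALSE)
}

#' Convert BED intervals back to 1-based inclusive event coordinates
#'
#' @param bed data.frame `chrom`, `chromStart`, `chromEnd`, `name`.
#' @return data.frame `name`, `chromosome`, `start_bp`, `end_bp`.
#' @export
bed_to_events <- function(bed) {
  data.frame(name = bed$name, chromosome = bed$chrom,
             start_bp = bed$chromStart + 1L, end_bp = bed$chromEnd,
             stringsAsFactors = FALSE)
}
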
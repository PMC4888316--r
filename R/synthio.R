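#' Generate a synthetic SNP marker map
#'
#' Builds an autosome-style marker map: per chromosome, marker positions are
#' cumulative exponential spacings (mean `mean_spacing_bp`), and each marker
#' carries the GC fraction of its flanking window, modelled as a sinusoid of
#' period `gc_wave_period_bp` around 0.5 plus noise, clipped to [0.2, 0.8].
#' This emulates the long-range GC structure responsible for intensity
#' waviness on real arrays.
#'
#' @param n_chromosomes number of chromosomes (autosome labels "1", "2", ...).
#' @param markers_per_chromosome markers per chromosome.
#' @param mean_spacing_bp mean inter-marker spacing in basepairs.
#' @param gc_wave_period_bp period of the GC sinusoid in basepairs.
#' @param seed integer seed; output is a pure function of the arguments.
#' @param gc_amplitude amplitude of the GC sinusoid (default 0.15).
#' @param gc_noise_sd s.d. of marker-level GC noise (default 0.02).
#' @return data.frame with columns `marker_id`, `chromosome`, `position`
#'   (1-based), `gc_fraction`; positions strictly increasing per chromosome.
#' @export
generate_marker_map <- function(n_chromosomes, markers_per_chromosome,
                                mean_spacing_bp = 10000,
                                gc_wave_period_bp = 2e6, seed,
                                gc_amplitude = 0.15, gc_noise_sd = 0.02) {
  if (n_chromosomes < 1 || markers_per_chromosome < 1 ||
      mean_spacing_bp <= 0 || gc_wave_period_bp <= 0)
    stop("all sizes must be positive")
  with_seed(seed, {
    maps <- lapply(seq_len(n_chromosomes), function(ch) {
      gaps <- pmax(1, round(stats::rexp(markers_per_chromosome,
                                        rate = 1 / mean_spacing_bp)))
      pos <- cumsum(gaps)
      phase <- stats::runif(1, 0, 2 * pi)
      gc <- 0.5 + gc_amplitude * sin(2 * pi * pos / gc_wave_period_bp + phase) +
        stats::rnorm(markers_per_chromosome, 0, gc_noise_sd)
      data.frame(
        marker_id = sprintf("SNP_%d_%06d", ch, seq_len(markers_per_chromosome)),
        chromosome = as.character(ch),
        position = as.integer(pos),
        gc_fraction = pmin(0.8, pmax(0.2, gc)),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, maps)
  })
}

#' Describe a CNV to plant in synthetic intensity data
#'
#' @param chromosome chromosome label present in the marker map.
#' @param start_bp,end_bp 1-based inclusive span; must cover >= 3 map markers.
#' @param state `"loss"` or `"gain"`.
#' @param carrier_fraction fraction of samples carrying the event, in (0, 1].
#' @param lrr_shift expected LRR displacement in carriers; negative for loss,
#'   positive for gain. A hemizygous deletion sits near -0.55 (or -1.0 for
#'   easy benchmarks), a single-copy duplication near +0.4.
#' @param carrier_ids optional explicit carrier sample ids (overrides
#'   `carrier_fraction` sampling).
#' @return one-row data.frame usable in the `planted` argument of
#'   [generate_lrr()]; rbind several to plant several events.
#' @export
planted_cnv <- function(chromosome, start_bp, end_bp, state = c("loss", "gain"),
                        carrier_fraction, lrr_shift, carrier_ids = NULL) {
  state <- match.arg(state)
  if (end_bp < start_bp) stop("end_bp must be >= start_bp")
  if (carrier_fraction <= 0 || carrier_fraction > 1)
    stop("carrier_fraction must be in (0, 1]")
  if (state == "loss" && lrr_shift >= 0) stop("loss events need lrr_shift < 0")
  if (state == "gain" && lrr_shift <= 0) stop("gain events need lrr_shift > 0")
  out <- data.frame(chromosome = as.character(chromosome),
                    start_bp = as.integer(start_bp), end_bp = as.integer(end_bp),
                    state = state, carrier_fraction = carrier_fraction,
                    lrr_shift = lrr_shift, stringsAsFactors = FALSE)
  out$carrier_ids <- list(carrier_ids)
  out
}

#' Generate a multi-sample LRR matrix with planted CNVs
#'
#' Baseline LRR is i.i.d. Normal(0, `noise_sd`) per marker (optionally AR(1)
#' along markers via `ar_rho`). Carriers of each planted event get its
#' `lrr_shift` added over the event's markers. All samples additionally share
#' a GC wave: `gc_wave_amplitude * (gc_fraction - mean(gc_fraction))`.
#'
#' @param map marker map from [generate_marker_map()].
#' @param n_samples cohort size; samples are named "S0001", ...
#' @param planted data.frame of planted events ([planted_cnv()] rows), or NULL.
#' @param noise_sd marker-level LRR noise s.d. (> 0).
#' @param gc_wave_amplitude strength of the shared GC waviness (0 disables).
#' @param seed integer seed.
#' @param ar_rho AR(1) coefficient for marker-to-marker noise correlation
#'   (default 0, i.i.d.).
#' @return list with `intensity` (an [intensity_matrix()]) and `truth`
#'   (list with `planted_cnvs` including realised `carrier_ids`, and the
#'   per-event marker index ranges).
#' @export
generate_lrr <- function(map, n_samples, planted = NULL, noise_sd = 0.15,
                         gc_wave_amplitude = 0, seed, ar_rho = 0) {
  stopifnot(noise_sd > 0, n_samples >= 1)
  sample_ids <- sprintf("S%04d", seq_len(n_samples))
  m <- nrow(map)
  with_seed(seed, {
    lrr <- matrix(stats::rnorm(n_samples * m, 0, noise_sd),
                  nrow = n_samples, ncol = m,
                  dimnames = list(sample_ids, map$marker_id))
    if (ar_rho != 0) {
      for (ch in unique(map$chromosome)) {
        idx <- which(map$chromosome == ch)
        for (k in idx[-1])
          lrr[, k] <- ar_rho * lrr[, k - 1L] + sqrt(1 - ar_rho^2) * lrr[, k]
      }
    }
    truth_events <- NULL
    if (!is.null(planted) && nrow(planted) > 0) {
      carriers_list <- vector("list", nrow(planted))
      first_idx <- last_idx <- integer(nrow(planted))
      for (e in seq_len(nrow(planted))) {
        ev <- planted[e, ]
        idx <- which(map$chromosome == ev$chromosome &
                       map$position >= ev$start_bp & map$position <= ev$end_bp)
        if (length(idx) < 3)
          stop(sprintf("planted event %s:%d-%d covers %d map markers (>= 3 required)",
                       ev$chromosome, ev$start_bp, ev$end_bp, length(idx)))
        ids <- if (!is.null(planted$carrier_ids) &&
                   !is.null(planted$carrier_ids[[e]])) {
          bad <- setdiff(planted$carrier_ids[[e]], sample_ids)
          if (length(bad)) stop("unknown carrier ids: ", paste(bad, collapse = ", "))
          planted$carrier_ids[[e]]
        } else {
          sample(sample_ids, max(1L, round(ev$carrier_fraction * n_samples)))
        }
        lrr[ids, idx] <- lrr[ids, idx] + ev$lrr_shift
        carriers_list[[e]] <- ids
        first_idx[e] <- min(idx); last_idx[e] <- max(idx)
      }
      truth_events <- planted
      truth_events$carrier_ids <- carriers_list
      truth_events$first_marker <- first_idx
      truth_events$last_marker <- last_idx
    }
    if (gc_wave_amplitude != 0) {
      wave <- gc_wave_amplitude * (map$gc_fraction - mean(map$gc_fraction))
      lrr <- sweep(lrr, 2, wave, "+")
    }
    list(intensity = intensity_matrix(lrr, map),
         truth = list(planted_cnvs = truth_events,
                      noise_sd = noise_sd,
                      gc_wave_amplitude = gc_wave_amplitude))
  })
}

#' Generate correlated EBV-style traits with planted CNV effects
#'
#' Traits are drawn from a multivariate normal with the target correlation
#' structure (unit variances scaled by `trait_sd`), then additive genetic
#' effects `dose %*% effects` and optional per-sample stratification offsets
#' are added. Each sample x trait gets an EBV accuracy drawn uniformly in
#' `accuracy_range`, independent of the trait value (accuracy only gates
#' inclusion downstream).
#'
#' @param dose samples x loci numeric matrix of copy-number dose (e.g. the
#'   genotype coding 0/1/2), or NULL when `effects` is NULL.
#' @param trait_corr k x k positive-definite target correlation matrix.
#' @param effects loci x traits matrix of additive effects (trait units per
#'   unit dose), or NULL for a null cohort. Row/column names must match
#'   `dose` columns and `trait_names`.
#' @param stratification optional data.frame `sample_id`, `subpop`, `offset`;
#'   `offset` is added to every trait of the sample.
#' @param accuracy_range length-2 range for uniform accuracy draws.
#' @param trait_sd residual polygenic s.d. per trait (default 1).
#' @param trait_names trait labels; defaults to the nine growth traits
#'   BW, PWG, WG, CW, MW, PW, CY, MY, PY (truncated/recycled to k).
#' @param sample_ids sample ids; defaults to rownames of `dose`.
#' @param seed integer seed.
#' @return data.frame `sample_id`, then `<trait>_ebv` and `<trait>_acc`
#'   columns; the realised effect matrix is attached as attribute `effects`.
#' @export
generate_traits <- function(dose = NULL, trait_corr, effects = NULL,
                            stratification = NULL,
                            accuracy_range = c(0.3, 0.99), trait_sd = 1,
                            trait_names = NULL, sample_ids = NULL, seed) {
  k <- nrow(trait_corr)
  stopifnot(is.matrix(trait_corr), ncol(trait_corr) == k)
  ev <- eigen(trait_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) stop("trait_corr must be positive definite")
  if (is.null(trait_names)) {
    def <- c("BW", "PWG", "WG", "CW", "MW", "PW", "CY", "MY", "PY")
    trait_names <- if (k <= length(def)) def[seq_len(k)] else
      paste0("T", seq_len(k))
  }
  if (is.null(sample_ids)) {
    if (is.null(dose)) stop("provide sample_ids when dose is NULL")
    sample_ids <- rownames(dose)
  }
  n <- length(sample_ids)
  with_seed(seed, {
    y <- MASS::mvrnorm(n, mu = rep(0, k), Sigma = trait_corr) * trait_sd
    if (n == 1) y <- matrix(y, nrow = 1)
    colnames(y) <- trait_names
    if (!is.null(effects)) {
      stopifnot(!is.null(dose))
      B <- matrix(0, ncol(dose), k,
                  dimnames = list(colnames(dose), trait_names))
      B[rownames(effects), colnames(effects)] <- effects
      y <- y + dose[sample_ids, , drop = FALSE] %*% B
    }
    if (!is.null(stratification)) {
      off <- stratification$offset[match(sample_ids, stratification$sample_id)]
      if (anyNA(off)) stop("stratification is missing samples")
      y <- y + off
    }
    acc <- matrix(stats::runif(n * k, accuracy_range[1], accuracy_range[2]),
                  n, k)
    out <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
    for (j in seq_len(k)) {
      out[[paste0(trait_names[j], "_ebv")]] <- as.numeric(y[, j])
      out[[paste0(trait_names[j], "_acc")]] <- round(acc[, j], 3)
    }
    attr(out, "effects") <- effects
    out
  })
}

#' Generate synthetic gene and QTL annotation tracks
#'
#' Genes get a strand, transcript span and a sorted non-overlapping exon
#' chain; QTLs get confidence-interval spans drawn uniformly from
#' `qtl_span_range_bp` (include values above 30 Mb to exercise the CI
#' filter downstream).
#'
#' @param map marker map defining the chromosome extents.
#' @param n_genes,n_qtls number of records to draw.
#' @param qtl_span_range_bp length-2 range of QTL CI spans in bp.
#' @param seed integer seed.
#' @param gene_span_range_bp length-2 range of transcript spans.
#' @return list with `genes` (data.frame `symbol`, `chromosome`, `strand`,
#'   `tx_start`, `tx_end`, list-columns `exon_starts`, `exon_ends`, 1-based
#'   inclusive) and `qtls` (data.frame `qtl_id`, `phenotype`, `chromosome`,
#'   `ci_start`, `ci_end`).
#' @export
generate_annotations <- function(map, n_genes, n_qtls,
                                 qtl_span_range_bp = c(5e5, 4e7), seed,
                                 gene_span_range_bp = c(5e3, 2e5)) {
  chroms <- unique(map$chromosome)
  extent <- vapply(chroms, function(ch) max(map$position[map$chromosome == ch]),
                   numeric(1))
  phenos <- c("body weight", "average daily gain", "carcass weight",
              "muscling score", "marbling", "feed intake")
  with_seed(seed, {
    genes <- if (n_genes > 0) {
      ch <- sample(chroms, n_genes, replace = TRUE)
      span <- round(stats::runif(n_genes, gene_span_range_bp[1],
                                 gene_span_range_bp[2]))
      start <- vapply(seq_len(n_genes), function(i)
        sample.int(max(1L, as.integer(extent[ch[i]] - span[i])), 1L), integer(1))
      end <- start + span - 1L
      exn <- sample(1:8, n_genes, replace = TRUE)
      ex <- lapply(seq_len(n_genes), function(i) {
        k <- exn[i]
        # cut the transcript into 2k+1 blocks; odd blocks are exons
        cuts <- sort(sample(seq(start[i] + 1L, end[i] - 1L),
                            min(2L * k, end[i] - start[i] - 1L)))
        b <- unique(as.integer(c(start[i], cuts, end[i] + 1L)))
        ns <- length(b) - 1L
        keep <- seq(1L, ns, by = 2L)
        list(starts = b[keep], ends = b[keep + 1L] - 1L)
      })
      g <- data.frame(symbol = sprintf("GENE%04d", seq_len(n_genes)),
                      chromosome = as.character(ch),
                      strand = sample(c("+", "-"), n_genes, replace = TRUE),
                      tx_start = as.integer(start), tx_end = as.integer(end),
                      stringsAsFactors = FALSE)
      g$exon_starts <- lapply(ex, `[[`, "starts")
      g$exon_ends <- lapply(ex, `[[`, "ends")
      g
    } else {
      data.frame(symbol = character(), chromosome = character(),
                 strand = character(), tx_start = integer(),
                 tx_end = integer(), stringsAsFactors = FALSE)
    }
    qtls <- if (n_qtls > 0) {
      ch <- sample(chroms, n_qtls, replace = TRUE)
      span <- round(stats::runif(n_qtls, qtl_span_range_bp[1],
                                 qtl_span_range_bp[2]))
      start <- vapply(seq_len(n_qtls), function(i)
        sample.int(max(1L, as.integer(pmax(1, extent[ch[i]] - span[i]))), 1L),
        integer(1))
      data.frame(qtl_id = sprintf("QTL%04d", seq_len(n_qtls)),
                 phenotype = sample(phenos, n_qtls, replace = TRUE),
                 chromosome = as.character(ch),
                 ci_start = as.integer(start),
                 ci_end = as.integer(start + span - 1L),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(qtl_id = character(), phenotype = character(),
                 chromosome = character(), ci_start = integer(),
                 ci_end = integer(), stringsAsFactors = FALSE)
    }
    list(genes = genes, qtls = qtls)
  })
}

#' Generate a synthetic qPCR CT table from known copy numbers
#'
#' Follows the standard amplification model at efficiency 2: the expected CT
#' of a DNA target is `base_ct - log2(copies / 2)` (one cycle earlier per
#' doubling of template), plus a per-sample pipetting offset shared by all
#' of that sample's wells, plus Normal(0, `ct_noise_sd`) well noise. The
#' control target always has 2 copies.
#'
#' @param copies samples x targets integer matrix of true copy numbers
#'   (rownames sample ids, colnames target ids).
#' @param reference_sample sample id used as the calibrator; its copy number
#'   should be 2 at every target for absolute copy calls to be interpretable.
#' @param ct_noise_sd well-level CT noise s.d. in cycles.
#' @param seed integer seed.
#' @param n_replicates replicate wells per (sample, target) (default 3).
#' @param control_target id of the internal control (default "BTF3").
#' @param assay_type `"dna"` or `"rna"` recorded on every row.
#' @param base_ct nominal CT at 2 copies (default 25).
#' @return data.frame `sample_id`, `target_id`, `assay_type`, `replicate`,
#'   `ct`, with `reference_sample` and `control_target` attributes; pass
#'   straight to [ddct()].
#' @export
generate_qpcr_fixture <- function(copies, reference_sample, ct_noise_sd = 0.2,
                                  seed, n_replicates = 3,
                                  control_target = "BTF3",
                                  assay_type = "dna", base_ct = 25) {
  stopifnot(is.matrix(copies), reference_sample %in% rownames(copies),
            all(copies > 0))
  samples <- rownames(copies)
  targets <- c(colnames(copies), control_target)
  with_seed(seed, {
    sample_offset <- stats::rnorm(length(samples), 0, 0.5)
    names(sample_offset) <- samples
    rows <- expand.grid(replicate = seq_len(n_replicates),
                        target_id = targets, sample_id = samples,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    cn <- rep(2, nrow(rows))
    is_target <- rows$target_id != control_target
    cn[is_target] <- copies[cbind(rows$sample_id[is_target],
                                  rows$target_id[is_target])]
    mu <- base_ct - log2(cn / 2) + sample_offset[rows$sample_id]
    noise <- if (ct_noise_sd > 0)
      stats::rnorm(nrow(rows), 0, ct_noise_sd) else 0
    out <- data.frame(sample_id = rows$sample_id, target_id = rows$target_id,
                      assay_type = assay_type, replicate = rows$replicate,
                      ct = mu + noise, stringsAsFactors = FALSE)
    attr(out, "reference_sample") <- reference_sample
    attr(out, "control_target") <- control_target
    out
  })
}
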
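#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

.events_granges <- function(events) {
  GenomicRanges::GRanges(seqnames = events$chromosome,
                         ranges = IRanges::IRanges(events$start_bp,
                                                   events$end_bp))
}

.warn_unknown_chroms <- function(events, track, what) {
  extra <- setdiff(unique(track$chromosome), unique(events$chromosome))
  if (length(extra))
    warning(sprintf("%s on chromosome(s) %s absent from the event track; skipped",
                    what, paste(extra, collapse = ", ")))
}

.empty_report <- function() {
  data.frame(cnv = character(), partner = character(), kind = character(),
             geometry = character(), overlap_bp = integer(),
             cnv_coverage_fraction = numeric(), stringsAsFactors = FALSE)
}

#' Overlap CNV events with genes
#'
#' Every (event, gene) pair sharing at least 1 bp is reported, with the
#' geometry classified: `gene-within-cnv` if the whole transcript lies
#' inside the event; otherwise `exon-overlap` if any exon intersects it;
#' `intron-contained` if the event sits inside the gene body touching no
#' exon; else `partial`. Overlap lengths are on 1-based inclusive
#' coordinates: `min(ends) - max(starts) + 1`.
#'
#' @param events event data.frame (`name`, `chromosome`, `start_bp`,
#'   `end_bp`), e.g. `name_by_loss_frequency(...)$events`.
#' @param genes gene track as from [generate_annotations()] or
#'   [read_genepred()].
#' @return data.frame `cnv`, `partner`, `kind`, `geometry`, `overlap_bp`,
#'   `cnv_coverage_fraction`.
#' @export
overlap_genes <- function(events, genes) {
  if (nrow(events) == 0 || nrow(genes) == 0) return(.empty_report())
  .warn_unknown_chroms(events, genes, "gene(s)")
  ge <- GenomicRanges::GRanges(seqnames = genes$chromosome,
                               ranges = IRanges::IRanges(genes$tx_start,
                                                         genes$tx_end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(.events_granges(events), ge))
  if (length(hits) == 0) return(.empty_report())
  rows <- lapply(seq_along(hits), function(i) {
    e <- events[S4Vectors::queryHits(hits)[i], ]
    g <- genes[S4Vectors::subjectHits(hits)[i], ]
    ov <- min(e$end_bp, g$tx_end) - max(e$start_bp, g$tx_start) + 1L
    es <- g$exon_starts[[1]]; ee <- g$exon_ends[[1]]
    exon_hit <- any(es <= e$end_bp & ee >= e$start_bp)
    geometry <- if (g$tx_start >= e$start_bp && g$tx_end <= e$end_bp) {
      "gene-within-cnv"
    } else if (exon_hit) {
      "exon-overlap"
    } else if (e$start_bp >= g$tx_start && e$end_bp <= g$tx_end) {
      "intron-contained"
    } else "partial"
    data.frame(cnv = e$name, partner = g$symbol, kind = "gene",
               geometry = geometry, overlap_bp = ov,
               cnv_coverage_fraction = ov / (e$end_bp - e$start_bp + 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Promoter window of each gene
#'
#' The `upstream_bp` window immediately upstream of the transcription start
#' site: `[tss - upstream_bp, tss - 1]` on the + strand (clipped at 1),
#' `[tss + 1, tss + upstream_bp]` on the - strand, where the TSS is
#' `tx_start` (+) or `tx_end` (-).
#'
#' @param genes gene track.
#' @param upstream_bp window size (default 2000).
#' @return data.frame `symbol`, `chromosome`, `start_bp`, `end_bp`.
#' @export
promoter_windows <- function(genes, upstream_bp = 2000) {
  plus <- genes$strand == "+"
  tss <- ifelse(plus, genes$tx_start, genes$tx_end)
  start <- ifelse(plus, pmax(1L, tss - upstream_bp), tss + 1L)
  end <- ifelse(plus, tss - 1L, tss + upstream_bp)
  data.frame(symbol = genes$symbol, chromosome = genes$chromosome,
             start_bp = as.integer(start), end_bp = as.integer(end),
             stringsAsFactors = FALSE)[end >= start, , drop = FALSE]
}

#' Overlap CNV events with gene promoter regions
#'
#' Reports every event intersecting (>= 1 bp) the upstream promoter window
#' of a gene; gene-body overlap alone does not qualify.
#'
#' @inheritParams overlap_genes
#' @param upstream_bp promoter window size (default 2000).
#' @return overlap report (kind `"promoter"`, geometry `"promoter"`).
#' @export
overlap_promoters <- function(events, genes, upstream_bp = 2000) {
  if (nrow(events) == 0 || nrow(genes) == 0) return(.empty_report())
  pw <- promoter_windows(genes, upstream_bp)
  if (nrow(pw) == 0) return(.empty_report())
  gr <- GenomicRanges::GRanges(seqnames = pw$chromosome,
                               ranges = IRanges::IRanges(pw$start_bp,
                                                         pw$end_bp))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(.events_granges(events), gr))
  if (length(hits) == 0) return(.empty_report())
  e <- events[S4Vectors::queryHits(hits), ]
  p <- pw[S4Vectors::subjectHits(hits), ]
  ov <- pmin(e$end_bp, p$end_bp) - pmax(e$start_bp, p$start_bp) + 1L
  out <- data.frame(cnv = e$name, partner = p$symbol, kind = "promoter",
                    geometry = "promoter", overlap_bp = as.integer(ov),
                    cnv_coverage_fraction = ov / (e$end_bp - e$start_bp + 1),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Overlap CNV events with QTL confidence intervals
#'
#' QTLs whose confidence-interval span exceeds `max_ci_bp` are discarded
#' first (over-wide intervals carry no localisation). A surviving QTL is
#' reported for an event only when it alone covers at least `min_coverage`
#' of the event's length — coverage is per QTL, never unioned across QTLs.
#'
#' @param events event data.frame.
#' @param qtls QTL track (`qtl_id`, `phenotype`, `chromosome`, `ci_start`,
#'   `ci_end`).
#' @param max_ci_bp CI span ceiling (default 30 Mb).
#' @param min_coverage minimum fraction of the event covered (default 0.5).
#' @return overlap report (kind `"qtl"`, geometry `"qtl-coverage"`).
#' @export
overlap_qtls <- function(events, qtls, max_ci_bp = 3e7, min_coverage = 0.5) {
  if (nrow(events) == 0 || nrow(qtls) == 0) return(.empty_report())
  span <- qtls$ci_end - qtls$ci_start + 1
  qtls <- qtls[span <= max_ci_bp, , drop = FALSE]
  if (nrow(qtls) == 0) return(.empty_report())
  .warn_unknown_chroms(events, qtls, "QTL(s)")
  gr <- GenomicRanges::GRanges(seqnames = qtls$chromosome,
                               ranges = IRanges::IRanges(qtls$ci_start,
                                                         qtls$ci_end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(.events_granges(events), gr))
  if (length(hits) == 0) return(.empty_report())
  e <- events[S4Vectors::queryHits(hits), ]
  q <- qtls[S4Vectors::subjectHits(hits), ]
  ov <- pmin(e$end_bp, q$ci_end) - pmax(e$start_bp, q$ci_start) + 1
  frac <- ov / (e$end_bp - e$start_bp + 1)
  keep <- frac >= min_coverage
  if (!any(keep)) return(.empty_report())
  out <- data.frame(cnv = e$name[keep], partner = q$qtl_id[keep],
                    kind = "qtl", geometry = "qtl-coverage",
                    overlap_bp = as.integer(ov[keep]),
                    cnv_coverage_fraction = frac[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a genePred gene track
#'
#' Standard 10-column genePred TSV (name, chrom, strand, txStart, txEnd,
#' cdsStart, cdsEnd, exonCount, exonStarts, exonEnds; 0-based half-open),
#' converted to this package's 1-based inclusive representation.
#'
#' @param path file path.
#' @return gene track data.frame with list-columns `exon_starts`,
#'   `exon_ends`.
#' @export
read_genepred <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("name", "chrom", "strand", "txStart",
                                        "txEnd", "cdsStart", "cdsEnd",
                                        "exonCount", "exonStarts", "exonEnds"),
                          colClasses = c("character", "character", "character",
                                         "integer", "integer", "integer",
                                         "integer", "integer", "character",
                                         "character"))
  split_coords <- function(s) lapply(strsplit(s, ",", fixed = TRUE),
                                     function(v) as.integer(v[nzchar(v)]))
  out <- data.frame(symbol = df$name, chromosome = df$chrom,
                    strand = df$strand,
                    tx_start = df$txStart + 1L, tx_end = df$txEnd,
                    stringsAsFactors = FALSE)
  out$exon_starts <- lapply(split_coords(df$exonStarts), function(v) v + 1L)
  out$exon_ends <- split_coords(df$exonEnds)
  out
}

#' Write a gene track as genePred
#'
#' @param genes gene track data.frame (1-based inclusive).
#' @param path output path.
#' @export
write_genepred <- function(genes, path) {
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    es <- genes$exon_starts[[i]] - 1L
    ee <- genes$exon_ends[[i]]
    paste(genes$symbol[i], genes$chromosome[i], genes$strand[i],
          genes$tx_start[i] - 1L, genes$tx_end[i],
          genes$tx_start[i] - 1L, genes$tx_end[i],
          length(es),
          paste0(paste(es, collapse = ","), ","),
          paste0(paste(ee, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a QTL track from GFF3
#'
#' Animal-QTLdb-style GFF3: one feature per QTL with `ID` and `Name`
#' (phenotype) attributes; the feature span is the confidence interval.
#'
#' @param path file path.
#' @return QTL track data.frame.
#' @export
read_qtl_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  data.frame(qtl_id = as.character(gr$ID),
             phenotype = as.character(gr$Name),
             chromosome = as.character(GenomicRanges::seqnames(gr)),
             ci_start = GenomicRanges::start(gr),
             ci_end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Write a QTL track as GFF3
#'
#' @param qtls QTL track data.frame.
#' @param path output path.
#' @export
write_qtl_gff3 <- function(qtls, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = qtls$chromosome,
    ranges = IRanges::IRanges(qtls$ci_start, qtls$ci_end),
    ID = qtls$qtl_id, Name = qtls$phenotype)
  gr$type <- "QTL"
  gr$source <- "cnvgwas"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
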
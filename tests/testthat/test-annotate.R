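mk_gene <- function(symbol, chrom, strand, tx_start, tx_end,
                    exon_starts, exon_ends) {
  g <- data.frame(symbol = symbol, chromosome = chrom, strand = strand,
                  tx_start = tx_start, tx_end = tx_end,
                  stringsAsFactors = FALSE)
  g$exon_starts <- list(exon_starts)
  g$exon_ends <- list(exon_ends)
  g
}

mk_event <- function(name, chrom, start, end) {
  data.frame(name = name, chromosome = chrom, start_bp = start, end_bp = end,
             stringsAsFactors = FALSE)
}

test_that("gene overlap honours the 1-bp rule and classifies geometry", {
  # single-exon gene touching the event at exactly one basepair
  gene <- mk_gene("G1", "1", "+", 200L, 300L, 200L, 300L)
  ev <- mk_event("CNV1", "1", 100L, 200L)
  rep1 <- overlap_genes(ev, gene)
  expect_equal(nrow(rep1), 1)
  expect_equal(rep1$overlap_bp, 1L)
  expect_equal(rep1$overlap_bp, bp_overlap_oracle(100, 200, 200, 300))
  # disjoint: no record
  expect_equal(nrow(overlap_genes(mk_event("CNV1", "1", 100L, 200L),
                                  mk_gene("G2", "1", "+", 300L, 400L,
                                          300L, 400L))), 0)
  # event inside an intron touches no exon
  gene9 <- mk_gene("G9", "2", "+", 1000L, 9000L,
                   c(1000L, 8000L), c(1999L, 9000L))
  ev9 <- mk_event("CNV99", "2", 3000L, 4000L)
  rep9 <- overlap_genes(ev9, gene9)
  expect_equal(rep9$geometry, "intron-contained")
  # a gene wholly inside the event
  small <- mk_gene("G3", "2", "-", 3200L, 3400L, 3200L, 3400L)
  repw <- overlap_genes(ev9, small)
  expect_equal(repw$geometry, "gene-within-cnv")
  expect_equal(repw$cnv_coverage_fraction, 201 / 1001)
  # exon-crossing partial overlap at the 5' end
  repx <- overlap_genes(mk_event("CNV5", "2", 500L, 1500L), gene9)
  expect_equal(repx$geometry, "exon-overlap")
})

test_that("every emitted gene overlap matches the per-basepair oracle", {
  with_seed(91, {
    for (i in 1:25) {
      es <- sample(1:9000, 1); ee <- es + sample(50:999, 1)
      gs <- sample(1:9000, 1); ge <- gs + sample(50:999, 1)
      ev <- mk_event("CNVx", "1", es, ee)
      gn <- mk_gene("Gx", "1", "+", gs, ge, gs, ge)
      rep <- overlap_genes(ev, gn)
      ov <- bp_overlap_oracle(es, ee, gs, ge)
      if (ov == 0) {
        expect_equal(nrow(rep), 0)
      } else {
        expect_equal(rep$overlap_bp, ov)
        expect_equal(rep$cnv_coverage_fraction, ov / (ee - es + 1))
      }
    }
  })
})

test_that("promoter windows are strand-aware and exclude gene-body-only hits", {
  plus <- mk_gene("GP", "1", "+", 5000L, 8000L, 5000L, 8000L)
  expect_equal(nrow(overlap_promoters(mk_event("CNV1", "1", 3500L, 4500L),
                                      plus)), 1)     # window [3000, 4999]
  expect_equal(nrow(overlap_promoters(mk_event("CNV2", "1", 2000L, 2999L),
                                      plus)), 0)     # just upstream of window
  minus <- mk_gene("GM", "1", "-", 2000L, 5000L, 2000L, 5000L)
  expect_equal(nrow(overlap_promoters(mk_event("CNV3", "1", 5500L, 6500L),
                                      minus)), 1)    # window [5001, 7000]
  expect_equal(nrow(overlap_promoters(mk_event("CNV4", "1", 5500L, 7500L),
                                      minus))
               , 1)
  # overlap confined to the gene body yields no promoter record
  expect_equal(nrow(overlap_promoters(mk_event("CNV5", "1", 6000L, 7000L),
                                      plus)), 0)
  # window clipping at the chromosome start keeps coordinates valid
  near_start <- mk_gene("GS", "1", "+", 500L, 900L, 500L, 900L)
  w <- promoter_windows(near_start)
  expect_equal(w$start_bp, 1L)
  expect_equal(w$end_bp, 499L)
})

test_that("QTL overlap drops wide CIs and applies the 50% coverage rule", {
  qtls <- data.frame(
    qtl_id = c("Q1", "Q2", "Q3"),
    phenotype = "body weight",
    chromosome = "1",
    ci_start = c(1L, 1000L, 10000L),
    ci_end = c(31000000L, 1499L, 10489L),   # spans 31 Mb, 500 bp, 490 bp
    stringsAsFactors = FALSE)
  ev <- mk_event("CNV1", "1", 1000L, 1999L)  # 1000 bp
  rep <- overlap_qtls(ev, qtls)
  # Q1 discarded by the 30 Mb CI filter despite fully covering the event
  expect_false("Q1" %in% rep$partner)
  # Q2 covers exactly 500/1000 = 50%: emitted
  expect_true("Q2" %in% rep$partner)
  expect_equal(rep$cnv_coverage_fraction[rep$partner == "Q2"], 0.5)
  # 49% coverage: not emitted
  ev49 <- mk_event("CNV2", "1", 10000L, 10999L)
  expect_equal(nrow(overlap_qtls(ev49, qtls[3, ])), 0)
  expect_equal(bp_overlap_oracle(10000, 10999, 10000, 10489), 490)
})

test_that("overlap reports are invariant to track row order", {
  with_seed(92, {
    genes <- do.call(rbind, lapply(1:8, function(i) {
      s <- sample(1:50000, 1)
      mk_gene(paste0("G", i), "1", sample(c("+", "-"), 1), s, s + 2000L,
              s, s + 2000L)
    }))
    evs <- do.call(rbind, lapply(1:5, function(i) {
      s <- sample(1:50000, 1)
      mk_event(paste0("CNV", i), "1", s, s + 3000L)
    }))
  })
  sort_rep <- function(r) r[order(r$cnv, r$partner), , drop = FALSE]
  r1 <- sort_rep(overlap_genes(evs, genes))
  r2 <- sort_rep(overlap_genes(evs[sample(5), ], genes[sample(8), ]))
  rownames(r1) <- rownames(r2) <- NULL
  expect_equal(r1, r2)
})

test_that("BED round-tripping preserves overlap decisions", {
  evs <- rbind(mk_event("CNV1", "1", 894L, 5749L),
               mk_event("CNV2", "2", 100L, 200L))
  back <- bed_to_events(events_to_bed(evs))
  names(back)[names(back) == "chromosome"] <- "chromosome"
  gene <- mk_gene("G1", "1", "+", 5749L, 9000L, 5749L, 9000L)
  r1 <- overlap_genes(evs, gene)
  r2 <- overlap_genes(back, gene)
  expect_equal(r1, r2)
})

test_that("genePred and GFF3 tracks round-trip through their writers", {
  map <- generate_marker_map(2, 50, 20000, 1e6, seed = 93)
  ann <- generate_annotations(map, 12, 8, seed = 94)
  fg <- tempfile(fileext = ".genePred")
  write_genepred(ann$genes, fg)
  genes2 <- read_genepred(fg)
  expect_equal(genes2$symbol, ann$genes$symbol)
  expect_equal(genes2$tx_start, ann$genes$tx_start)
  expect_equal(genes2$tx_end, ann$genes$tx_end)
  expect_equal(genes2$exon_starts, ann$genes$exon_starts)
  expect_equal(genes2$exon_ends, ann$genes$exon_ends)
  fq <- tempfile(fileext = ".gff3")
  write_qtl_gff3(ann$qtls, fq)
  qtls2 <- read_qtl_gff3(fq)
  expect_equal(qtls2[order(qtls2$qtl_id), ]$ci_start,
               ann$qtls[order(ann$qtls$qtl_id), ]$ci_start)
  expect_equal(qtls2[order(qtls2$qtl_id), ]$ci_end,
               ann$qtls[order(ann$qtls$qtl_id), ]$ci_end)
})
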
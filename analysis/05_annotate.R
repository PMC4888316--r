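#!/usr/bin/env Rscript
# Stage 5: annotate the significantly associated CNVs against the gene and
# QTL tracks: >= 1 bp gene overlap with geometry classification, 2-kb
# promoter windows, and QTL confidence intervals (spans > 30 Mb discarded,
# >= 50% CNV coverage required).

suppressMessages(library(cnvgwas))

dat <- "scratch/data"
out <- "results"

events <- read.delim(file.path(out, "cnv_events.tsv"),
                     colClasses = c(chromosome = "character"))
res <- read.delim(file.path(out, "associations.tsv"))
sig_names <- unique(res$cnv[res$significant %in% TRUE])
sig <- events[events$name %in% sig_names, , drop = FALSE]

genes <- read_genepred(file.path(dat, "genes.genePred"))
qtls <- read_qtl_gff3(file.path(dat, "qtls.gff3"))

report <- rbind(overlap_genes(sig, genes),
                overlap_promoters(sig, genes, upstream_bp = 2000),
                overlap_qtls(sig, qtls, max_ci_bp = 3e7, min_coverage = 0.5))
write.table(report, file.path(out, "annotation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("annotated %d significant CNVs against %d genes and %d QTLs (%d QTLs pass the 30 Mb CI filter)\n",
            nrow(sig), nrow(genes), nrow(qtls),
            sum(qtls$ci_end - qtls$ci_start + 1 <= 3e7)))
for (k in c("gene", "promoter", "qtl"))
  cat(sprintf("  %s overlaps: %d\n", k, sum(report$kind == k)))
if (nrow(report))
  print(report[order(report$cnv), ], row.names = FALSE)
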
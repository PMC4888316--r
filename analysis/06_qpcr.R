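#!/usr/bin/env Rscript
# Stage 6: qPCR-style validation arithmetic. Five retained CNVs are
# "assayed" in nine animals: triplicate CT values are simulated from the
# true copy numbers (CT noise sd 0.2 cycles), quantified by 2^-ddCT against
# a diploid calibrator and the DNA control, called as integer copies, and
# scored for concordance against the array's three-state calls. A 12-vs-2
# copy-group comparison of expression RQs illustrates the gene-dosage ANOVA.

suppressMessages(library(cnvgwas))

dat <- "scratch/data"
out <- "results"
seed <- 20260924

events <- read.delim(file.path(out, "cnv_events.tsv"),
                     colClasses = c(chromosome = "character"))
gdf <- read.delim(file.path(out, "genotypes.tsv"), check.names = FALSE,
                  colClasses = c(sample_id = "character"))
g <- as.matrix(gdf[, -1]); rownames(g) <- gdf$sample_id

truth <- jsonlite::read_json(file.path(dat, "truth.json"),
                             simplifyVector = TRUE)
tr_ev <- truth$planted_cnvs

# pick the 5 highest-carrier retained CNVs and 9 animals, mixing carriers
# and non-carriers of the first target
targets <- events$name[order(-events$carrier_count)][1:5]
set.seed(seed + 60)
carr <- names(which(g[, targets[1]] != 1))
noncarr <- setdiff(rownames(g), carr)
samples <- c(sample(carr, 4), sample(noncarr, 5))

# true copies: map each retained CNV back to its planted event
true_copies <- matrix(2L, length(samples), length(targets),
                      dimnames = list(samples, targets))
for (j in seq_along(targets)) {
  ev <- events[events$name == targets[j], ]
  hit <- which(tr_ev$chromosome == ev$chromosome &
                 pmin(tr_ev$end_bp, ev$end_bp) -
                   pmax(tr_ev$start_bp, ev$start_bp) + 1 > 0)
  if (length(hit) == 1) {
    carriers <- truth$carriers[[hit]]
    cn <- if (tr_ev$state[hit] == "loss") 1L else 3L
    true_copies[samples %in% carriers, j] <- cn
  }
}
# calibrator: an animal diploid at all five targets
cal <- rownames(g)[rowSums(g[, targets, drop = FALSE] != 1) == 0][1]
assay <- rbind(true_copies,
               matrix(2L, 1, length(targets), dimnames = list(cal, targets)))

ct <- generate_qpcr_fixture(assay, cal, ct_noise_sd = 0.2, seed = seed + 61)
rq <- ddct_table(ct)
rq <- rq[rq$sample_id != cal, ]
write.table(rq, file.path(out, "qpcr_quantities.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

arr <- data.frame(sample_id = rep(samples, length(targets)),
                  cnv = rep(targets, each = length(samples)),
                  state = unlist(lapply(targets, function(t) {
                    s <- g[samples, t]
                    ifelse(s == 0, "loss", ifelse(s == 2, "gain", "neutral"))
                  })), stringsAsFactors = FALSE)
qp <- data.frame(sample_id = rq$sample_id, cnv = rq$target_id,
                 copies = rq$copies, stringsAsFactors = FALSE)
conc <- concordance(arr, qp)
cat(sprintf("%d qPCR reactions (%d CNVs x %d animals): concordance with array calls %.0f%%\n",
            nrow(rq), length(targets), length(samples), 100 * conc))

# expression comparison: twelve 2-copy vs two 3-copy animals, RQ ~ dosage
set.seed(seed + 62)
expr2 <- 2^rnorm(12, 0, 0.25)            # diploid expression RQs around 1
expr3 <- 1.5 * 2^rnorm(2, 0, 0.25)       # 1.5x at three copies
aov_res <- anova_copy_groups(list(cn2 = expr2, cn3 = expr3))
cat(sprintf("expression ANOVA, 12 two-copy vs 2 three-copy animals: F = %.2f, p = %.3g\n",
            aov_res$f, aov_res$p))
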
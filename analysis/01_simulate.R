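#!/usr/bin/env Rscript
# Stage 1: simulate a desk-scale cohort with known truth.
#
# 300 animals x 3 chromosomes x 400 markers (~10 kb spacing), twelve planted
# CNVs spanning the carrier-frequency range from rare (2%) to nearly fixed
# (90%), GC waviness shared across samples, and nine correlated EBV-style
# traits. Three CNVs carry additive effects on the weaning-gain /
# conformation trait cluster. Staging inputs land under scratch/data/
# together with the truth set, so later stages (and the reader) can score
# recovery; result tables go under results/.

suppressMessages(library(cnvgwas))

out <- "scratch/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260924

map <- generate_marker_map(3, 400, 10000, 2e6, seed = seed)
pos <- function(ch, i) map$position[map$chromosome == ch][i]

planted <- rbind(
  planted_cnv("1", pos("1", 40),  pos("1", 51),  "loss", 0.30, -0.55),
  planted_cnv("1", pos("1", 120), pos("1", 127), "gain", 0.10, +0.45),
  planted_cnv("1", pos("1", 210), pos("1", 229), "loss", 0.90, -0.55),
  planted_cnv("1", pos("1", 320), pos("1", 329), "loss", 0.05, -0.55),
  planted_cnv("2", pos("2", 30),  pos("2", 41),  "gain", 0.25, +0.45),
  planted_cnv("2", pos("2", 140), pos("2", 149), "loss", 0.50, -0.55),
  planted_cnv("2", pos("2", 230), pos("2", 241), "loss", 0.02, -0.55),
  planted_cnv("2", pos("2", 330), pos("2", 341), "gain", 0.40, +0.45),
  planted_cnv("3", pos("3", 50),  pos("3", 61),  "loss", 0.20, -0.55),
  planted_cnv("3", pos("3", 150), pos("3", 161), "gain", 0.15, +0.45),
  planted_cnv("3", pos("3", 250), pos("3", 261), "loss", 0.70, -0.55),
  planted_cnv("3", pos("3", 350), pos("3", 361), "loss", 0.12, -0.55))

sim <- generate_lrr(map, 300, planted, noise_sd = 0.15,
                    gc_wave_amplitude = 0.25, seed = seed + 1)
ids <- rownames(sim$intensity$lrr)
truth <- sim$truth$planted_cnvs

# true genotype dose per planted event: loss carriers 0, gain carriers 2
dose <- matrix(1, length(ids), nrow(truth),
               dimnames = list(ids, paste0("ev", seq_len(nrow(truth)))))
for (e in seq_len(nrow(truth))) {
  dose[ids %in% truth$carrier_ids[[e]], e] <-
    if (truth$state[e] == "loss") 0 else 2
}

# nine growth traits from a two-factor model (overall size + muscling),
# which reproduces the qualitative correlation structure of such cohorts:
# weak BW links, a tight weaning-gain/conformation cluster, CPM traits
# strongly inter-correlated. Factor loadings per trait:
traits9 <- c("BW", "PWG", "WG", "CW", "MW", "PW", "CY", "MY", "PY")
L <- rbind(
  size     = c(0.25, 0.55, 0.85, 0.80, 0.55, 0.55, 0.75, 0.55, 0.55),
  muscling = c(0.05, 0.10, 0.15, 0.25, 0.70, 0.70, 0.30, 0.72, 0.72))
corr <- t(L) %*% L
diag(corr) <- 1
dimnames(corr) <- list(traits9, traits9)

effects <- matrix(0, nrow(truth), 9,
                  dimnames = list(colnames(dose), traits9))
effects["ev1", c("WG", "CW", "CY")] <- c(0.45, 0.40, 0.35)   # common loss
effects["ev6", c("MW", "MY", "PW", "PY")] <- 0.40            # CPM cluster
effects["ev5", "WG"] <- 0.35                                  # gain event

tt <- generate_traits(dose, corr, effects, trait_names = traits9,
                      accuracy_range = c(0.35, 0.99), seed = seed + 2)

ann <- generate_annotations(map, 60, 30, qtl_span_range_bp = c(2e5, 4e7),
                            seed = seed + 3)

write_marker_map(map, file.path(out, "marker_map.tsv"))
write_lrr_matrix(sim$intensity, file.path(out, "lrr_matrix.tsv"))
write.table(tt, file.path(out, "traits.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write_genepred(ann$genes, file.path(out, "genes.genePred"))
write_qtl_gff3(ann$qtls, file.path(out, "qtls.gff3"))

truth_out <- truth[c("chromosome", "start_bp", "end_bp", "state",
                     "carrier_fraction", "lrr_shift")]
truth_out$n_carriers <- lengths(truth$carrier_ids)
jsonlite::write_json(
  list(planted_cnvs = truth_out,
       carriers = lapply(truth$carrier_ids, identity),
       effects = as.data.frame(effects)),
  file.path(out, "truth.json"), pretty = TRUE, digits = NA)

cat(sprintf("simulated %d samples x %d markers, %d planted CNVs (carrier counts %s)\n",
            length(ids), nrow(map), nrow(truth),
            paste(truth_out$n_carriers, collapse = "/")))
cat("inputs written under", out, "\n")
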
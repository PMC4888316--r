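# A small but complete cohort: 2 chromosomes x 150 markers, 40 samples,
# two planted common CNVs (one per chromosome), GC waviness, three
# correlated traits with additive effects of both events, gene/QTL tracks.
build_run_inputs <- function(dir, seed = 7) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  map <- generate_marker_map(2, 150, 10000, 2e6, seed = seed)
  p1 <- map$position[map$chromosome == "1"]
  p2 <- map$position[map$chromosome == "2"]
  pl <- rbind(
    planted_cnv("1", p1[60], p1[71], "loss", 0.3, -1.0),
    planted_cnv("2", p2[100], p2[111], "gain", 0.25, 1.0))
  sim <- generate_lrr(map, 40, pl, noise_sd = 0.15,
                      gc_wave_amplitude = 0.2, seed = seed + 1)
  ids <- rownames(sim$intensity$lrr)
  # true dose coding per event (loss carriers 0, gain carriers 2, else 1)
  dose <- matrix(1, length(ids), 2,
                 dimnames = list(ids, c("ev1", "ev2")))
  dose[ids %in% sim$truth$planted_cnvs$carrier_ids[[1]], 1] <- 0
  dose[ids %in% sim$truth$planted_cnvs$carrier_ids[[2]], 2] <- 2
  corr <- matrix(c(1, 0.6, 0.2, 0.6, 1, 0.2, 0.2, 0.2, 1), 3)
  eff <- matrix(c(1.5, 0, 0, 1.5, 0, 0), 2, 3,
                dimnames = list(c("ev1", "ev2"), c("WG", "CW", "BW")))
  tt <- generate_traits(dose, corr, eff, trait_names = c("WG", "CW", "BW"),
                        accuracy_range = c(0.55, 0.99), trait_sd = 0.5,
                        seed = seed + 2)
  ann <- generate_annotations(map, 25, 12, qtl_span_range_bp = c(1e5, 4e7),
                              seed = seed + 3)
  write_marker_map(map, file.path(dir, "map.tsv"))
  write_lrr_matrix(sim$intensity, file.path(dir, "lrr.tsv"))
  write.table(tt, file.path(dir, "traits.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_genepred(ann$genes, file.path(dir, "genes.genePred"))
  write_qtl_gff3(ann$qtls, file.path(dir, "qtls.gff3"))
  list(dir = dir, truth = sim$truth, map = map)
}

run_cfg <- function(inp, out_dir, seed = 11) {
  pipeline_config(
    marker_map = file.path(inp$dir, "map.tsv"),
    lrr_matrix = file.path(inp$dir, "lrr.tsv"),
    traits = file.path(inp$dir, "traits.tsv"),
    genes = file.path(inp$dir, "genes.genePred"),
    qtls = file.path(inp$dir, "qtls.gff3"),
    out_dir = out_dir,
    min_carrier_samples = 5, n_permutations = 300, k_pcs = 0, seed = seed)
}
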
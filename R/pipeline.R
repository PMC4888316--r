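#' Pipeline configuration
#'
#' Bundles every input path and threshold of the end-to-end CNV association
#' workflow. Defaults are the workflow's canonical settings: minimum 10
#' carrier samples, 5 Mb maximum event length, EBV accuracy > 0.5, 10
#' genotype PCs, 10,000 permutations, FDR alpha 0.05, 2 kb promoter
#' windows, 30 Mb QTL CI ceiling and 50% QTL coverage.
#'
#' @param marker_map path to the marker map TSV.
#' @param lrr_matrix path to the LRR matrix TSV.
#' @param traits path to the trait table TSV.
#' @param out_dir run directory (created if needed).
#' @param lrr_dialect `"matrix"` or `"long"`.
#' @param genes optional genePred path.
#' @param qtls optional QTL GFF3 path.
#' @param allowed_chromosomes chromosomes to keep; NULL = all in the map.
#' @param segmentation a [segmentation_params()].
#' @param min_carrier_samples,max_length_bp event filters.
#' @param traits_to_test trait names; NULL = every trait in the table.
#' @param min_accuracy,k_pcs,n_permutations,alpha,seed association settings.
#' @param upstream_bp,max_ci_bp,min_coverage annotation settings.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(marker_map, lrr_matrix, traits, out_dir,
                            lrr_dialect = "matrix", genes = NULL, qtls = NULL,
                            allowed_chromosomes = NULL,
                            segmentation = segmentation_params(),
                            min_carrier_samples = 10, max_length_bp = 5e6,
                            traits_to_test = NULL, min_accuracy = 0.5,
                            k_pcs = 10, n_permutations = 10000, alpha = 0.05,
                            seed = 1, upstream_bp = 2000, max_ci_bp = 3e7,
                            min_coverage = 0.5) {
  stopifnot(min_carrier_samples >= 1, max_length_bp > 0, k_pcs >= 0,
            n_permutations >= 100, alpha > 0, alpha < 1, upstream_bp > 0,
            max_ci_bp > 0, min_coverage > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the CNV association pipeline end to end
#'
#' Stages: preprocess (read, autosome restriction, imputation, GC
#' correction) -> segment -> callset (merge, filter, name, genotypes) ->
#' assoc (per trait, PC-corrected permutation association) -> annotate
#' (significant events vs genes, promoters, QTLs). Every stage writes its
#' artifacts into the run directory; a JSON manifest records inputs
#' (md5 checksums), thresholds, seed and per-stage record counts, and
#' `summary.txt` gives a human-readable recap. Stages communicate only via
#' these files, so any stage can be re-run from its on-disk inputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  stages <- character()
  fail <- function(stage, e)
    stop(sprintf("stage '%s' failed (%s); partial outputs in %s",
                 stage, conditionMessage(e), config$out_dir), call. = FALSE)

  # -- preprocess ------------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("cnvgwas")),
    seed = config$seed,
    inputs = lapply(Filter(Negate(is.null),
                           list(marker_map = config$marker_map,
                                lrr_matrix = config$lrr_matrix,
                                traits = config$traits, genes = config$genes,
                                qtls = config$qtls)),
                    function(p) unname(tools::md5sum(p))),
    thresholds = list(
      segmentation = unclass(config$segmentation),
      min_carrier_samples = config$min_carrier_samples,
      max_length_bp = config$max_length_bp,
      min_accuracy = config$min_accuracy, k_pcs = config$k_pcs,
      n_permutations = config$n_permutations, alpha = config$alpha,
      upstream_bp = config$upstream_bp, max_ci_bp = config$max_ci_bp,
      min_coverage = config$min_coverage))
  counts <- list()
  m <- tryCatch({
    map <- read_marker_map(config$marker_map)
    m <- read_lrr_matrix(config$lrr_matrix, map, config$lrr_dialect)
    allowed <- config$allowed_chromosomes
    if (is.null(allowed)) allowed <- unique(map$chromosome)
    m <- restrict_to_autosomes(m, allowed)
    m <- impute_missing(m)
    m <- gc_correct(m)
    write_lrr_matrix(m, out("lrr_corrected.tsv"))
    write_marker_map(m$map, out("marker_map_used.tsv"))
    m
  }, error = function(e) fail("preprocess", e))
  counts$markers_used <- ncol(m$lrr); counts$samples <- nrow(m$lrr)
  stages <- c(stages, "preprocess")
  message("stage preprocess done: ", counts$samples, " samples x ",
          counts$markers_used, " markers")

  # -- segment ---------------------------------------------------------------
  calls <- tryCatch({
    segs <- segment_multivariate(m, config$segmentation)
    .write_tsv(segs, out("segments.tsv"))
    calls <- call_states(segs, m, config$segmentation$state_threshold)
    .write_tsv(data.frame(sample_id = rownames(calls$states),
                          calls$states, check.names = FALSE),
               out("state_calls.tsv"))
    calls
  }, error = function(e) fail("segment", e))
  counts$segments <- nrow(calls$segments)
  stages <- c(stages, "segment")
  message("stage segment done: ", counts$segments, " segments")

  # -- callset ---------------------------------------------------------------
  cnvs <- tryCatch({
    cnvs <- merge_events(calls)
    counts$merged_events <- nrow(cnvs$events)
    cnvs <- filter_events(cnvs, config$min_carrier_samples,
                          config$max_length_bp)
    cnvs <- name_by_loss_frequency(cnvs)
    .write_tsv(cnvs$events, out("cnv_events.tsv"))
    .write_tsv(events_to_bed(cnvs$events), out("cnv_events.bed"))
    g <- build_genotypes(cnvs)
    .write_tsv(data.frame(sample_id = rownames(g), g, check.names = FALSE),
               out("genotypes.tsv"))
    cnvs
  }, error = function(e) fail("callset", e))
  counts$retained_events <- nrow(cnvs$events)
  stages <- c(stages, "callset")
  message("stage callset done: ", counts$retained_events, " retained events")

  # -- assoc -----------------------------------------------------------------
  assoc_all <- tryCatch({
    g <- build_genotypes(cnvs)
    tt <- utils::read.delim(config$traits, stringsAsFactors = FALSE,
                            colClasses = c(sample_id = "character"))
    traits_run <- config$traits_to_test
    if (is.null(traits_run)) traits_run <- trait_names(tt)
    .write_tsv(as.data.frame(trait_correlations(tt)),
               out("trait_correlations.tsv"))
    k <- min(config$k_pcs, min(dim(g)) - 1)
    pcs <- if (k >= 1 && ncol(g) > 1) compute_pcs(g, k) else NULL
    res <- lapply(seq_along(traits_run), function(i) {
      a <- associate(g, tt, traits_run[i], pcs,
                     n_permutations = config$n_permutations,
                     seed = config$seed + i, alpha = config$alpha,
                     min_accuracy = config$min_accuracy)
      pos <- match(a$cnv, cnvs$events$name)
      a$chromosome <- cnvs$events$chromosome[pos]
      a$start_bp <- cnvs$events$start_bp[pos]
      a$neg_log10_p <- -log10(a$p_perm)
      .write_tsv(a, out(paste0("assoc_", traits_run[i], ".tsv")))
      a
    })
    assoc_all <- do.call(rbind, res)
    .write_tsv(assoc_all, out("associations.tsv"))
    assoc_all
  }, error = function(e) fail("assoc", e))
  counts$significant_associations <- sum(assoc_all$significant, na.rm = TRUE)
  counts$significant_cnvs <-
    length(unique(assoc_all$cnv[assoc_all$significant %in% TRUE]))
  stages <- c(stages, "assoc")
  message("stage assoc done: ", counts$significant_associations,
          " significant associations over ", counts$significant_cnvs, " CNVs")

  # -- annotate --------------------------------------------------------------
  tryCatch({
    sig <- cnvs$events[cnvs$events$name %in%
                         assoc_all$cnv[assoc_all$significant %in% TRUE], ,
                       drop = FALSE]
    rep_rows <- .empty_report()
    if (!is.null(config$genes)) {
      genes <- read_genepred(config$genes)
      rep_rows <- rbind(rep_rows, overlap_genes(sig, genes),
                        overlap_promoters(sig, genes, config$upstream_bp))
    }
    if (!is.null(config$qtls)) {
      qtls <- read_qtl_gff3(config$qtls)
      rep_rows <- rbind(rep_rows,
                        overlap_qtls(sig, qtls, config$max_ci_bp,
                                     config$min_coverage))
    }
    .write_tsv(rep_rows, out("annotation.tsv"))
    counts$annotation_records <- nrow(rep_rows)
  }, error = function(e) fail("annotate", e))
  stages <- c(stages, "annotate")
  message("stage annotate done: ", counts$annotation_records, " records")

  manifest$stages <- stages
  manifest$counts <- counts
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  writeLines(c(
    sprintf("samples: %d, markers used: %d", counts$samples,
            counts$markers_used),
    sprintf("segments: %d; merged events: %d; retained events: %d",
            counts$segments, counts$merged_events, counts$retained_events),
    sprintf("significant associations: %d over %d CNVs (alpha %.2f, FDR)",
            counts$significant_associations, counts$significant_cnvs,
            config$alpha),
    sprintf("annotation records: %d", counts$annotation_records)),
    out("summary.txt"))
  invisible(manifest)
}
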
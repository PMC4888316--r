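#' Construct an intensity matrix
#'
#' Container for a samples x markers Log R Ratio (LRR) matrix tied to its
#' marker map. Columns must appear in map order; values may be NA (masked
#' missing entries).
#'
#' @param lrr numeric matrix, rownames sample ids, colnames marker ids.
#' @param map marker map data.frame (`marker_id`, `chromosome`, `position`,
#'   `gc_fraction`); positions must be strictly increasing per chromosome.
#' @param corrected has GC correction been applied already?
#' @return object of class `intensity_matrix`.
#' @export
intensity_matrix <- function(lrr, map, corrected = FALSE) {
  stopifnot(is.matrix(lrr), !is.null(rownames(lrr)), !is.null(colnames(lrr)))
  req <- c("marker_id", "chromosome", "position", "gc_fraction")
  if (!all(req %in% names(map)))
    stop("map needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(map$marker_id)) stop("duplicate marker_id in map")
  if (anyDuplicated(rownames(lrr)))
    stop("duplicate sample id: ",
         paste(unique(rownames(lrr)[duplicated(rownames(lrr))]), collapse = ", "))
  unknown <- setdiff(colnames(lrr), map$marker_id)
  if (length(unknown))
    stop("markers absent from the map: ",
         paste(utils::head(unknown, 10), collapse = ", "))
  map <- map[match(colnames(lrr), map$marker_id), , drop = FALSE]
  rownames(map) <- NULL
  for (ch in unique(map$chromosome)) {
    p <- map$position[map$chromosome == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  structure(list(lrr = lrr, map = map, corrected = corrected),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix: %d samples x %d markers on %d chromosome(s)%s\n",
              nrow(x$lrr), ncol(x$lrr), length(unique(x$map$chromosome)),
              if (x$corrected) " [GC-corrected]" else ""))
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$lrr)

#' Read a marker map TSV
#'
#' Columns: `marker_id`, `chromosome`, `position`, `gc_fraction`.
#'
#' @param path file path.
#' @return marker map data.frame.
#' @export
read_marker_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(marker_id = "character",
                                          chromosome = "character"))
  if (any(map$gc_fraction < 0 | map$gc_fraction > 1))
    stop("gc_fraction outside [0, 1]")
  map
}

#' Write a marker map TSV
#' @param map marker map data.frame.
#' @param path output path.
#' @export
write_marker_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an LRR matrix TSV
#'
#' Two dialects: `"matrix"` (header `sample_id` then one column per marker,
#' one row per sample — a transposed GenomeStudio-style export) and `"long"`
#' (columns `sample_id`, `marker_id`, `lrr`, one row per call, pivoted on
#' read). Missing entries stay NA. A duplicated sample (matrix dialect) or
#' duplicated (sample, marker) pair (long dialect) is an error naming the
#' offender; markers absent from `map` are an error listing them.
#'
#' @param path file path.
#' @param map marker map the matrix must be keyed to.
#' @param dialect `"matrix"` or `"long"`.
#' @param corrected set TRUE when the file holds already-GC-corrected LRR.
#' @return an [intensity_matrix()].
#' @export
read_lrr_matrix <- function(path, map, dialect = c("matrix", "long"),
                            corrected = FALSE) {
  dialect <- match.arg(dialect)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1L)
    stop(sprintf("ragged TSV: line %d has %d fields, expected %d",
                 which(nf != nf[1])[1], nf[nf != nf[1]][1], nf[1]))
  if (dialect == "matrix") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                            colClasses = c(sample_id = "character"))
    if (names(df)[1] != "sample_id") stop("matrix dialect needs a 'sample_id' first column")
    if (anyDuplicated(df$sample_id))
      stop("duplicate sample id: ",
           paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
    lrr <- as.matrix(df[, -1, drop = FALSE])
    rownames(lrr) <- df$sample_id
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = c(sample_id = "character",
                                           marker_id = "character"))
    dup <- duplicated(df[c("sample_id", "marker_id")])
    if (any(dup))
      stop("duplicate (sample, marker) pair: ",
           paste(df$sample_id[dup][1], df$marker_id[dup][1]))
    samples <- unique(df$sample_id)
    markers <- intersect(map$marker_id, unique(df$marker_id))
    lrr <- matrix(NA_real_, length(samples), length(markers),
                  dimnames = list(samples, markers))
    bad <- setdiff(unique(df$marker_id), map$marker_id)
    if (length(bad))
      stop("markers absent from the map: ",
           paste(utils::head(bad, 10), collapse = ", "))
    lrr[cbind(df$sample_id, df$marker_id)] <- df$lrr
  }
  intensity_matrix(lrr, map, corrected)
}

#' Write an LRR matrix TSV (matrix dialect)
#' @param m an [intensity_matrix()].
#' @param path output path.
#' @export
write_lrr_matrix <- function(m, path) {
  df <- data.frame(sample_id = rownames(m$lrr), m$lrr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict an intensity matrix to a chromosome set
#'
#' Drops markers outside `allowed_chromosomes` (the autosomes, typically)
#' and reports the retained count and percentage; the percentage is attached
#' as attribute `retention_pct`.
#'
#' @param m an [intensity_matrix()].
#' @param allowed_chromosomes character vector of chromosome labels to keep;
#'   default `as.character(1:29)`, the bovine autosomes.
#' @return filtered [intensity_matrix()].
#' @export
restrict_to_autosomes <- function(m, allowed_chromosomes = as.character(1:29)) {
  stopifnot(inherits(m, "intensity_matrix"), length(allowed_chromosomes) > 0)
  keep <- m$map$chromosome %in% allowed_chromosomes
  if (!any(keep)) stop("no markers on the allowed chromosomes")
  pct <- retention_percentage(sum(keep), length(keep))
  message(sprintf("retained %d of %d markers (%.2f%%) on allowed chromosomes",
                  sum(keep), length(keep), pct))
  out <- intensity_matrix(m$lrr[, keep, drop = FALSE],
                          m$map[keep, , drop = FALSE], m$corrected)
  attr(out, "retention_pct") <- pct
  out
}

#' Remove GC-content waviness from LRR
#'
#' Per sample, ordinary least squares of LRR on the marker GC fraction is
#' fitted and the fitted component removed; each sample's mean LRR is
#' preserved exactly (only the centred GC term is subtracted). Missing
#' entries are ignored in the fit and left missing. The operation is
#' idempotent: the residuals are GC-orthogonal, so a second pass fits a
#' zero slope.
#'
#' @param m an [intensity_matrix()], not yet corrected.
#' @return corrected [intensity_matrix()] (`corrected = TRUE`).
#' @export
gc_correct <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (m$corrected) stop("matrix is already GC-corrected")
  gc <- m$map$gc_fraction
  if (stats::sd(gc) == 0) {
    warning("gc_fraction is constant; GC correction is a no-op")
    return(intensity_matrix(m$lrr, m$map, corrected = TRUE))
  }
  gcc <- gc - mean(gc)
  lrr <- m$lrr
  if (anyNA(lrr)) {
    slopes <- apply(lrr, 1, function(x) {
      ok <- !is.na(x)
      g <- gc[ok] - mean(gc[ok])
      sum(g * (x[ok] - mean(x[ok]))) / sum(g * g)
    })
    adj <- outer(slopes, gcc)
    lrr <- lrr - adj
  } else {
    varg <- sum(gcc * gcc)
    slopes <- as.numeric(lrr %*% gcc) / varg  # rowMeans cancel against centred gc
    lrr <- lrr - outer(slopes, gcc)
  }
  intensity_matrix(lrr, m$map, corrected = TRUE)
}

#' Mean-impute missing LRR entries per marker
#'
#' Segmentation needs a dense matrix; missing calls are replaced by the
#' marker's cross-sample mean (0 if a whole marker is missing), with the
#' imputed count reported.
#'
#' @param m an [intensity_matrix()].
#' @return dense [intensity_matrix()].
#' @export
impute_missing <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  lrr <- m$lrr
  nmiss <- sum(is.na(lrr))
  if (nmiss > 0) {
    mu <- colMeans(lrr, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(lrr), arr.ind = TRUE)
    lrr[idx] <- mu[idx[, 2]]
    message(sprintf("imputed %d missing LRR entries with marker means", nmiss))
  }
  intensity_matrix(lrr, m$map, m$corrected)
}
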
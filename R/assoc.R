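#' Samples passing the EBV accuracy gate for a trait
#'
#' Estimated breeding values are analysed only for animals whose EBV
#' accuracy (square root of reliability) strictly exceeds the threshold and
#' whose EBV is present.
#'
#' @param traits trait table: `sample_id`, then `<trait>_ebv`, `<trait>_acc`
#'   per trait.
#' @param trait trait name, e.g. `"WG"`.
#' @param min_accuracy accuracy threshold (default 0.5; strict inequality).
#' @return character vector of retained sample ids.
#' @export
filter_by_accuracy <- function(traits, trait, min_accuracy = 0.5) {
  ecol <- paste0(trait, "_ebv"); acol <- paste0(trait, "_acc")
  if (!all(c(ecol, acol) %in% names(traits)))
    stop("trait not found in table: ", trait)
  keep <- !is.na(traits[[ecol]]) & !is.na(traits[[acol]]) &
    traits[[acol]] > min_accuracy
  if (!any(keep))
    stop("no samples pass the accuracy gate for trait ", trait)
  traits$sample_id[keep]
}

#' Trait names present in a trait table
#' @param traits trait table.
#' @return character vector of trait names.
#' @export
trait_names <- function(traits) {
  sub("_ebv$", "", grep("_ebv$", names(traits), value = TRUE))
}

#' Pairwise Pearson correlations between traits
#'
#' Computed on samples complete for all traits (listwise deletion), the way
#' a genetic-correlation screen across breeding values is usually
#' summarised. A zero-variance trait yields NA correlations with a warning.
#'
#' @param traits trait table.
#' @param complete_cases_only drop samples missing any trait (default TRUE).
#' @return k x k symmetric correlation matrix with unit diagonal.
#' @export
trait_correlations <- function(traits, complete_cases_only = TRUE) {
  tn <- trait_names(traits)
  y <- as.matrix(traits[paste0(tn, "_ebv")])
  colnames(y) <- tn
  if (complete_cases_only) y <- y[stats::complete.cases(y), , drop = FALSE]
  if (nrow(y) < 3) stop("need at least 3 complete-case samples")
  sds <- apply(y, 2, stats::sd)
  if (any(sds == 0))
    warning("zero-variance trait(s): ", paste(tn[sds == 0], collapse = ", "),
            "; correlations reported as NA")
  r <- suppressWarnings(stats::cor(y))
  r[sds == 0, ] <- NA; r[, sds == 0] <- NA
  diag(r) <- ifelse(sds == 0, NA, 1)
  r
}

#' Principal components of the CNV genotype matrix
#'
#' Columns are centred and unit-scaled (zero-variance columns dropped with
#' a warning), then the top-`k` left singular directions, scaled by their
#' singular values, are returned as per-sample scores. Signs follow a
#' deterministic convention: each component's largest-magnitude loading is
#' made positive.
#'
#' @param g samples x events genotype matrix.
#' @param k number of components; must satisfy 0 < k < min(dim(g)).
#' @return samples x k score matrix (columns PC1..PCk).
#' @export
compute_pcs <- function(g, k) {
  if (k <= 0) stop("k must be positive")
  sds <- apply(g, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d zero-variance column(s) before PCA",
                    sum(sds == 0)))
    g <- g[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (k >= min(dim(g)))
    stop("k must be smaller than min(n_samples, n_events)")
  z <- scale(g, center = TRUE, scale = sds)
  sv <- svd(z, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)],
                                                            k, k),
                  2, flip, "*")
  dimnames(scores) <- list(rownames(g), paste0("PC", seq_len(k)))
  scores
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values `q_(i) = min_{j>=i} p_(j) * m / j`, capped at 1,
#' returned in the input order.
#'
#' @param p p-values in (0, 1].
#' @return q-values, same length and order.
#' @export
fdr_adjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' CNV-trait association with PC correction and permutation p-values
#'
#' For each CNV event j separately, the trait's EBV is regressed on an
#' intercept, the supplied principal-component scores, and the event's
#' additive genotype dose x_j; the t-statistic of x_j is the test
#' statistic. Permutation p-values use the Freedman-Lane scheme: the EBV is
#' regressed on the covariates alone, its residuals are permuted (one
#' shared permutation stream, fixed by `seed`, reused across events so the
#' genome-wide null preserves the between-event correlation), the full
#' model is refit, and
#' `p = (1 + #[|t_null| >= |t_obs|]) / (1 + n_permutations)`; two-sided.
#' Benjamini-Hochberg FDR is then applied across events for this trait.
#'
#' @param g samples x events genotype matrix ({0,1,2}).
#' @param traits trait table.
#' @param trait trait name to analyse.
#' @param pcs samples x k PC score matrix (rownames sample ids), or NULL
#'   for no stratification correction.
#' @param n_permutations number of permutations (>= 100; default 10000).
#' @param seed integer seed for the permutation stream.
#' @param alpha FDR significance level (default 0.05).
#' @param min_accuracy EBV accuracy gate (default 0.5).
#' @return data.frame with one row per event: `cnv`, `trait`, `n_used`,
#'   `beta_hat`, `se`, `t_stat`, `p_asym` (asymptotic, diagnostic),
#'   `p_perm`, `q_fdr`, `significant`, `zero_variance`.
#' @export
associate <- function(g, traits, trait, pcs = NULL, n_permutations = 10000,
                      seed, alpha = 0.05, min_accuracy = 0.5) {
  stopifnot(n_permutations >= 100, alpha > 0, alpha < 1)
  ids <- filter_by_accuracy(traits, trait, min_accuracy)
  ids <- intersect(rownames(g), ids)
  if (!is.null(pcs)) ids <- intersect(ids, rownames(pcs))
  n <- length(ids)
  y <- traits[[paste0(trait, "_ebv")]][match(ids, traits$sample_id)]
  X <- g[ids, , drop = FALSE]
  Z <- cbind(intercept = rep(1, n),
             if (!is.null(pcs)) pcs[ids, , drop = FALSE])
  qrZ <- qr(Z)
  if (qrZ$rank < ncol(Z)) {
    bad <- colnames(Z)[setdiff(seq_len(ncol(Z)), qrZ$pivot[seq_len(qrZ$rank)])]
    stop("collinear covariate columns: ", paste(bad, collapse = ", "))
  }
  df <- n - ncol(Z) - 1L
  if (df < 1) stop("not enough samples for the design")
  yr <- qr.resid(qrZ, y)
  Xr <- qr.resid(qrZ, X)
  xx <- colSums(Xr * Xr)
  zero_var <- apply(X, 2, stats::sd) == 0 | xx < 1e-12
  xx[zero_var] <- NA
  num <- as.numeric(crossprod(Xr, yr))
  beta <- num / xx
  rss_y <- sum(yr * yr)
  sigma2 <- (rss_y - num^2 / xx) / df
  se <- sqrt(sigma2 / xx)
  tobs <- beta / se
  p_asym <- 2 * stats::pt(-abs(tobs), df)
  # permutation null: t for all events under each permuted residual vector
  exceed <- integer(ncol(X))
  with_seed(seed, {
    done <- 0L
    while (done < n_permutations) {
      b <- min(1000L, n_permutations - done)
      P <- vapply(seq_len(b), function(i) yr[sample.int(n)], numeric(n))
      # residual permutations already lie in Z's residual space only up to
      # the permutation; re-project so each column is a valid null response
      PR <- qr.resid(qrZ, P)
      numn <- crossprod(Xr, PR)                      # events x b
      rssn <- colSums(PR * PR)                       # b
      s2 <- (matrix(rssn, ncol(X), b, byrow = TRUE) - numn^2 / xx) / df
      tn <- (numn / xx) / sqrt(s2 / xx)
      exceed <- exceed + rowSums(abs(tn) >= abs(tobs), na.rm = TRUE)
      done <- done + b
    }
  })
  p_perm <- (1 + exceed) / (1 + n_permutations)
  p_perm[zero_var] <- NA
  q <- rep(NA_real_, length(p_perm))
  q[!zero_var] <- fdr_adjust(p_perm[!zero_var])
  out <- data.frame(
    cnv = colnames(g), trait = trait, n_used = n,
    beta_hat = beta, se = se, t_stat = tobs, p_asym = p_asym,
    p_perm = p_perm, q_fdr = q,
    significant = !is.na(q) & q < alpha,
    zero_variance = zero_var,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
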
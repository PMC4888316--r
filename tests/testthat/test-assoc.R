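test_that("the accuracy gate is strict and drops missing EBVs", {
  tt <- data.frame(sample_id = c("A", "B", "C", "D"),
                   WG_ebv = c(1, 2, 3, NA), WG_acc = c(0.4, 0.5, 0.6, 0.8),
                   stringsAsFactors = FALSE)
  expect_equal(filter_by_accuracy(tt, "WG", 0.5), "C")
  tt$WG_acc <- 0.9
  expect_equal(filter_by_accuracy(tt, "WG"), c("A", "B", "C"))
  expect_error(filter_by_accuracy(tt, "CW"), "CW")
  tt$WG_acc <- 0.1
  expect_error(filter_by_accuracy(tt, "WG"), "accuracy")
})

test_that("trait correlations match closed forms and the MVN generator", {
  tt <- data.frame(sample_id = c("A", "B", "C"),
                   BW_ebv = c(1, 2, 3), BW_acc = 0.9,
                   WG_ebv = c(3, 2, 1), WG_acc = 0.9,
                   stringsAsFactors = FALSE)
  r <- trait_correlations(tt)
  expect_equal(r["BW", "WG"], -1)
  expect_equal(diag(r), c(BW = 1, WG = 1))
  # the strong weaning-gain / conformation correlation regime, n = 2013
  target <- matrix(c(1, 0.8, 0.8, 1), 2)
  big <- generate_traits(trait_corr = target, trait_names = c("WG", "CW"),
                         sample_ids = sprintf("S%04d", 1:2013), seed = 55)
  r2 <- trait_correlations(big)
  expect_true(r2["WG", "CW"] >= 0.77 && r2["WG", "CW"] <= 0.83)
  # zero-variance trait is flagged, not silently propagated
  tt$BW_ebv <- 5
  expect_warning(r3 <- trait_correlations(tt), "zero-variance")
  expect_true(is.na(r3["BW", "WG"]))
})

test_that("genotype PCs reproduce a dense eigendecomposition", {
  with_seed(61, {
    g <- matrix(sample(0:2, 200, replace = TRUE), 20, 10,
                dimnames = list(sprintf("S%02d", 1:20), paste0("E", 1:10)))
  })
  scores <- compute_pcs(g, 5)
  z <- scale(g)
  eig <- eigen(crossprod(z), symmetric = TRUE)
  for (j in 1:5) {
    oracle <- z %*% eig$vectors[, j]
    # same subspace and scale, up to sign
    expect_lt(min(sum((scores[, j] - oracle)^2),
                  sum((scores[, j] + oracle)^2)), 1e-16 * sum(oracle^2) + 1e-8)
  }
  # deterministic sign convention
  expect_identical(scores, compute_pcs(g, 5))
  # rank-1 matrix: PC1 carries all the variance
  g1 <- outer(c(0:4, 0:4) / 2, c(2, 4, 6))
  dimnames(g1) <- list(sprintf("S%02d", 1:10), paste0("E", 1:3))
  s1 <- compute_pcs(g1 + 1, 2)
  expect_gt(sum(s1[, 1]^2) / (sum(s1^2)), 1 - 1e-10)
  expect_error(compute_pcs(g, 0), "positive")
  expect_error(compute_pcs(g, 10), "smaller")
})

test_that("PC1 separates planted subpopulations", {
  sg <- stratified_genotypes(seed = 62)
  pcs <- compute_pcs(sg$g, 2)
  r <- cor(pcs[, 1], as.numeric(sg$subpop == "B"))
  expect_gt(abs(r), 0.9)
})

test_that("BH adjustment matches hand computation and an independent oracle", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(1), 1)
  expect_error(fdr_adjust(c(0.5, 0)), "\\(0, 1\\]")
  with_seed(63, {
    for (i in 1:100) {
      p <- runif(sample(3:40, 1))^sample(1:3, 1)
      q <- fdr_adjust(p)
      expect_equal(q, bh_oracle(p))
      o <- order(p)
      expect_true(all(diff(q[o]) >= -1e-15))
      expect_true(all(q <= 1))
    }
  })
})

test_that("association recovers a planted effect and is seed-reproducible", {
  with_seed(71, {
    n <- 400
    ids <- sprintf("S%04d", 1:n)
    g <- matrix(1L, n, 25, dimnames = list(ids, paste0("CNV", 1:25)))
    for (j in 1:25) g[runif(n) < 0.3, j] <- sample(c(0L, 2L), 1)
    y <- 0.8 * g[, 7] + rnorm(n)
  })
  tt <- as_trait_table(ids, y, "MW")
  res <- associate(g, tt, "MW", pcs = NULL, n_permutations = 1000, seed = 72)
  hit <- res[res$cnv == "CNV7", ]
  expect_true(hit$significant)
  expect_true(hit$beta_hat >= 0.6 && hit$beta_hat <= 1.0)
  expect_true(all(res$p_perm >= 1 / 1001))
  # bit-reproducible under the same seed
  res2 <- associate(g, tt, "MW", pcs = NULL, n_permutations = 1000, seed = 72)
  expect_identical(res, res2)
})

test_that("zero-variance genotype columns are flagged, not tested", {
  with_seed(73, {
    ids <- sprintf("S%03d", 1:100)
    g <- cbind(CNV1 = rep(1L, 100),
               CNV2 = sample(0:2, 100, replace = TRUE))
    rownames(g) <- ids
    y <- rnorm(100)
  })
  tt <- as_trait_table(ids, y, "PY")
  res <- associate(g, tt, "PY", NULL, n_permutations = 200, seed = 74)
  expect_true(res$zero_variance[res$cnv == "CNV1"])
  expect_true(is.na(res$p_perm[res$cnv == "CNV1"]))
  expect_false(is.na(res$p_perm[res$cnv == "CNV2"]))
})

test_that("detection rate rises monotonically with the planted effect size", {
  rates <- vapply(c(0.2, 0.5, 1.0), function(beta) {
    found <- 0L
    for (seed in 1:20) {
      with_seed(800 + seed, {
        n <- 150
        ids <- sprintf("S%03d", seq_len(n))
        x <- ifelse(runif(n) < 0.3, 0L, 1L)
        g <- cbind(CNV1 = x)
        rownames(g) <- ids
        y <- beta * x + rnorm(n)
      })
      tt <- as_trait_table(ids, y, "CY")
      res <- associate(g, tt, "CY", NULL, n_permutations = 200,
                       seed = 900 + seed)
      found <- found + res$significant[1]
    }
    found / 20
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], rates[1])
})

test_that("correlated traits sharing a causal CNV flag it for both", {
  with_seed(81, {
    n <- 500
    ids <- sprintf("S%04d", 1:n)
    g <- matrix(1L, n, 10, dimnames = list(ids, paste0("CNV", 1:10)))
    for (j in 1:10) g[runif(n) < 0.3, j] <- 0L
  })
  target <- matrix(c(1, 0.9, 0.9, 1), 2)
  eff <- matrix(c(0.8, 0.8), 1, 2, dimnames = list("CNV3", c("MW", "MY")))
  tt <- generate_traits(g, target, eff, trait_names = c("MW", "MY"),
                        accuracy_range = c(0.6, 0.99), seed = 82)
  hits <- lapply(c("MW", "MY"), function(tr) {
    res <- associate(g, tt, tr, NULL, n_permutations = 500, seed = 83)
    res$cnv[res$significant]
  })
  expect_true("CNV3" %in% hits[[1]])
  expect_true("CNV3" %in% hits[[2]])
})
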
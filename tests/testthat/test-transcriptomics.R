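mk_expr <- function(nGenes, nRoi, seed) {
  set.seed(seed)
  matrix(rnorm(nGenes * nRoi), nGenes, nRoi,
    dimnames = list(sprintf("GENE%03d", seq_len(nGenes)),
      as.character(seq_len(nRoi))))
}

test_that("PLS1 recovers a planted spatial gene and its variance share", {
  n_roi <- 100L
  expr <- mk_expr(10L, n_roi, 901L)
  set.seed(902)
  map <- rnorm(n_roi)
  expr["GENE007", ] <- 3 * map
  fit <- plsrSpatial(map, expr)
  expect_identical(names(which.max(abs(fit$gene_weights))), "GENE007")
  expect_gt(fit$var_explained_pls1, 0.9)
  expect_identical(rankGenes(fit)$gene[1L],
    names(sort(fit$gene_weights, decreasing = TRUE))[1L])
})

test_that("in the noise-free rank-1 limit PLS1 equals the univariate fit", {
  n_roi <- 30L
  set.seed(910)
  map <- rnorm(n_roi)
  ortho <- residuals(lm(rnorm(n_roi) ~ map)) # second gene, orthogonal to map
  expr <- rbind(sig = 2 * map + 1, other = ortho)
  colnames(expr) <- as.character(seq_len(n_roi))
  fit <- plsrSpatial(map, expr)
  expect_equal(fit$var_explained_pls1, 1, tolerance = 1e-8)
  # component-1 scores reproduce the centered response up to scale
  expect_equal(abs(cor(fit$pls1_roi_scores, map)), 1, tolerance = 1e-8)
})

test_that("a map orthogonal to every gene explains almost nothing", {
  n_roi <- 100L
  expr <- mk_expr(50L, n_roi, 920L)
  set.seed(921)
  raw <- rnorm(n_roi)
  # orthogonalize against the standardized gene span, keep a tiny residual
  x <- scale(t(expr))
  ortho <- residuals(lm(raw ~ x))
  map <- ortho + 0.01 * rnorm(n_roi)
  fit <- plsrSpatial(map, expr)
  expect_lt(fit$var_explained_pls1, 0.05)
})

test_that("PLS is invariant to gene order and per-gene affine rescaling", {
  n_roi <- 40L
  expr <- mk_expr(20L, n_roi, 930L)
  set.seed(931)
  map <- rnorm(n_roi)
  f1 <- plsrSpatial(map, expr)
  perm <- sample.int(nrow(expr))
  f2 <- plsrSpatial(map, expr[perm, ])
  expect_equal(f2$gene_weights[names(f1$gene_weights)], f1$gene_weights,
    tolerance = 1e-10)
  rescaled <- expr
  rescaled[3L, ] <- 100 + 7 * rescaled[3L, ]
  f3 <- plsrSpatial(map, rescaled)
  expect_equal(f3$var_explained_pls1, f1$var_explained_pls1, tolerance = 1e-10)
  expect_equal(f3$gene_weights, f1$gene_weights, tolerance = 1e-10)

  expect_error(plsrSpatial(rep(1, n_roi), expr), "constant")
  expect_error(plsrSpatial(map[1:10], expr), "must equal ROI count")
})

test_that("PLS agrees with an established PLS implementation on component 1", {
  skip_if_not_installed("mixOmics")
  n_roi <- 50L
  expr <- mk_expr(15L, n_roi, 940L)
  set.seed(941)
  map <- rnorm(n_roi) + 0.8 * expr[2L, ]
  fit <- plsrSpatial(map, expr)
  ref <- mixOmics::pls(scale(t(expr)), map, ncomp = 1L, scale = FALSE,
    mode = "regression")
  w_ref <- ref$loadings$X[, 1L]
  # weights are defined up to a global sign
  s <- sign(sum(w_ref * fit$gene_weights))
  expect_equal(unname(fit$gene_weights), unname(s * w_ref), tolerance = 1e-6)
})

test_that("permutation p-values detect planted signal and respect the plus-one bound", {
  n_roi <- 60L
  expr <- mk_expr(30L, n_roi, 950L)
  set.seed(951)
  map <- rnorm(n_roi)
  expr["GENE004", ] <- 2 * map + 0.3 * rnorm(n_roi)
  pt <- permutationTestPls(map, expr, nPerm = 999L, seed = 5L)
  expect_lte(pt$perm_p, 0.01)
  expect_gte(pt$perm_p, 1 / 1000)

  pt_small <- permutationTestPls(map, expr, nPerm = 99L, seed = 5L)
  expect_gte(pt_small$perm_p, 1 / 100)
  expect_error(permutationTestPls(map, expr, nPerm = 50L), "at least 99")
})

test_that("gene ranking is deterministic, sign-symmetric and tie-stable", {
  n_roi <- 40L
  expr <- mk_expr(12L, n_roi, 960L)
  set.seed(961)
  map <- rnorm(n_roi)
  fit <- plsrSpatial(map, expr)
  fit_neg <- plsrSpatial(-map, expr)
  expect_equal(fit_neg$gene_weights, -fit$gene_weights, tolerance = 1e-10)
  expect_identical(rankGenes(fit)$gene, rev(rankGenes(fit_neg)$gene))

  tied <- fit
  tied$gene_weights[] <- 0.5
  expect_identical(rankGenes(tied)$gene, sort(names(fit$gene_weights)))
})

test_that("the running-sum enrichment score matches a brute-force oracle exactly", {
  set.seed(970)
  for (rep in 1:5) {
    n <- 20L
    scores <- sort(rnorm(n), decreasing = TRUE)
    names(scores) <- sprintf("G%02d", sample.int(99L, n))
    set_genes <- sample(names(scores), 6L)
    got <- connGradients:::.gseaES(scores, names(scores) %in% set_genes)
    expect_equal(got$es, gseaOracle(scores, set_genes), tolerance = 1e-12)
  }
})

test_that("enrichment score agrees with the fgsea statistic", {
  skip_if_not_installed("fgsea")
  set.seed(980)
  n <- 50L
  scores <- sort(rnorm(n), decreasing = TRUE)
  names(scores) <- sprintf("G%02d", seq_len(n))
  set_genes <- sample(names(scores), 10L)
  got <- connGradients:::.gseaES(scores, names(scores) %in% set_genes)
  ref <- fgsea::calcGseaStat(stats = scores,
    selectedStats = which(names(scores) %in% set_genes), gseaParam = 1)
  expect_equal(got$es, ref, tolerance = 1e-6)
})

test_that("gsea flags concentrated sets, zeroes the all-gene set, and sizes correctly", {
  set.seed(990)
  n <- 500L
  scores <- sort(rnorm(n, sd = 2), decreasing = TRUE)
  names(scores) <- sprintf("GENE%04d", seq_len(n))
  sets <- list(
    top = names(scores)[1:20],
    everything = names(scores),
    tiny = names(scores)[3:4],
    missing = c("NOPE1", "NOPE2", "NOPE3")
  )
  expect_warning(res <- gsea(rankGenes(structure(
    list(gene_weights = scores), class = "plsResult")), sets,
    nPerm = 199L, seed = 3L, maxSize = 400L), "no genes")
  expect_identical(res$set, "top") # size bounds drop tiny and everything
  expect_gt(res$es, 0)
  expect_lte(res$p, 0.01)
  expect_gt(res$nes, 1)

  res_all <- gsea(scores, list(everything = names(scores)),
    nPerm = 99L, seed = 3L, minSize = 1L, maxSize = 1000L)
  expect_equal(res_all$es, 0)
})

test_that("the planted expression gene set is recovered at FDR < 0.05", {
  atlas <- tinyAtlas(60L)
  sc <- scenarioConfig(nRoi = 60L, nGenes = 200L, nSignalGenes = 20L)
  recovered <- logical(8L)
  for (s in seq_len(8L)) {
    set.seed(1000L + s)
    map <- rnorm(60L)
    ex <- generateExpression(atlas, sc, map, seed = 1000L + s)
    fit <- plsrSpatial(map, ex$expr)
    res <- gsea(rankGenes(fit), ex$gene_sets, nPerm = 199L, seed = s)
    # the planted signal concentrates at one extreme of the ranking; the
    # enrichment sign depends on the PLS1 global sign, so judge by q only
    recovered[s] <- nrow(res) == 1L && res$q < 0.05
  }
  expect_gte(mean(recovered), 0.9)
})
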
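test_that("atlas generation respects community counts and is deterministic", {
  a7 <- generateAtlas(7L, seed = 1L)
  expect_identical(nrow(a7), 7L)
  expect_identical(sort(table(a7$community)), sort(table(a7$community)))
  expect_true(all(table(a7$community) == 1L))

  a <- generateAtlas(100L, seed = 1L)
  b <- generateAtlas(100L, seed = 1L)
  expect_identical(a, b)
  expect_false(identical(a, generateAtlas(100L, seed = 2L)))
  expect_error(generateAtlas(5L, seed = 1L), "at least the number of communities")
  # contiguous community blocks
  expect_identical(a$community, a$community[order(match(a$community, unique(a$community)))])
})

test_that("noise-free scans with parallel loadings correlate perfectly", {
  atlas <- tinyAtlas(10L)
  u <- c(0.5, 0.5, seq(-0.9, 0.9, length.out = 8L))
  v <- c(0.3, 0.3, seq(0.9, -0.9, length.out = 8L))
  sc <- scenarioConfig(nRoi = 10L, nTimepoints = 30L, noiseSd = 0,
    loadingSd = 0, targetRoi = 5L, latentAxes = list(u = u, v = v))
  ts <- generateTimeSeries(atlas, sc, seed = 3L)
  fc <- connValues(computeFC(ts))
  expect_equal(fc[1L, 2L], 1, tolerance = 1e-12)

  bad <- scenarioConfig(nRoi = 10L, targetRoi = 5L,
    latentAxes = list(u = rep(0, 10L), v = rep(0, 10L)))
  expect_error(generateTimeSeries(atlas, bad, seed = 1L), "degenerate")
  long <- scenarioConfig(nRoi = 10L, targetRoi = 5L,
    latentAxes = list(u = rep(1, 9L), v = rep(0, 9L)))
  expect_error(generateTimeSeries(atlas, long, seed = 1L), "match the atlas")
})

test_that("the recovered template gradients track the planted axes", {
  atlas <- defaultAtlas()
  ax <- latentAxes(atlas)
  tmpl <- defaultTemplate()
  s <- gradientScores(tmpl)
  expect_gt(abs(cor(s[, 1L], ax$u, method = "spearman")), 0.9)
  expect_gt(abs(cor(s[, 2L], ax$v, method = "spearman")), 0.9)
  # both primary gradients lie in the planted plane
  cc <- cancor(s[, 1:2], cbind(ax$u, ax$v))$cor
  expect_gt(min(cc), 0.95)
  # the two leading axes dominate the embedding: together they carry many
  # times the uniform per-component share (the absolute fraction is capped
  # well below the ~69% seen on real data by the 10% profile sparsity of
  # the default chain; see the methods vignette)
  ve <- varianceExplained(tmpl)
  expect_gt(sum(ve[1:2]), 0.3)
  expect_gt(sum(ve[1:2]), 10 * 2 / (nrow(atlas) - 1))
})

test_that("the planted group effect is detectable with high power", {
  atlas <- defaultAtlas()
  sc <- scenarioConfig()
  target <- connGradients:::resolveTargetRoi(atlas, sc)
  tmpl <- defaultTemplate()
  g2_at_target <- function(seed, affected) {
    emb <- procrustesAlign(pcaEmbedding(affinityFromTimeSeries(
      generateTimeSeries(atlas, sc, affected = affected, seed = seed)), k = 10L),
      tmpl)
    gradientScores(emb)[target, 2L]
  }
  n_rep <- 100L
  pvals <- numeric(n_rep)
  effects <- numeric(n_rep)
  for (rep in seq_len(n_rep)) {
    ga <- vapply(1:16, function(s) g2_at_target(rep * 200L + s, TRUE), numeric(1L))
    gb <- vapply(1:16, function(s) g2_at_target(rep * 200L + 100L + s, FALSE),
      numeric(1L))
    ht <- t.test(ga, gb)
    pvals[rep] <- ht$p.value
    effects[rep] <- mean(ga) - mean(gb)
  }
  expect_gt(mean(pvals < 0.05), 0.8)
  # the planted loading decrease shifts the aligned G2 in the direction
  # given by the template's (sign-conventional) orientation toward v
  ax <- latentAxes(atlas)
  orientation <- sign(cor(gradientScores(tmpl)[, 2L], ax$v))
  expect_lt(orientation * mean(effects), 0)
})

test_that("cohort generation matches the configured prevalences and record invariants", {
  atlas <- defaultAtlas()
  sc <- scenarioConfig()
  co <- generateCohort(atlas, sc, seed = 11L)
  r <- co$records
  expect_identical(sum(r$session == "pre" & r$tinnitus), 18L)
  expect_identical(sum(r$session == "post" & r$tinnitus), 21L)
  expect_equal(100 * 18 / 32, 56.25)
  expect_equal(100 * 21 / 32, 65.625)
  # VAS present iff tinnitus; HC never has tinnitus
  expect_identical(is.na(r$vas), !r$tinnitus)
  expect_false(any(r$tinnitus[r$group %in% c("HC", "REF")]))
  # THI items only take 0/2/4 and scores are consistent
  items <- as.matrix(r[, sprintf("thi%02d", 1:25)])
  expect_true(all(items %in% c(0L, 2L, 4L)))
  expect_identical(r$thi_score[r$tinnitus],
    as.integer(rowSums(items[r$tinnitus, ])))
  expect_identical(r$thi_level, thiLevel(r$thi_score))

  co2 <- generateCohort(atlas, sc, seed = 11L)
  expect_identical(co$records, co2$records)
  expect_equal(co$timeseries, co2$timeseries)
})

test_that("cohort files written to disk round-trip byte-identically across reruns", {
  atlas <- tinyAtlas(20L)
  sc <- scenarioConfig(nRoi = 20L, nPatients = 4L, nControls = 3L,
    nReference = 3L, prevalencePre = 2L, prevalencePost = 3L,
    targetRoi = 5L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generateCohort(atlas, sc, seed = 9L, writeDir = d1)
  generateCohort(atlas, sc, seed = 9L, writeDir = d2)
  expect_identical(readLines(file.path(d1, "cohort.csv")),
    readLines(file.path(d2, "cohort.csv")))
  f <- list.files(d1, pattern = "tsv$")[1L]
  expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("clinical coupling is absent at zero and grows with the coefficient", {
  atlas <- defaultAtlas()
  # null: among tinnitus cases (the planted shift plus a zero THI make the
  # pooled patient set structurally correlated even without coupling),
  # severity decouples from the loading; the 95% envelope of a null
  # Spearman rho at n cases is qnorm(0.975)/sqrt(n - 1)
  rhos0 <- vapply(1:20, function(s) {
    sc <- scenarioConfig(coupling = 0)
    co <- generateCohort(atlas, sc, seed = 3000L + s)
    vs <- co$records[co$records$group == "VS" & co$records$tinnitus, ]
    spearmanAssoc(vs$target_loading, vs$thi_score)$rho /
      (qnorm(0.975) / sqrt(nrow(vs) - 1))
  }, numeric(1L))
  expect_gte(mean(abs(rhos0) < 1), 17 / 20)

  mean_abs_rho <- vapply(c(0, 1.5, 3), function(cp) {
    mean(vapply(1:6, function(s) {
      co <- generateCohort(atlas, scenarioConfig(coupling = cp),
        seed = 4000L + s)
      vs <- co$records[co$records$group == "VS" & co$records$tinnitus, ]
      abs(spearmanAssoc(vs$target_loading, vs$thi_score)$rho)
    }, numeric(1L)))
  }, numeric(1L))
  expect_true(all(diff(mean_abs_rho) > 0))
})

test_that("expression generation plants recoverable signal genes deterministically", {
  atlas <- tinyAtlas(50L)
  sc <- scenarioConfig(nRoi = 50L, nGenes = 100L, nSignalGenes = 10L)
  set.seed(42)
  map <- rnorm(50L)
  ex1 <- generateExpression(atlas, sc, map, seed = 6L)
  ex2 <- generateExpression(atlas, sc, map, seed = 6L)
  expect_identical(ex1$expr, ex2$expr)
  expect_length(ex1$signal_genes, 10L)

  # noise-free single signal gene ranks first in PLS1 weight
  sc1 <- scenarioConfig(nRoi = 50L, nGenes = 50L, nSignalGenes = 1L)
  ex <- generateExpression(atlas, sc1, map, seed = 7L, noiseSd = 1)
  ex$expr[ex$signal_genes, ] <- 5 * as.numeric(scale(map)) # noise-free limit
  fit <- plsrSpatial(map, ex$expr)
  expect_identical(rankGenes(fit)$gene[
    which.max(abs(rankGenes(fit)$weight))], ex$signal_genes)

  expect_error(generateExpression(atlas, sc1, map[1:10], seed = 1L),
    "must equal atlas size")
})
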
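test_that("bhFdr reproduces the step-up adjustment computed by hand", {
  # min over the tail of p * m / rank: all four collapse to 0.04
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4L))
  expect_equal(bhFdr(rep(0.2, 5L)), rep(0.2, 5L))
  expect_equal(bhFdr(0.37), 0.37)
  expect_error(bhFdr(numeric(0)), "empty")
  expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")

  # hand-rolled step-up oracle on random vectors
  set.seed(123)
  for (rep in 1:5) {
    p <- runif(20L)
    m <- length(p)
    ord <- order(p)
    q_oracle <- numeric(m)
    running <- 1
    for (i in m:1) {
      running <- min(running, p[ord[i]] * m / i)
      q_oracle[ord[i]] <- running
    }
    expect_equal(bhFdr(p), q_oracle, tolerance = 1e-12)
  }
})

test_that("roiGroupTest reproduces hand-computed t statistics and trivial cases", {
  # Welch t on [1,2,3] vs [4,5,6]: (2-5)/sqrt(1/3 + 1/3) = -3.674, df = 4
  a <- matrix(c(1, 2, 3), 3L, 2L)
  b <- matrix(c(4, 5, 6), 3L, 2L)
  colnames(a) <- colnames(b) <- c("1", "2")
  res <- roiGroupTest(a, b, dim = 1L)
  expect_equal(res$t, rep(-3 / sqrt(2 / 3), 2L), tolerance = 1e-10)
  expect_equal(res$t, rep(-3.674, 2L), tolerance = 1e-3)
  expect_equal(res$p, rep(2 * pt(-3 / sqrt(2 / 3), df = 4), 2L),
    tolerance = 1e-10)

  # identical paired groups: t = 0, p = 1
  res0 <- roiGroupTest(a, a, dim = 1L, paired = TRUE)
  expect_equal(res0$t, c(0, 0))
  expect_equal(res0$p, c(1, 1))
  expect_false(any(res0$significant))

  expect_error(roiGroupTest(a[1L, , drop = FALSE], b, dim = 1L), "at least 2")
  expect_error(roiGroupTest(a, b[1:2, ], dim = 1L, paired = TRUE),
    "equal group sizes")
})

test_that("paired and unpaired tests agree in sign on the same data", {
  set.seed(99)
  for (rep in 1:10) {
    a <- matrix(rnorm(40L), 8L, 5L, dimnames = list(NULL, as.character(1:5)))
    b <- matrix(rnorm(40L, 0.5), 8L, 5L, dimnames = list(NULL, as.character(1:5)))
    tu <- roiGroupTest(a, b, dim = 3L)$t
    tp <- roiGroupTest(a, b, dim = 3L, paired = TRUE)$t
    expect_true(all(sign(tu) == sign(tp) | tu == 0 | tp == 0))
  }
})

test_that("the planted gradient effect is detected at the target ROI and only there", {
  atlas <- defaultAtlas()
  sc <- scenarioConfig()
  target <- connGradients:::resolveTargetRoi(atlas, sc)
  tmpl <- defaultTemplate()
  embed <- function(seed, affected) {
    procrustesAlign(pcaEmbedding(affinityFromTimeSeries(
      generateTimeSeries(atlas, sc, affected = affected, seed = seed)), k = 10L),
      tmpl)
  }
  n_rep <- 10L
  hits <- logical(n_rep)
  false_flags <- integer(n_rep)
  for (rep in seq_len(n_rep)) {
    ga <- lapply(1:16, function(s) embed(rep * 1000L + s, TRUE))
    gb <- lapply(1:16, function(s) embed(rep * 1000L + 500L + s, FALSE))
    res <- roiGroupTest(ga, gb, dim = 2L)
    hits[rep] <- res$significant[res$roi_id == as.character(target)]
    false_flags[rep] <- sum(res$significant[res$roi_id != as.character(target)])
  }
  expect_gte(mean(hits), 0.8)
  # false positives stay within FDR expectations (q < 0.05 family of 99)
  expect_lte(mean(false_flags), 0.05 * nrow(atlas))
})

test_that("seedDistanceTest matches row-restricted full testing and composes communities", {
  atlas <- tinyAtlas(10L)
  set.seed(71)
  mk <- function(shift) {
    lapply(1:6, function(s) {
      emb <- pcaEmbedding(randomAffinity(10L, seed = 200L + s + shift), k = 3L)
      emb@aligned <- TRUE
      emb@referenceId <- "t"
      emb
    })
  }
  ga <- mk(0L)
  gb <- mk(50L)
  prof <- seedDistanceTest(3L, ga, gb, atlas)
  # identical groups: nothing altered
  none <- seedDistanceTest(3L, ga, ga, atlas, paired = TRUE)
  expect_identical(none$altered_count, 0L)
  expect_length(none$community_composition, 0L)

  # q-values equal the seed row of the manual per-target distance tests
  da <- t(sapply(ga, function(e) gradientDistance(e)[3L, ]))
  db <- t(sapply(gb, function(e) gradientDistance(e)[3L, ]))
  manual_p <- sapply(setdiff(1:10, 3L), function(j) {
    t.test(da[, j], db[, j])$p.value
  })
  expect_equal(prof$tests$p, manual_p, tolerance = 1e-12)
  expect_equal(prof$tests$q, bhFdr(manual_p), tolerance = 1e-12)
  expect_error(seedDistanceTest(99L, ga, gb, atlas), "not in atlas")
})

test_that("community composition reproduces published fraction arithmetic", {
  # a 40-ROI atlas in which 25 of the 39 altered targets sit in the DMN
  atlas <- validateAtlas(data.frame(
    roi_id = 1:40,
    roi_name = sprintf("R%02d", 1:40),
    community = rep(c("Vis", "DMN", "FP"), c(5L, 25L, 10L)),
    hemisphere = rep(c("L", "R"), 20L),
    x = as.numeric(1:40), y = 0, z = 0
  ))
  dmn <- atlas$roi_id[atlas$community == "DMN"]
  # seed ROI 1 plus 14 non-DMN targets stay; all 25 DMN + 14 others altered
  altered <- c(dmn, setdiff(atlas$roi_id, c(dmn, 1L))[1:14])
  n_case <- 8L
  base <- matrix(rnorm(n_case * 40L, 10, 0.1), n_case, 40L)
  shifted <- base
  shifted[, altered] <- shifted[, altered] + 5
  prof <- seedDistanceTest(1L, shifted, base, atlas)
  expect_identical(prof$altered_count, 39L)
  expect_equal(unname(prof$community_composition[["DMN"]]),
    sum(altered %in% dmn) / 39, tolerance = 1e-12)
  expect_equal(sum(prof$community_composition), 1, tolerance = 1e-12)
  expect_equal(round(sum(altered %in% dmn) / 39, 3), 0.641)
})

test_that("spearmanAssoc handles monotone, reversed and tied data", {
  x <- c(1, 3, 5, 7, 11)
  expect_equal(spearmanAssoc(x, x^3)$rho, 1)
  expect_equal(spearmanAssoc(x, -x)$rho, -1)
  expect_equal(spearmanAssoc(x, x^3)$p, 0)

  # tie handling against the direct average-rank formula
  f <- c(1, 2, 2, 3, 4)
  m <- c(1, 2, 3, 3, 5)
  got <- spearmanAssoc(f, m)
  rho_oracle <- cor(rank(f), rank(m)) # average ranks by definition
  expect_equal(got$rho, rho_oracle, tolerance = 1e-12)
  t_oracle <- rho_oracle * sqrt(3 / (1 - rho_oracle^2))
  expect_equal(got$p, 2 * pt(-abs(t_oracle), df = 3), tolerance = 1e-12)
  # agreement with the established implementation's estimate
  expect_equal(got$rho,
    suppressWarnings(cor.test(f, m, method = "spearman"))$estimate[[1L]],
    tolerance = 1e-12)

  expect_error(spearmanAssoc(rep(1, 6L), 1:6), "constant")
  expect_error(spearmanAssoc(1:4, 1:4), "at least 5")
})

test_that("BH-FDR keeps the false-flag fraction at the nominal level under the null", {
  set.seed(2024)
  n_cohort <- 200L
  frac <- numeric(n_cohort)
  for (i in seq_len(n_cohort)) {
    a <- matrix(rnorm(10L * 50L), 10L, 50L, dimnames = list(NULL, as.character(1:50)))
    b <- matrix(rnorm(10L * 50L), 10L, 50L, dimnames = list(NULL, as.character(1:50)))
    res <- roiGroupTest(a, b, dim = 1L, alpha = 0.05)
    frac[i] <- mean(res$significant)
  }
  # mean flagged fraction is bounded by alpha up to binomial error
  expect_lte(mean(frac), 0.05 + 2 * sd(frac) / sqrt(n_cohort))
})
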
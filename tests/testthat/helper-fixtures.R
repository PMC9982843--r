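# Shared fixtures, built lazily once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# small well-formed atlas
tinyAtlas <- function(n = 10L) {
  generateAtlas(n, seed = 1L)
}

defaultAtlas <- function() {
  fixture("atlas100", function() generateAtlas(100L, seed = 1L))
}

# reference template at the default scenario (32 held-out scans), reused by
# recovery and power tests
defaultTemplate <- function() {
  fixture("template", function() {
    atlas <- defaultAtlas()
    sc <- scenarioConfig()
    conns <- lapply(1:32, function(s) {
      computeFC(generateTimeSeries(atlas, sc, affected = FALSE, seed = 90000L + s))
    })
    buildTemplate(conns, k = 10L, templateId = "ref32")
  })
}

# random symmetric matrix with unit diagonal, |off-diagonal| < 1
randomAffinity <- function(n, seed) {
  set.seed(seed)
  m <- matrix(runif(n * n, -0.5, 0.9), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(as.character(1:n), as.character(1:n))
  m
}

randomOrthogonal <- function(k, seed, reflection = FALSE) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(k * k), k, k)))
  if (reflection && det(q) > 0) q[, 1L] <- -q[, 1L]
  if (!reflection && det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# exhaustive two-sided Fisher oracle: enumerate all tables with the observed
# margins, sum hypergeometric point probabilities <= observed * (1 + 1e-7)
fisherEnumOracle <- function(tab) {
  r1 <- sum(tab[1L, ]); r2 <- sum(tab[2L, ])
  c1 <- sum(tab[, 1L])
  p_obs <- stats::dhyper(tab[1L, 1L], r1, r2, c1)
  a_range <- max(0L, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(a_range, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# plain running-sum GSEA enrichment oracle (direct position loop)
gseaOracle <- function(scores, setGenes, exponent = 1) {
  genes <- names(scores)
  n <- length(genes)
  nh <- sum(genes %in% setGenes)
  nr <- sum(abs(scores[genes %in% setGenes])^exponent)
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (genes[i] %in% setGenes) {
      run <- run + abs(scores[[i]])^exponent / nr
    } else {
      run <- run - 1 / (n - nh)
    }
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}
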
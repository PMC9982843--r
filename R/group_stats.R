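#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment (monotonized, capped at 1) of a vector of
#' p-values; a thin, validating wrapper around \code{stats::p.adjust}.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return q-values, same length and order.
#' @export
bhFdr <- function(pvals) {
  if (length(pvals) == 0L) stop("empty p-value vector")
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1] with no missing values")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' ROI-wise group comparison of gradient scores
#'
#' For each ROI, compares one gradient component between two groups of
#' aligned embeddings with a two-sample t-test — Welch by default for
#' independent groups, or a paired t-test for matched pre/post designs —
#' and adjusts the N p-values of that component with BH-FDR (the FDR family
#' is the N ROIs of one component, matching per-component reporting).
#'
#' @param groupA,groupB lists of aligned \code{GradientEmbedding}s; for
#'   \code{paired = TRUE} they must be matched in subject order and length.
#' @param dim gradient component index to test.
#' @param paired paired t-test instead of two-sample.
#' @param alpha FDR level defining the \code{significant} flag.
#' @param varEqual use the pooled-variance Student test instead of Welch
#'   (independent tests only).
#' @return data frame with one row per ROI: \code{roi_id}, \code{dim},
#'   \code{t}, \code{p}, \code{q}, \code{significant}.
#' @export
roiGroupTest <- function(groupA, groupB, dim = 1L, paired = FALSE,
                         alpha = 0.05, varEqual = FALSE) {
  xa <- .stackScores(groupA, dim)
  xb <- .stackScores(groupB, dim)
  if (ncol(xa) != ncol(xb)) stop("groups are on different atlases")
  if (nrow(xa) < 2L || nrow(xb) < 2L) stop("need at least 2 subjects per group")
  if (paired && nrow(xa) != nrow(xb)) {
    stop("paired test requires equal group sizes in matched order")
  }
  n <- ncol(xa)
  tt <- numeric(n)
  pp <- numeric(n)
  for (i in seq_len(n)) {
    if (paired && isTRUE(all.equal(xa[, i], xb[, i]))) {
      tt[i] <- 0
      pp[i] <- 1
    } else {
      ht <- stats::t.test(xa[, i], xb[, i], paired = paired,
        var.equal = varEqual)
      tt[i] <- unname(ht$statistic)
      pp[i] <- ht$p.value
    }
  }
  qq <- bhFdr(pp)
  ids <- colnames(xa)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  data.frame(
    roi_id = ids, dim = as.integer(dim), t = tt, p = pp, q = qq,
    significant = qq < alpha, stringsAsFactors = FALSE
  )
}

.stackScores <- function(embeddings, dim) {
  if (is.matrix(embeddings)) return(embeddings)
  ok <- vapply(embeddings, function(e) is(e, "GradientEmbedding") && isAligned(e),
    logical(1L))
  if (!all(ok)) stop("all embeddings must be aligned GradientEmbedding objects")
  do.call(rbind, lapply(embeddings, function(e) {
    s <- gradientScores(e)
    if (dim < 1L || dim > ncol(s)) stop("dim out of range 1..", ncol(s))
    s[, dim]
  }))
}

.stackDistances <- function(embeddings, seed, dims) {
  do.call(rbind, lapply(embeddings, function(e) {
    gradientDistance(e, dims = dims)[seed, ]
  }))
}

#' Seed-based gradient-distance group comparison
#'
#' Tests, for one seed ROI, whether its gradient distance to every other ROI
#' differs between groups; BH-FDR across the N-1 targets. For the altered
#' (q < alpha) targets the community composition is tabulated from the
#' atlas, giving the fraction of altered connections falling in each
#' functional community.
#'
#' @param seedRoi roi_id of the seed (must be in the atlas).
#' @param groupA,groupB lists of aligned embeddings (or case x ROI distance
#'   matrices restricted to the seed row).
#' @param atlas validated atlas data frame.
#' @param paired paired t-test instead of Welch.
#' @param alpha FDR level.
#' @param dims gradient components used for the distance.
#' @return list with elements \code{seed_roi}, \code{tests} (data frame per
#'   target: roi_id, t, p, q, significant), \code{altered_count} and
#'   \code{community_composition} (named fractions over altered targets,
#'   summing to 1 when any target is altered).
#' @export
seedDistanceTest <- function(seedRoi, groupA, groupB, atlas, paired = FALSE,
                             alpha = 0.05, dims = c(1L, 2L)) {
  atlas <- validateAtlas(atlas)
  if (!seedRoi %in% atlas$roi_id) stop("seed ROI ", seedRoi, " not in atlas")
  seed_idx <- match(seedRoi, atlas$roi_id)
  da <- if (is.matrix(groupA)) groupA else .stackDistances(groupA, seed_idx, dims)
  db <- if (is.matrix(groupB)) groupB else .stackDistances(groupB, seed_idx, dims)
  targets <- setdiff(seq_len(nrow(atlas)), seed_idx)
  tt <- numeric(length(targets))
  pp <- numeric(length(targets))
  for (j in seq_along(targets)) {
    i <- targets[j]
    if (paired && isTRUE(all.equal(da[, i], db[, i]))) {
      tt[j] <- 0
      pp[j] <- 1
    } else {
      ht <- stats::t.test(da[, i], db[, i], paired = paired)
      tt[j] <- unname(ht$statistic)
      pp[j] <- ht$p.value
    }
  }
  qq <- bhFdr(pp)
  tests <- data.frame(
    roi_id = atlas$roi_id[targets], t = tt, p = pp, q = qq,
    significant = qq < alpha, stringsAsFactors = FALSE
  )
  altered <- tests$roi_id[tests$significant]
  comp <- numeric(0)
  if (length(altered)) {
    tab <- table(atlas$community[match(altered, atlas$roi_id)])
    comp <- as.numeric(tab) / length(altered)
    names(comp) <- names(tab)
  }
  list(
    seed_roi = seedRoi,
    tests = tests,
    altered_count = length(altered),
    community_composition = comp
  )
}

#' Spearman association between a gradient feature and a clinical measure
#'
#' Spearman rho with average-rank tie handling and a two-sided p from the
#' t-approximation t = rho * sqrt((n-2) / (1-rho^2)), the convention for
#' moderate samples with ties.
#'
#' @param feature numeric per-case values (e.g. a seed's aligned G2 score).
#' @param measure numeric per-case clinical values (THI score/level, VAS);
#'   ties allowed.
#' @return list with \code{rho}, \code{p} and \code{n}.
#' @export
spearmanAssoc <- function(feature, measure) {
  if (length(feature) != length(measure)) stop("feature/measure length mismatch")
  keep <- stats::complete.cases(feature, measure)
  feature <- feature[keep]
  measure <- measure[keep]
  n <- length(feature)
  if (n < 5L) stop("need at least 5 complete cases")
  if (stats::sd(feature) == 0 || stats::sd(measure) == 0) {
    stop("Spearman rho undefined for a constant vector")
  }
  rho <- stats::cor(rank(feature), rank(measure))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}
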
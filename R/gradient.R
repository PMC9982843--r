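#' PCA gradient embedding of an affinity matrix
#'
#' Column-centers the affinity matrix and projects its rows onto the top-k
#' right singular vectors. Component k's variance fraction is
#' sigma_k^2 / sum(sigma^2) over all N-1 possible components, so the
#' reported fractions are comparable across choices of k. Each component is
#' given a deterministic orientation: the loading entry with the largest
#' absolute value is made positive.
#'
#' @param affinity \code{Connectome} at stage \code{"affinity"} (or a plain
#'   symmetric matrix).
#' @param k number of components, 2 <= k <= N-1.
#' @return unaligned \code{\linkS4class{GradientEmbedding}}.
#' @export
pcaEmbedding <- function(affinity, k = 10L) {
  a <- if (is(affinity, "Connectome")) {
    if (connStage(affinity) != "affinity") {
      stop("pcaEmbedding expects an 'affinity' connectome, got stage '",
        connStage(affinity), "'")
    }
    connValues(affinity)
  } else {
    as.matrix(affinity)
  }
  n <- nrow(a)
  if (max(abs(a - t(a))) > 1e-8) stop("affinity matrix must be symmetric")
  if (k < 2L || k > n - 1L) {
    stop(sprintf("k must lie in [2, %d], got %d", n - 1L, k))
  }
  centered <- sweep(a, 2L, colMeans(a))
  sv <- svd(centered, nu = 0L, nv = k)
  scores <- centered %*% sv$v
  # sign convention: largest-|loading| entry of each right singular vector positive
  for (j in seq_len(k)) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) {
      scores[, j] <- -scores[, j]
    }
  }
  d2 <- sv$d^2
  ve <- d2[seq_len(k)] / sum(d2)
  colnames(scores) <- paste0("G", seq_len(k))
  rownames(scores) <- rownames(a)
  new("GradientEmbedding",
    scores = scores, varianceExplained = ve,
    aligned = FALSE, referenceId = NA_character_
  )
}

#' Group-level gradient template from a reference cohort
#'
#' Averages the raw Pearson connectomes of a reference cohort element-wise,
#' then runs the standard chain (Fisher z, row-wise threshold, cosine
#' affinity, PCA) on the mean matrix. The resulting embedding is the
#' alignment target for all per-subject embeddings; it should be built from
#' subjects held out of the group comparisons.
#'
#' @param connectomes list of \code{Connectome} objects at stage
#'   \code{"raw_r"}, all on the same atlas.
#' @param fraction threshold fraction for the chain.
#' @param k number of components.
#' @param templateId identifier recorded as \code{referenceId} on the
#'   template and on everything later aligned to it.
#' @return \code{GradientEmbedding} marked aligned to itself.
#' @export
buildTemplate <- function(connectomes, fraction = 0.10, k = 10L,
                          templateId = "template") {
  if (length(connectomes) < 2L) stop("need at least 2 reference connectomes")
  ok <- vapply(connectomes, function(cc) {
    is(cc, "Connectome") && connStage(cc) == "raw_r"
  }, logical(1L))
  if (!all(ok)) stop("all template inputs must be 'raw_r' connectomes")
  ns <- vapply(connectomes, function(cc) nrow(connValues(cc)), integer(1L))
  if (length(unique(ns)) != 1L) {
    stop("reference connectomes differ in size: ", paste(unique(ns), collapse = ", "))
  }
  mean_r <- Reduce(`+`, lapply(connectomes, connValues)) / length(connectomes)
  emb <- pcaEmbedding(
    cosineAffinity(thresholdTopFraction(fisherZ(newConnectome(mean_r, "raw_r")),
      fraction)),
    k = k
  )
  emb@aligned <- TRUE
  emb@referenceId <- templateId
  validObject(emb)
  emb
}

#' Procrustes rotation of an embedding onto a template
#'
#' Finds the orthogonal matrix Q (rotation or reflection; no scaling, no
#' further translation — scores are already column-centered) minimizing the
#' Frobenius norm of \code{scores \%*\% Q - template}, and returns the
#' rotated embedding. The residual Frobenius norm is attached as attribute
#' \code{"procrustes_residual"} on the scores.
#'
#' @param embedding unaligned (or aligned) \code{GradientEmbedding}.
#' @param template \code{GradientEmbedding} of matching dimensions.
#' @param scale if TRUE additionally apply the optimal isotropic scale
#'   (off by default: pure rotation/reflection).
#' @return aligned \code{GradientEmbedding} carrying the template's
#'   \code{referenceId}.
#' @export
procrustesAlign <- function(embedding, template, scale = FALSE) {
  stopifnot(is(embedding, "GradientEmbedding"), is(template, "GradientEmbedding"))
  e <- gradientScores(embedding)
  tm <- gradientScores(template)
  if (!all(dim(e) == dim(tm))) {
    stop(sprintf(
      "embedding (%d x %d) and template (%d x %d) dimensions differ",
      nrow(e), ncol(e), nrow(tm), ncol(tm)
    ))
  }
  m <- crossprod(e, tm)
  sv <- svd(m)
  q <- sv$u %*% t(sv$v)
  rotated <- e %*% q
  if (scale) {
    s <- sum(sv$d) / sum(e^2)
    rotated <- s * rotated
  }
  dimnames(rotated) <- dimnames(e)
  attr(rotated, "procrustes_residual") <- sqrt(sum((rotated - tm)^2))
  out <- embedding
  out@scores <- rotated
  out@aligned <- TRUE
  out@referenceId <- if (is.na(referenceId(template))) "template" else
    referenceId(template)
  validObject(out)
  out
}

#' Euclidean gradient distance between ROIs
#'
#' Distance between every pair of ROIs in the plane (or subspace) spanned by
#' the selected gradient components — the measure of functional segregation
#' within the hierarchy. Cross-subject comparison of these distances is only
#' meaningful after alignment, so unaligned input is an error.
#'
#' @param embedding aligned \code{GradientEmbedding}.
#' @param dims component indices to use, default the primary two.
#' @return symmetric N x N matrix of nonnegative distances, zero diagonal;
#'   attribute \code{"dims"} records the components used.
#' @export
gradientDistance <- function(embedding, dims = c(1L, 2L)) {
  stopifnot(is(embedding, "GradientEmbedding"))
  if (!isAligned(embedding)) {
    stop("gradient distances require an aligned embedding; run procrustesAlign() first")
  }
  s <- gradientScores(embedding)
  if (any(dims < 1L) || any(dims > ncol(s))) {
    stop("dims out of range 1..", ncol(s))
  }
  d <- as.matrix(stats::dist(s[, dims, drop = FALSE]))
  dimnames(d) <- list(rownames(s), rownames(s))
  attr(d, "dims") <- as.integer(dims)
  d
}

#' Write / read an embedding as TSV with a JSON sidecar
#'
#' The score matrix round-trips as TSV (roi_id + G1..Gk columns); variance
#' fractions, alignment flag and reference id go to \code{<path>.json}.
#'
#' @param embedding a \code{GradientEmbedding}.
#' @param path output TSV path.
#' @export
writeEmbedding <- function(embedding, path) {
  stopifnot(is(embedding, "GradientEmbedding"))
  s <- gradientScores(embedding)
  df <- data.frame(
    roi_id = if (is.null(rownames(s))) seq_len(nrow(s)) else rownames(s),
    s, check.names = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(
      variance_explained = varianceExplained(embedding),
      aligned = isAligned(embedding),
      reference_id = referenceId(embedding)
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  invisible(path)
}

#' @rdname writeEmbedding
#' @export
readEmbedding <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  s <- as.matrix(df[, -1L, drop = FALSE])
  rownames(s) <- as.character(df[[1L]])
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ref <- meta$reference_id
  new("GradientEmbedding",
    scores = s,
    varianceExplained = as.numeric(meta$variance_explained),
    aligned = isTRUE(meta$aligned),
    referenceId = if (is.null(ref) || is.na(ref)) NA_character_ else as.character(ref)
  )
}
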
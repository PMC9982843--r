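#' Pearson functional connectome from regional time series
#'
#' Correlates every pair of ROI time series; the entry point of the
#' connectome processing chain (Pearson r -> Fisher z -> row-wise top-fraction
#' threshold -> cosine affinity).
#'
#' @param ts numeric T x N matrix, one column per ROI, T >= 3.
#' @return \code{\linkS4class{Connectome}} at stage \code{"raw_r"}.
#' @export
computeFC <- function(ts) {
  ts <- as.matrix(ts)
  if (!is.numeric(ts)) stop("time series must be numeric")
  if (nrow(ts) < 3L) stop("need at least 3 time points")
  sds <- apply(ts, 2L, stats::sd)
  if (any(sds == 0)) {
    roi <- colnames(ts)[which(sds == 0)[1L]]
    if (is.null(roi)) roi <- as.character(which(sds == 0)[1L])
    stop("constant time series for ROI ", roi)
  }
  r <- stats::cor(ts)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  if (is.null(colnames(ts))) {
    dimnames(r) <- list(seq_len(ncol(ts)), seq_len(ncol(ts)))
  }
  newConnectome(r, "raw_r")
}

#' Fisher z-transform of a Pearson connectome
#'
#' Applies arctanh to the off-diagonal correlations, clipping |r| at
#' 1 - 1e-7 beforehand so duplicate-column degeneracies cannot produce
#' infinities. The diagonal is set to 0 and excluded from all later steps.
#'
#' @param conn \code{Connectome} at stage \code{"raw_r"}.
#' @return \code{Connectome} at stage \code{"z"}.
#' @export
fisherZ <- function(conn) {
  stopifnot(is(conn, "Connectome"))
  if (connStage(conn) != "raw_r") {
    stop("fisherZ expects a 'raw_r' connectome, got stage '", connStage(conn), "'")
  }
  r <- connValues(conn)
  clip <- 1 - 1e-7
  z <- atanh(pmin(pmax(r, -clip), clip))
  diag(z) <- 0
  newConnectome(z, "z")
}

#' Row-wise top-fraction thresholding
#'
#' Each ROI keeps its \code{ceiling(fraction * (N-1))} strongest off-diagonal
#' connections; the rest are zeroed. Ties are broken in favour of the larger
#' value, then the lower column index, so the retained support is
#' deterministic. The result is generally asymmetric (row-wise retention is
#' the convention of the gradient literature; set \code{global = TRUE} for a
#' single matrix-wide cutoff instead).
#'
#' @param conn \code{Connectome} at stage \code{"z"}.
#' @param fraction proportion in (0, 1] of connections retained per row.
#' @param global if TRUE, keep the top fraction of all off-diagonal entries
#'   matrix-wide instead of per row.
#' @return \code{Connectome} at stage \code{"thresholded"}.
#' @export
thresholdTopFraction <- function(conn, fraction = 0.10, global = FALSE) {
  stopifnot(is(conn, "Connectome"))
  if (connStage(conn) != "z") {
    stop("thresholdTopFraction expects a 'z' connectome, got stage '",
      connStage(conn), "'")
  }
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    stop("threshold fraction must lie in (0, 1]")
  }
  z <- connValues(conn)
  n <- nrow(z)
  out <- matrix(0, n, n, dimnames = dimnames(z))
  if (global) {
    off <- which(row(z) != col(z))
    keep_n <- ceiling(fraction * length(off))
    # order() is stable, so among equal values the lower linear index wins
    ord <- off[order(z[off], decreasing = TRUE)]
    keep <- ord[seq_len(keep_n)]
    out[keep] <- z[keep]
  } else {
    keep_n <- ceiling(fraction * (n - 1L))
    for (i in seq_len(n)) {
      row_i <- z[i, ]
      idx <- setdiff(seq_len(n), i)
      ord <- idx[order(row_i[idx], decreasing = TRUE)] # stable: lower index wins ties
      keep <- ord[seq_len(keep_n)]
      out[i, keep] <- row_i[keep]
    }
  }
  newConnectome(out, "thresholded", thresholdFraction = fraction)
}

#' Cosine-similarity affinity between connectivity profiles
#'
#' Computes the cosine similarity of every pair of thresholded rows
#' (zeros included, so the sparsity pattern contributes), giving the
#' symmetric affinity matrix that is embedded by \code{\link{pcaEmbedding}}.
#'
#' @param conn \code{Connectome} at stage \code{"thresholded"}.
#' @return \code{Connectome} at stage \code{"affinity"}; unit diagonal.
#' @export
cosineAffinity <- function(conn) {
  stopifnot(is(conn, "Connectome"))
  if (connStage(conn) != "thresholded") {
    stop("cosineAffinity expects a 'thresholded' connectome, got stage '",
      connStage(conn), "'")
  }
  x <- connValues(conn)
  norms <- sqrt(rowSums(x^2))
  if (any(norms == 0)) {
    roi <- rownames(x)[which(norms == 0)[1L]]
    if (is.null(roi)) roi <- as.character(which(norms == 0)[1L])
    stop("all-zero thresholded connectivity profile for ROI ", roi)
  }
  a <- tcrossprod(x / norms)
  a <- (a + t(a)) / 2
  a[a > 1] <- 1
  a[a < -1] <- -1
  diag(a) <- 1
  newConnectome(a, "affinity", thresholdFraction = conn@thresholdFraction)
}

#' Full affinity chain from time series
#'
#' Convenience wrapper running Pearson FC, Fisher z, row-wise thresholding
#' and cosine affinity in sequence.
#'
#' @param ts T x N time-series matrix.
#' @param fraction threshold fraction, see \code{\link{thresholdTopFraction}}.
#' @return \code{Connectome} at stage \code{"affinity"}.
#' @export
affinityFromTimeSeries <- function(ts, fraction = 0.10) {
  cosineAffinity(thresholdTopFraction(fisherZ(computeFC(ts)), fraction))
}

#' Write / read a connectome matrix as TSV with a JSON sidecar
#'
#' The matrix round-trips as a TSV with roi ids as header; the stage tag and
#' threshold fraction go to \code{<path>.json}.
#'
#' @param conn a \code{Connectome}.
#' @param path output TSV path.
#' @export
writeConnectome <- function(conn, path) {
  stopifnot(is(conn, "Connectome"))
  utils::write.table(connValues(conn), path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  meta <- list(stage = connStage(conn), threshold_fraction = conn@thresholdFraction)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname writeConnectome
#' @export
readConnectome <- function(path) {
  vals <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
    check.names = FALSE))
  rownames(vals) <- colnames(vals)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  tf <- meta$threshold_fraction
  newConnectome(vals, meta$stage,
    thresholdFraction = if (is.null(tf)) NA_real_ else as.numeric(tf)
  )
}
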
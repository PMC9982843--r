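#' @import methods
NULL

CONN_STAGES <- c("raw_r", "z", "thresholded", "affinity")

#' Connectome matrix with a processing-stage tag
#'
#' An N x N matrix of region-pair connectivity together with a tag recording
#' where it sits in the processing chain: raw Pearson correlations
#' (\code{"raw_r"}), Fisher z values (\code{"z"}), row-wise top-fraction
#' thresholded z values (\code{"thresholded"}), or the cosine-similarity
#' affinity matrix (\code{"affinity"}) that feeds the gradient embedding.
#' Stage transitions are performed by \code{\link{fisherZ}},
#' \code{\link{thresholdTopFraction}} and \code{\link{cosineAffinity}}, each
#' of which checks the stage of its input, so objects cannot silently skip a
#' step of the chain.
#'
#' @slot values numeric N x N matrix; row/column names are ROI ids.
#' @slot stage one of \code{"raw_r"}, \code{"z"}, \code{"thresholded"},
#'   \code{"affinity"}.
#' @slot thresholdFraction fraction of off-diagonal entries retained per row
#'   at the thresholding step; \code{NA_real_} before that step.
#'
#' @seealso \code{\link{computeFC}} for the entry point of the chain.
#' @export
setClass("Connectome",
  representation(
    values = "matrix",
    stage = "character",
    thresholdFraction = "numeric"
  ),
  prototype(thresholdFraction = NA_real_)
)

setValidity("Connectome", function(object) {
  v <- object@values
  msgs <- character()
  if (nrow(v) != ncol(v)) {
    msgs <- c(msgs, "'values' must be square")
  }
  if (length(object@stage) != 1L || !object@stage %in% CONN_STAGES) {
    msgs <- c(msgs, sprintf(
      "'stage' must be one of: %s", paste(CONN_STAGES, collapse = ", ")
    ))
  }
  if (any(!is.finite(v))) {
    msgs <- c(msgs, "'values' contains non-finite entries")
  }
  if (length(msgs) == 0L && object@stage %in% c("raw_r", "affinity")) {
    if (max(abs(v - t(v))) > 1e-10) {
      msgs <- c(msgs, sprintf("stage '%s' requires a symmetric matrix", object@stage))
    }
    if (max(abs(diag(v) - 1)) > 1e-10) {
      msgs <- c(msgs, sprintf("stage '%s' requires unit diagonal", object@stage))
    }
    if (max(abs(v)) > 1 + 1e-10) {
      msgs <- c(msgs, sprintf("stage '%s' requires entries in [-1, 1]", object@stage))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Gradient embedding of a connectome affinity matrix
#'
#' ROI-by-component scores from the PCA embedding of an affinity matrix,
#' together with the fraction of affinity variance each component explains.
#' Unaligned embeddings come out of \code{\link{pcaEmbedding}} with a
#' deterministic per-component sign convention; aligned embeddings carry the
#' identifier of the template they were Procrustes-rotated onto and are the
#' only ones accepted by cross-subject comparisons such as
#' \code{\link{gradientDistance}}.
#'
#' @slot scores numeric N x k matrix of component scores (columns G1..Gk).
#' @slot varianceExplained length-k nonincreasing vector of variance
#'   fractions relative to the total variance of all N-1 possible components.
#' @slot aligned logical; TRUE after Procrustes alignment.
#' @slot referenceId identifier of the alignment template
#'   (\code{NA_character_} when unaligned).
#'
#' @export
setClass("GradientEmbedding",
  representation(
    scores = "matrix",
    varianceExplained = "numeric",
    aligned = "logical",
    referenceId = "character"
  ),
  prototype(aligned = FALSE, referenceId = NA_character_)
)

setValidity("GradientEmbedding", function(object) {
  msgs <- character()
  k <- ncol(object@scores)
  if (length(object@varianceExplained) != k) {
    msgs <- c(msgs, "'varianceExplained' length must equal ncol(scores)")
  } else if (k > 1L && any(diff(object@varianceExplained) > 1e-12)) {
    msgs <- c(msgs, "'varianceExplained' must be nonincreasing")
  }
  if (length(object@varianceExplained) &&
      (any(object@varianceExplained < -1e-12) ||
       sum(object@varianceExplained) > 1 + 1e-8)) {
    msgs <- c(msgs, "'varianceExplained' must be fractions summing to at most 1")
  }
  if (length(object@aligned) != 1L || is.na(object@aligned)) {
    msgs <- c(msgs, "'aligned' must be TRUE or FALSE")
  } else if (object@aligned && is.na(object@referenceId)) {
    msgs <- c(msgs, "aligned embeddings must carry a 'referenceId'")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn Connectome matrix of connectivity values
#' @param object,x a \code{Connectome} or \code{GradientEmbedding}
#' @export
connValues <- function(x) {
  stopifnot(is(x, "Connectome"))
  x@values
}

#' @describeIn Connectome processing stage tag
#' @export
connStage <- function(x) {
  stopifnot(is(x, "Connectome"))
  x@stage
}

#' @describeIn GradientEmbedding N x k matrix of component scores
#' @param x,object a \code{GradientEmbedding}
#' @export
gradientScores <- function(x) {
  stopifnot(is(x, "GradientEmbedding"))
  x@scores
}

#' @describeIn GradientEmbedding per-component variance fractions
#' @export
varianceExplained <- function(x) {
  stopifnot(is(x, "GradientEmbedding"))
  x@varianceExplained
}

#' @describeIn GradientEmbedding has the embedding been aligned to a template?
#' @export
isAligned <- function(x) {
  stopifnot(is(x, "GradientEmbedding"))
  x@aligned
}

#' @describeIn GradientEmbedding identifier of the alignment template
#' @export
referenceId <- function(x) {
  stopifnot(is(x, "GradientEmbedding"))
  x@referenceId
}

setMethod("show", "Connectome", function(object) {
  cat(sprintf(
    "Connectome: %d x %d, stage '%s'%s\n",
    nrow(object@values), ncol(object@values), object@stage,
    if (is.na(object@thresholdFraction)) "" else
      sprintf(" (threshold fraction %.3g)", object@thresholdFraction)
  ))
})

setMethod("show", "GradientEmbedding", function(object) {
  ve <- object@varianceExplained
  cat(sprintf(
    "GradientEmbedding: %d ROIs x %d components, %s\n",
    nrow(object@scores), ncol(object@scores),
    if (object@aligned) sprintf("aligned to '%s'", object@referenceId)
    else "unaligned"
  ))
  if (length(ve) >= 2L) {
    cat(sprintf(
      "  variance explained: G1 %.1f%%, G2 %.1f%% (G1+G2 %.1f%%)\n",
      100 * ve[1L], 100 * ve[2L], 100 * (ve[1L] + ve[2L])
    ))
  }
})

setMethod("dim", "Connectome", function(x) dim(x@values))
setMethod("dim", "GradientEmbedding", function(x) dim(x@scores))

newConnectome <- function(values, stage, thresholdFraction = NA_real_) {
  new("Connectome",
    values = values, stage = stage,
    thresholdFraction = thresholdFraction
  )
}
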
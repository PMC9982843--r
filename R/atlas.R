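#' Canonical functional community labels
#'
#' The seven canonical resting-state communities (visual, somatomotor,
#' dorsal attention, ventral attention, limbic, frontoparietal, default
#' mode) plus a subcortical bucket used to annotate ROIs.
#'
#' @export
atlasCommunities <- function() {
  c("Vis", "SM", "DA", "VA", "Lim", "FP", "DMN", "Subcortical")
}

ATLAS_COLUMNS <- c("roi_id", "roi_name", "community", "hemisphere", "x", "y", "z")

#' Validate an atlas annotation table
#'
#' Checks that a data frame is a well-formed atlas: the six required columns,
#' unique contiguous ROI ids starting at 1, known community labels,
#' hemisphere in L/R/NA, numeric mm coordinates, and at least 3 ROIs. The
#' row order of the returned table defines the ROI order of every matrix in
#' an analysis.
#'
#' @param atlas data frame with columns \code{roi_id}, \code{roi_name},
#'   \code{community}, \code{hemisphere}, \code{x}, \code{y}, \code{z}.
#' @return the validated data frame (invisibly unchanged), class
#'   \code{"atlas"} prepended.
#' @export
validateAtlas <- function(atlas) {
  missing_cols <- setdiff(ATLAS_COLUMNS, names(atlas))
  if (length(missing_cols)) {
    stop("atlas is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  ids <- atlas$roi_id
  if (anyNA(suppressWarnings(as.integer(ids))) || any(ids != as.integer(ids))) {
    stop("atlas roi_id must be integer")
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate roi_id in atlas: ", paste(unique(dup), collapse = ", "))
  }
  if (nrow(atlas) < 3L) stop("atlas must contain at least 3 ROIs")
  if (!identical(as.integer(ids), seq_len(nrow(atlas)))) {
    stop("atlas roi_id must be contiguous 1..N in row order")
  }
  bad <- !atlas$community %in% atlasCommunities()
  if (any(bad)) {
    stop(sprintf(
      "unknown community label '%s' at roi_id %d; allowed labels: %s",
      atlas$community[which(bad)[1L]], ids[which(bad)[1L]],
      paste(atlasCommunities(), collapse = ", ")
    ))
  }
  hemi <- as.character(atlas$hemisphere)
  if (any(!hemi %in% c("L", "R", "NA") & !is.na(hemi))) {
    stop("atlas hemisphere must be 'L', 'R' or 'NA'")
  }
  for (cc in c("x", "y", "z")) {
    if (!is.numeric(atlas[[cc]]) || anyNA(atlas[[cc]])) {
      stop("atlas coordinate column '", cc, "' must be numeric with no missing values")
    }
  }
  atlas$roi_id <- as.integer(atlas$roi_id)
  atlas$roi_name <- as.character(atlas$roi_name)
  atlas$community <- as.character(atlas$community)
  atlas$hemisphere <- as.character(atlas$hemisphere)
  class(atlas) <- unique(c("atlas", class(atlas)))
  atlas
}

#' Read an atlas annotation table
#'
#' Reads a TSV/CSV file (delimiter inferred from the header line) with one
#' row per ROI and validates it with \code{\link{validateAtlas}}. Row order
#' is preserved and becomes the ROI order of all downstream matrices.
#'
#' @param path path to a delimited text file with a header row.
#' @return validated atlas data frame.
#' @export
readAtlas <- function(path) {
  if (!file.exists(path)) stop("atlas file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  atlas <- utils::read.table(path,
    header = TRUE, sep = sep,
    stringsAsFactors = FALSE, quote = "\"", comment.char = "",
    na.strings = character()
  )
  validateAtlas(atlas)
}

#' Write an atlas annotation table as TSV
#'
#' @param atlas validated atlas data frame.
#' @param path output file path.
#' @export
writeAtlas <- function(atlas, path) {
  atlas <- validateAtlas(atlas)
  utils::write.table(as.data.frame(unclass(atlas))[ATLAS_COLUMNS],
    path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read a regional time-series matrix
#'
#' Reads a numeric TSV with one column per ROI and one row per time point
#' and checks it against the atlas: column count must equal the atlas size,
#' at least 8 time points, and no missing or non-numeric cells.
#'
#' @param path path to a numeric TSV (header row of ROI ids optional).
#' @param atlas validated atlas data frame defining the expected ROI count.
#' @return numeric T x N matrix, columns in atlas ROI order.
#' @export
readTimeSeries <- function(path, atlas) {
  atlas <- validateAtlas(atlas)
  if (!file.exists(path)) stop("time-series file not found: ", path)
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  raw <- utils::read.table(path,
    header = has_header, sep = "\t",
    colClasses = "character", comment.char = "", quote = ""
  )
  if (ncol(raw) != nrow(atlas)) {
    stop(sprintf(
      "time-series file has %d columns but atlas defines %d ROIs",
      ncol(raw), nrow(atlas)
    ))
  }
  mat <- suppressWarnings(apply(as.matrix(raw), 2L, as.numeric))
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "non-numeric value in time-series file at row %d, column %d: '%s'",
      bad[["row"]], bad[["col"]], raw[bad[["row"]], bad[["col"]]]
    ))
  }
  if (nrow(mat) < 8L) stop("time series must have at least 8 time points")
  dimnames(mat) <- list(NULL, as.character(atlas$roi_id))
  mat
}

#' Write a time-series matrix as TSV
#'
#' @param ts numeric T x N matrix.
#' @param path output file path.
#' @export
writeTimeSeries <- function(ts, path) {
  # written headerless: a purely numeric roi_id header would be
  # indistinguishable from a data row, and column order is the atlas's
  utils::write.table(ts, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
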
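#' Partial least squares regression of a regional map on gene expression
#'
#' Regresses a per-ROI alteration map (e.g. a t-statistic map from a group
#' comparison) on a genes x ROI expression matrix by PLS, with ROIs as
#' observations and genes as predictors. Genes are standardized (mean 0,
#' SD 1 across ROIs) internally. The first component (PLS1) is the gene
#' expression profile most strongly covarying with the map; its per-gene
#' weights define the transcriptomic signature and its variance explained
#' is the share of (centered) response variance captured after component 1.
#' Components are extracted by the standard iterative latent-variable
#' scheme; with a single response the weight direction is the response-
#' covariance direction, so the fit is deterministic.
#'
#' @param map numeric per-ROI values, length equal to \code{ncol(expr)}.
#' @param expr numeric genes x ROI matrix, rownames = gene symbols.
#' @param nComponents number of latent components to extract.
#' @return list of class \code{"plsResult"}: \code{pls1_roi_scores},
#'   \code{gene_weights} (named, component 1), \code{var_explained_pls1},
#'   \code{var_explained} (per component), \code{n_components},
#'   \code{perm_p = NA} until \code{\link{permutationTestPls}} is run.
#' @export
plsrSpatial <- function(map, expr, nComponents = 1L) {
  expr <- as.matrix(expr)
  n_roi <- ncol(expr)
  n_gene <- nrow(expr)
  if (length(map) != n_roi) {
    stop("map length (", length(map), ") must equal ROI count (", n_roi, ")")
  }
  if (n_roi < 3L) stop("need at least 3 ROIs")
  if (n_gene < 2L) stop("need at least 2 genes")
  if (anyNA(map) || anyNA(expr)) stop("missing values are not allowed")
  if (stats::sd(map) == 0) stop("alteration map is constant")
  gene_sd <- apply(expr, 1L, stats::sd)
  if (any(gene_sd == 0)) {
    stop("constant expression for gene ", rownames(expr)[which(gene_sd == 0)[1L]])
  }
  if (is.null(rownames(expr))) {
    rownames(expr) <- paste0("gene", seq_len(n_gene))
  }
  x <- scale(t(expr)) # ROIs x genes, standardized per gene
  y <- map - mean(map)
  tss <- sum(y^2)
  ncomp <- min(nComponents, n_gene, n_roi - 1L)

  scores <- matrix(0, n_roi, ncomp)
  weights <- matrix(0, n_gene, ncomp, dimnames = list(rownames(expr), NULL))
  ve <- numeric(ncomp)
  x_d <- x
  y_d <- y
  for (h in seq_len(ncomp)) {
    w <- crossprod(x_d, y_d)[, 1L]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      ncomp <- h - 1L
      break
    }
    w <- w / nw
    t_h <- x_d %*% w
    tt <- sum(t_h^2)
    p_h <- crossprod(x_d, t_h)[, 1L] / tt
    q_h <- sum(y_d * t_h) / tt
    x_d <- x_d - tcrossprod(t_h, p_h)
    y_d <- y_d - q_h * t_h
    scores[, h] <- t_h
    weights[, h] <- w
    ve[h] <- 1 - sum(y_d^2) / tss
  }
  if (ncomp < 1L) stop("no informative component could be extracted")
  ve <- ve[seq_len(ncomp)]
  per_comp <- diff(c(0, ve))
  structure(list(
    pls1_roi_scores = scores[, 1L],
    gene_weights = weights[, 1L],
    var_explained_pls1 = ve[1L],
    var_explained = per_comp,
    n_components = ncomp,
    perm_p = NA_real_,
    n_perm = 0L
  ), class = "plsResult")
}

#' Permutation significance of the PLS1 variance explained
#'
#' Shuffles the ROI order of the alteration map \code{nPerm} times,
#' refitting PLS1 each time, and reports the plus-one permutation p-value
#' of the observed component-1 variance explained. Uniform shuffles are
#' used; note they do not preserve spatial autocorrelation of the map, so
#' for spatially smooth maps the p-value is anticonservative relative to
#' autocorrelation-preserving nulls.
#'
#' @param map,expr as in \code{\link{plsrSpatial}}.
#' @param nPerm number of permutations, at least 99.
#' @param seed integer seed for the shuffles.
#' @return list: \code{perm_p}, \code{observed} (variance explained),
#'   \code{n_perm}, \code{null} (the permuted values).
#' @export
permutationTestPls <- function(map, expr, nPerm = 999L, seed = 1L) {
  if (nPerm < 99L) stop("need at least 99 permutations")
  obs <- plsrSpatial(map, expr)$var_explained_pls1
  set.seed(.deriveSeed(seed, "pls_perm"))
  null <- vapply(seq_len(nPerm), function(i) {
    plsrSpatial(map[sample.int(length(map))], expr)$var_explained_pls1
  }, numeric(1L))
  p <- (1 + sum(null >= obs)) / (1 + nPerm)
  list(perm_p = p, observed = obs, n_perm = as.integer(nPerm), null = null)
}

#' Rank genes by their PLS1 weight
#'
#' @param pls a \code{plsResult}.
#' @return data frame \code{gene}, \code{weight}, sorted by weight
#'   descending, ties broken by gene symbol.
#' @export
rankGenes <- function(pls) {
  stopifnot(inherits(pls, "plsResult"))
  w <- pls$gene_weights
  ord <- order(-w, names(w))
  data.frame(gene = names(w)[ord], weight = unname(w[ord]),
    stringsAsFactors = FALSE)
}

#' Gene set enrichment analysis on a ranked gene list
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment (weight exponent 1 on
#' the absolute ranking score) of each gene set against the ranked list,
#' with a gene-label permutation null: \code{nPerm} random same-size sets
#' are drawn, the normalized enrichment score is the observed ES divided by
#' the mean |ES| of null draws with matching sign, the p-value is one-sided
#' on the matching-sign null with the plus-one rule, and BH-FDR is applied
#' across sets. Sets are filtered to sizes within \code{[minSize, maxSize]}
#' after intersection with the ranked genes; empty intersections are
#' skipped with a warning.
#'
#' @param ranked data frame with columns \code{gene} and \code{weight}
#'   (from \code{\link{rankGenes}}), or a named numeric vector of scores,
#'   sorted decreasing.
#' @param sets named list of gene-symbol vectors (see \code{\link{readGmt}}).
#' @param nPerm permutations per set.
#' @param seed integer seed.
#' @param minSize,maxSize post-intersection set-size bounds.
#' @return data frame per retained set: \code{set}, \code{size}, \code{es},
#'   \code{nes}, \code{p}, \code{q}, \code{leading_edge}
#'   (comma-separated symbols).
#' @export
gsea <- function(ranked, sets, nPerm = 999L, seed = 1L,
                 minSize = 5L, maxSize = 500L) {
  if (is.data.frame(ranked)) {
    scores <- ranked$weight
    names(scores) <- ranked$gene
  } else {
    scores <- ranked
  }
  if (is.unsorted(rev(scores))) {
    ord <- order(-scores, names(scores))
    scores <- scores[ord]
  }
  genes <- names(scores)
  n <- length(genes)
  keep <- list()
  for (nm in names(sets)) {
    s <- intersect(sets[[nm]], genes)
    if (length(s) == 0L) {
      warning("gene set '", nm, "' has no genes in the ranked list; skipped")
      next
    }
    if (length(s) < minSize || length(s) > maxSize) next
    keep[[nm]] <- s
  }
  if (length(keep) == 0L) {
    return(data.frame(set = character(), size = integer(), es = numeric(),
      nes = numeric(), p = numeric(), q = numeric(),
      leading_edge = character(), stringsAsFactors = FALSE))
  }
  set.seed(.deriveSeed(seed, "gsea"))
  rows <- lapply(names(keep), function(nm) {
    s <- keep[[nm]]
    hit <- genes %in% s
    obs <- .gseaES(scores, hit)
    nh <- length(s)
    null_es <- vapply(seq_len(nPerm), function(i) {
      h <- logical(n)
      h[sample.int(n, nh)] <- TRUE
      .gseaES(scores, h)$es
    }, numeric(1L))
    same <- null_es[sign(null_es) == sign(obs$es)]
    nes <- if (length(same)) obs$es / mean(abs(same)) else NA_real_
    p <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
    data.frame(set = nm, size = nh, es = obs$es, nes = nes, p = p,
      leading_edge = paste(obs$leading_edge, collapse = ","),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bhFdr(out$p)
  out[, c("set", "size", "es", "nes", "p", "q", "leading_edge")]
}

# running-sum enrichment score; scores sorted decreasing, hit = logical mask
.gseaES <- function(scores, hit, weightExponent = 1) {
  n <- length(scores)
  nh <- sum(hit)
  if (nh == 0L || nh == n) {
    return(list(es = 0, leading_edge = character(0)))
  }
  w <- abs(scores)^weightExponent
  nr <- sum(w[hit])
  if (nr == 0) {
    # all hit scores are exactly zero: fall back to unweighted steps
    p_hit <- cumsum(hit) / nh
  } else {
    p_hit <- cumsum(ifelse(hit, w, 0)) / nr
  }
  p_miss <- cumsum(!hit) / (n - nh)
  dev <- p_hit - p_miss
  i <- which.max(abs(dev))
  es <- unname(dev[i])
  genes <- names(scores)
  le <- if (es >= 0) genes[hit & seq_len(n) <= i] else genes[hit & seq_len(n) > i]
  list(es = es, leading_edge = le)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: set name, description, then member gene symbols,
#' tab-separated.
#'
#' @param path GMT file path.
#' @return named list of gene-symbol vectors; descriptions kept in
#'   attribute \code{"description"}.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1L)) < 3L
  if (any(bad)) stop("malformed GMT line ", which(bad)[1L],
    ": need name, description and at least one gene")
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1L), 1L)
  attr(sets, "description") <- vapply(parts, `[[`, character(1L), 2L)
  sets
}

#' @rdname readGmt
#' @param sets named list of gene-symbol vectors.
#' @param descriptions optional character vector of set descriptions.
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "description")
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  lines <- mapply(function(nm, desc, genes) {
    paste(c(nm, desc, genes), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a genes x ROI expression matrix as TSV
#'
#' First column is the gene symbol; remaining columns are ROIs in atlas
#' order.
#'
#' @param path TSV path.
#' @return numeric matrix with gene symbols as rownames.
#' @export
readExpression <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
    check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  if (anyNA(m)) stop("missing expression values in ", path)
  rownames(m) <- df[[1L]]
  m
}

#' @rdname readExpression
#' @param expr numeric genes x ROI matrix with gene-symbol rownames.
#' @export
writeExpression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
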
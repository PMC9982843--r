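#' Leave-one-out stepwise regression for symptom prediction
#'
#' For every left-out case, fits a stepwise ordinary least squares model of
#' the clinical target on the candidate gradient features, with the
#' covariates (age, sex) and intercept always included. Forward steps add
#' the candidate with the smallest partial-t p-value when it is below
#' \code{alphaEnter}; backward steps drop the in-model candidate with the
#' largest p-value when it exceeds \code{alphaRemove}; steps alternate to
#' convergence. The left-out case is predicted from the converged model. A
#' candidate's reliability is the fraction of leave-one-out iterations in
#' which it entered the final model with p < 0.05; candidates at or above
#' the reliability cutoff (default 0.98) are reported as reliable.
#' Prediction quality is summarized by the mean absolute error and the
#' Pearson correlation of pooled predictions with the observed target,
#' declared significant only when its two-sided p is below 0.05.
#'
#' @param features numeric case x feature matrix of candidate predictors
#'   (column names are the candidate identifiers).
#' @param covariates data frame of always-included adjustment variables
#'   (e.g. age in years and sex coded 0/1); may have zero columns.
#' @param target numeric per-case measure (VAS, THI score or level).
#' @param alphaEnter,alphaRemove entry/removal p-value thresholds.
#' @param reliabilityCutoff minimum selection-and-significance fraction for
#'   a feature to be reported reliable.
#' @param maxIter bound on forward/backward sweeps per fit.
#' @return list of class \code{"looswrReport"}: \code{selected} (per-
#'   iteration feature sets), \code{reliability} (named fractions),
#'   \code{reliable_features}, \code{predictions}, \code{mae},
#'   \code{abs_error_sd}, \code{r}, \code{p_r}, \code{significant},
#'   \code{config}.
#' @export
looswr <- function(features, covariates, target,
                   alphaEnter = 0.05, alphaRemove = 0.05,
                   reliabilityCutoff = 0.98, maxIter = 50L) {
  features <- as.matrix(features)
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("feature", seq_len(ncol(features)))
  }
  n <- nrow(features)
  if (n < 10L) stop("need at least 10 cases")
  if (length(target) != n) stop("target length must match number of cases")
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) == 0L && ncol(covariates) == 0L) {
    covariates <- data.frame(row.names = seq_len(n))
  }
  if (nrow(covariates) != n) stop("covariates must have one row per case")
  if (anyNA(features) || anyNA(target) || anyNA(covariates)) {
    stop("missing values are not allowed")
  }
  if (stats::sd(target) == 0) stop("target is constant")
  candidates <- colnames(features)
  if (any(candidates %in% names(covariates))) {
    stop("feature and covariate names must not overlap")
  }
  # reject candidates numerically collinear with the covariates
  base_mm <- stats::model.matrix(~., data = covariates)
  for (f in candidates) {
    aug <- cbind(base_mm, features[, f])
    if (kappa(aug, exact = TRUE) > 1e10) {
      stop("feature '", f, "' is collinear with the covariates")
    }
  }

  dat <- cbind(covariates, as.data.frame(features), .target = target)
  covar_terms <- names(covariates)

  fit_formula <- function(sel) {
    rhs <- c("1", covar_terms, sel)
    stats::as.formula(paste(".target ~", paste(rhs, collapse = " + ")))
  }
  coef_p <- function(fit, term) {
    sm <- summary(fit)$coefficients
    if (!term %in% rownames(sm)) return(NA_real_)
    sm[term, "Pr(>|t|)"]
  }

  selected <- vector("list", n)
  significant_sel <- vector("list", n)
  predictions <- numeric(n)
  for (i in seq_len(n)) {
    train <- dat[-i, , drop = FALSE]
    sel <- character(0)
    for (iter in seq_len(maxIter)) {
      changed <- FALSE
      # forward: best candidate not yet in the model
      pool <- setdiff(candidates, sel)
      if (length(pool)) {
        pvals <- vapply(pool, function(f) {
          fit <- stats::lm(fit_formula(c(sel, f)), data = train)
          p <- coef_p(fit, f)
          if (is.na(p)) Inf else p
        }, numeric(1L))
        if (min(pvals) < alphaEnter) {
          sel <- c(sel, pool[which.min(pvals)]) # ties: first (manifest order)
          changed <- TRUE
        }
      }
      # backward: worst candidate currently in the model
      if (length(sel)) {
        fit <- stats::lm(fit_formula(sel), data = train)
        pvals <- vapply(sel, function(f) {
          p <- coef_p(fit, f)
          if (is.na(p)) Inf else p
        }, numeric(1L))
        if (max(pvals) > alphaRemove) {
          sel <- setdiff(sel, sel[which.max(pvals)])
          changed <- TRUE
        }
      }
      if (!changed) break
      if (iter == maxIter) stop("stepwise selection did not converge")
    }
    fit <- stats::lm(fit_formula(sel), data = train)
    predictions[i] <- stats::predict(fit, newdata = dat[i, , drop = FALSE])
    selected[[i]] <- sel
    significant_sel[[i]] <- sel[vapply(sel, function(f) {
      p <- coef_p(fit, f)
      !is.na(p) && p < 0.05
    }, logical(1L))]
  }

  reliability <- vapply(candidates, function(f) {
    mean(vapply(significant_sel, function(s) f %in% s, logical(1L)))
  }, numeric(1L))
  abs_err <- abs(predictions - target)
  r <- stats::cor(predictions, target)
  p_r <- if (is.na(r) || abs(r) >= 1) {
    if (is.na(r)) NA_real_ else 0
  } else {
    2 * stats::pt(-abs(r * sqrt((n - 2) / (1 - r^2))), df = n - 2)
  }
  structure(list(
    selected = selected,
    reliability = reliability,
    reliable_features = names(reliability)[reliability >= reliabilityCutoff],
    predictions = predictions,
    mae = mean(abs_err),
    abs_error_sd = stats::sd(abs_err),
    r = r,
    p_r = p_r,
    significant = !is.na(p_r) && p_r < 0.05,
    config = list(
      alpha_enter = alphaEnter, alpha_remove = alphaRemove,
      reliability_cutoff = reliabilityCutoff, n_cases = n,
      candidates = candidates
    )
  ), class = "looswrReport")
}

#' @export
print.looswrReport <- function(x, ...) {
  cat(sprintf(
    "Leave-one-out stepwise regression: %d cases, %d candidate feature(s)\n",
    x$config$n_cases, length(x$config$candidates)
  ))
  cat(sprintf("  MAE %.3f (abs-error SD %.3f), r = %.3f, p = %.4g%s\n",
    x$mae, x$abs_error_sd, x$r, x$p_r,
    if (isTRUE(x$significant)) " *" else ""))
  if (length(x$reliable_features)) {
    cat("  reliable features:", paste(x$reliable_features, collapse = ", "), "\n")
  } else {
    cat("  no reliable features\n")
  }
  invisible(x)
}
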
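#' Analysis configuration
#'
#' Tunable parameters of the gradient pipeline with the defaults used
#' throughout: 10% row-wise connection density, 10 embedding components
#' with the primary analyses on components 1-2, FDR level 0.05, symmetric
#' stepwise entry/removal thresholds of 0.05, and 1000 permutations for
#' the transcriptomic significance tests.
#'
#' @param thresholdFraction connection fraction retained per row, (0, 1].
#' @param nComponents embedding components computed and aligned.
#' @param primaryDims component pair used for gradient distances.
#' @param fdrAlpha FDR level for significance flags.
#' @param alphaEnter,alphaRemove stepwise thresholds.
#' @param nPermutations permutations for PLS/GSEA, at least 99.
#' @param randomSeed integer seed for the run.
#' @return list of class \code{"analysisConfig"}.
#' @export
analysisConfig <- function(thresholdFraction = 0.10, nComponents = 10L,
                           primaryDims = c(1L, 2L), fdrAlpha = 0.05,
                           alphaEnter = 0.05, alphaRemove = 0.05,
                           nPermutations = 1000L, randomSeed = 1L) {
  if (thresholdFraction <= 0 || thresholdFraction > 1) {
    stop("thresholdFraction must lie in (0, 1]")
  }
  if (nComponents < 2L) stop("need at least 2 components")
  if (!all(primaryDims %in% seq_len(nComponents))) {
    stop("primaryDims must be within 1..nComponents")
  }
  if (nPermutations < 99L) stop("need at least 99 permutations")
  structure(list(
    threshold_fraction = thresholdFraction,
    n_components = as.integer(nComponents),
    primary_dims = as.integer(primaryDims),
    fdr_alpha = fdrAlpha,
    alpha_enter = alphaEnter,
    alpha_remove = alphaRemove,
    n_permutations = as.integer(nPermutations),
    random_seed = as.integer(randomSeed)
  ), class = "analysisConfig")
}

#' Run the full gradient analysis end-to-end
#'
#' Generates (or loads) a cohort, builds per-scan affinity matrices and
#' gradient embeddings, aligns them to a template from the held-out
#' reference scans, and runs every downstream stage: ROI-wise group
#' comparison of the primary gradients (patients-with-tinnitus vs healthy
#' controls), the seed-based gradient-distance comparison at the most
#' altered ROI, the clinical contingency summary, Spearman associations of
#' the target gradient feature with THI score/level and VAS,
#' leave-one-out stepwise prediction of VAS, and the
#' imaging-transcriptomics PLS with gene-set enrichment. All tables are
#' written as TSV under \code{outDir} together with a \code{summary.json}
#' that carries the seed and a config hash; stage timings go to
#' \code{run.log} so the summary is byte-identical across reruns with the
#' same seed and configuration.
#'
#' @param outDir output directory (created if needed).
#' @param config \code{\link{analysisConfig}}.
#' @param scenario \code{\link{scenarioConfig}} for the synthetic cohort.
#' @param cohort optional pre-generated cohort (the return value of
#'   \code{\link{generateCohort}}); when supplied the generator is skipped
#'   and \code{scenario} is only used for the expression stage.
#' @return invisibly, the summary list.
#' @export
runPipeline <- function(outDir, config = analysisConfig(),
                        scenario = scenarioConfig(), cohort = NULL) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$random_seed
  cfg_hash <- .configHash(unclass(config))
  log_path <- file.path(outDir, "run.log")
  cat(sprintf("run started; seed=%d config_hash=%s\n", seed, cfg_hash),
    file = log_path)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      cat(sprintf("stage '%s' FAILED: %s\n", name, conditionMessage(e)),
        file = log_path, append = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
        call. = FALSE)
    })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    cat(sprintf("stage '%s' done in %.2fs\n", name, timings[[name]]),
      file = log_path, append = TRUE)
    res
  }

  atlas <- stage("atlas", generateAtlas(scenario$n_roi, seed = seed))
  cohort <- stage("cohort", {
    if (is.null(cohort)) generateCohort(atlas, scenario, seed = seed) else cohort
  })
  records <- cohort$records
  writeAtlas(atlas, file.path(outDir, "atlas.tsv"))
  utils::write.csv(records, file.path(outDir, "cohort.csv"), row.names = FALSE)

  conns <- stage("connectome", lapply(cohort$timeseries, computeFC))
  template <- stage("template", {
    buildTemplate(conns[records$group == "REF"],
      fraction = config$threshold_fraction, k = config$n_components,
      templateId = sprintf("ref_template_seed%d", seed))
  })
  embeddings <- stage("gradients", {
    lapply(conns, function(cc) {
      emb <- pcaEmbedding(
        cosineAffinity(thresholdTopFraction(fisherZ(cc),
          config$threshold_fraction)),
        k = config$n_components
      )
      procrustesAlign(emb, template)
    })
  })
  emb_dir <- file.path(outDir, "embeddings")
  dir.create(emb_dir, showWarnings = FALSE)
  for (nm in names(embeddings)) {
    writeEmbedding(embeddings[[nm]], file.path(emb_dir, paste0(nm, ".tsv")))
  }

  tin_idx <- which(records$group == "VS" & records$tinnitus)
  hc_idx <- which(records$group == "HC")
  group_tests <- stage("compare", {
    lapply(config$primary_dims, function(d) {
      res <- roiGroupTest(embeddings[tin_idx], embeddings[hc_idx],
        dim = d, alpha = config$fdr_alpha)
      res$config_hash <- cfg_hash
      utils::write.table(res,
        file.path(outDir, sprintf("group_stats_G%d.tsv", d)),
        sep = "\t", quote = FALSE, row.names = FALSE)
      res
    })
  })

  target <- cohort$target_roi
  seed_profile <- stage("distance", {
    seedDistanceTest(target, embeddings[tin_idx], embeddings[hc_idx],
      atlas, alpha = config$fdr_alpha, dims = config$primary_dims)
  })
  seed_profile$tests$config_hash <- cfg_hash
  utils::write.table(seed_profile$tests,
    file.path(outDir, "seed_distance.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  clin <- stage("clinical", {
    vs_pre <- records[records$group == "VS" & records$session == "pre", ]
    cohortSummary(
      transform(vs_pre, tinnitus = ifelse(tinnitus, "with", "without")),
      "tinnitus", c("sex")
    )
  })
  utils::write.table(clin, file.path(outDir, "clinical_summary.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  vs_idx <- which(records$group == "VS")
  g2_target <- vapply(embeddings[vs_idx], function(e) {
    gradientScores(e)[target, config$primary_dims[2L]]
  }, numeric(1L))
  assoc <- stage("associate", {
    tin_cases <- records$tinnitus[vs_idx]
    list(
      thi_score = spearmanAssoc(g2_target[tin_cases],
        records$thi_score[vs_idx][tin_cases]),
      thi_level = spearmanAssoc(g2_target[tin_cases],
        records$thi_level[vs_idx][tin_cases]),
      vas = spearmanAssoc(g2_target[tin_cases],
        records$vas[vs_idx][tin_cases])
    )
  })

  pred <- stage("predict", {
    tin_cases <- which(records$tinnitus[vs_idx])
    feat <- matrix(g2_target[tin_cases],
      ncol = 1L, dimnames = list(NULL, "target_G2"))
    looswr(feat,
      data.frame(
        age = records$age[vs_idx][tin_cases],
        sex = as.integer(records$sex[vs_idx][tin_cases] == "M")
      ),
      records$vas[vs_idx][tin_cases],
      alphaEnter = config$alpha_enter, alphaRemove = config$alpha_remove
    )
  })
  utils::write.table(
    data.frame(case = seq_along(pred$predictions),
      predicted = pred$predictions),
    file.path(outDir, "predictions.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )

  pls_res <- stage("pls", {
    tmap <- group_tests[[2L]]$t
    ex <- generateExpression(atlas, scenario, tmap, seed = seed)
    fit <- plsrSpatial(tmap, ex$expr)
    perm <- permutationTestPls(tmap, ex$expr,
      nPerm = config$n_permutations, seed = seed)
    enr <- gsea(rankGenes(fit), ex$gene_sets,
      nPerm = config$n_permutations, seed = seed)
    utils::write.table(enr[, setdiff(names(enr), "leading_edge")],
      file.path(outDir, "gsea.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    list(fit = fit, perm = perm, enrichment = enr)
  })

  summary <- list(
    seed = seed,
    config = unclass(config),
    config_hash = cfg_hash,
    n_scans = nrow(records),
    target_roi = target,
    variance_explained_g1_g2 = round(sum(varianceExplained(template)[1:2]), 6L),
    n_significant_rois = vapply(group_tests, function(r) sum(r$significant),
      integer(1L)),
    seed_altered_count = seed_profile$altered_count,
    community_composition = as.list(seed_profile$community_composition),
    spearman = lapply(assoc, function(a) list(rho = round(a$rho, 6L),
      p = signif(a$p, 6L))),
    prediction = list(
      mae = round(pred$mae, 6L), r = round(pred$r, 6L),
      p_r = signif(pred$p_r, 6L),
      reliable_features = pred$reliable_features
    ),
    pls = list(
      var_explained_pls1 = round(pls_res$fit$var_explained_pls1, 6L),
      perm_p = pls_res$perm$perm_p
    ),
    enrichment = if (nrow(pls_res$enrichment)) {
      list(
        top_set = pls_res$enrichment$set[1L],
        nes = round(pls_res$enrichment$nes[1L], 6L),
        q = signif(pls_res$enrichment$q[1L], 6L)
      )
    } else {
      NULL
    }
  )
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  cat(sprintf("run finished; total %.2fs\n",
    sum(unlist(timings))), file = log_path, append = TRUE)
  invisible(summary)
}
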
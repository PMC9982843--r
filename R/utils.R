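# Stage-local substreams: one user-facing seed per run, each randomized
# stage draws from a seed derived by a fixed per-stage offset, so stages
# are reproducible independently and adding a stage never perturbs others.
.stageOffsets <- c(
  atlas = 11L, timeseries = 23L, cohort = 37L, expression = 53L,
  pls_perm = 71L, gsea = 89L, pipeline = 101L
)

.deriveSeed <- function(seed, stage) {
  off <- .stageOffsets[[stage]]
  if (is.null(off)) stop("unknown rng stage: ", stage)
  (as.integer(seed) %% 20000003L) * 97L + off
}

# hash of a config list, used to tag every output of a run so tables from
# different configurations cannot be mixed undetected
.configHash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config[order(names(config))], tf,
    auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}
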
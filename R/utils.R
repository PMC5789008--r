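# Run an expression under a fixed RNG seed, restoring the caller's RNG state
# afterwards so simulators and the bootstrap do not perturb the session.
with_local_seed <- function(seed, expr) {
  seed <- as.integer(seed)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Stable hash of a configuration list, embedded in every pipeline output so
# intermediate files can be traced to the run that wrote them.
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                           digits = 15, force = TRUE,
                                           null = "null")), tf)
  unname(tools::md5sum(tf))
}
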
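# Classed conditions so callers (and the command-line driver) can react to
# specific failure modes without parsing messages.

rf_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "refates_error")))
}

rf_warn <- function(class, msg, ...) {
  warning(warningCondition(sprintf(msg, ...),
                           class = c(class, "refates_warning")))
}

# Run an expression with a locally seeded RNG, restoring the caller's RNG
# state afterwards so seeded package functions do not perturb user code.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
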
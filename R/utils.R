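# Internal helpers shared across modules.

# Evaluate `expr` under a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a per-entity child seed from a master seed; kept below 2^31 so it is a
# valid R integer seed. A Lehmer-style step keeps streams for different entities
# distinct, so subsetting entities never perturbs shared ones.
child_seed <- function(master, index) {
  m <- 2147483563
  as.integer((as.numeric(master) * 48271 + as.numeric(index) * 69621) %% m + 1)
}

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, min, max),
         call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
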
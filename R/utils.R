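# internal helpers shared across modules

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage seed derived from a run seed and a stage name,
# kept below 2^31 so it is a valid R integer.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

geometric_mean <- function(x) {
  x <- x[is.finite(x) & x > 0]
  if (length(x) == 0L) return(NA_real_)
  exp(mean(log(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
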
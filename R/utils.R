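# internal helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` under a local RNG seed, restoring the caller's RNG state.
# seed = NULL means "use the current RNG stream".
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# stop() without the call, sprintf-style
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_whole <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    fail("%s is missing required column(s): %s", what,
         paste(missing, collapse = ", "))
  }
}
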
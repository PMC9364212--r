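# internal helpers shared across modules

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
# `seed = NULL` leaves the current stream untouched (results then depend on
# the caller's RNG state, the usual R convention).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic per-stage child seed from a master seed: a stable hash of the
# stage name folded into the master seed, kept below 2^31 so it is a valid R
# integer. Adding a stage never perturbs another stage's stream.
child_seed <- function(master_seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483629
  as.integer((as.numeric(master_seed) + h) %% 2147483629)
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

is_proportion <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0 & x <= 1)
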
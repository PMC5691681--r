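`%||%` <- function(a, b) if (is.null(a)) b else a

## Run `expr` under a temporary RNG state seeded with `seed`, restoring the
## caller's .Random.seed afterwards. seed = NULL runs expr unmodified.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Numerically stable log(1 + exp(x)).
log1pexp <- function(x) ifelse(x > 33, x, log1p(exp(x)))

stop_if_not_df <- function(x, cols, what) {
  if (!is.data.frame(x)) stop(what, " must be a data.frame", call. = FALSE)
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0L) {
    stop(what, " is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}
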
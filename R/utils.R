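# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# global RNG state is untouched. seed = NULL uses (and advances) the global
# stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible child seed from a base seed; keeps results below
# .Machine$integer.max.
child_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 1103L + as.integer(index) * 12289L) %% 2147483587L
}

logit <- function(p) stats::qlogis(p)

# stats::plogis is numerically stable for arbitrarily large |x|.
logistic <- function(x) stats::plogis(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ebprob <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "ebprob_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}
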
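# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.  seed = NULL leaves the RNG stream untouched so callers
# that manage their own stream (e.g. the training loop) compose cleanly.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      stats::runif(1) # materialize .Random.seed
    }
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

kg_log <- function(..., verbose = getOption("kgprio.verbose", TRUE)) {
  if (isTRUE(verbose)) message("[kgprio] ", ...)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# logistic function, numerically safe at both tails
sigmoid <- function(x) 1 / (1 + exp(-x))

# log(1 + exp(x)) without overflow
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))
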
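#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a per-item seed from a base seed; stays inside 32-bit integer range.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + i * 16807) %% 2147483647)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop(what, " contains non-finite values", call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
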
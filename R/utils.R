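# Internal helpers: seeded RNG scoping and deterministic sub-seed derivation.

with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# deterministic child seed, kept inside 32-bit integer range
derive_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) + 0.0
  as.integer((s * 48271 + 11 * as.double(k) + 1) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    stopf("`%s` must be a single finite number >= %g", name, min)
  }
  invisible(x)
}
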
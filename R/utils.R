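`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible sub-seed from a string key and a root seed
#'
#' Every stochastic component of the package draws its randomness from a
#' stream keyed by an identifier (usually a study id) and one root seed, so
#' that adding or removing a study from a portfolio never perturbs the
#' results of the others. The hash is a plain polynomial rolling hash over
#' the UTF-8 bytes of the key, folded with the root seed modulo 2^31 - 1;
#' all intermediate products stay below 2^53 so the arithmetic is exact in
#' doubles.
#'
#' @param key character scalar, e.g. a study id.
#' @param seed integer root seed.
#' @return An integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @export
hash_seed <- function(key, seed) {
  stopifnot(length(key) == 1L, length(seed) == 1L, is.finite(seed))
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(enc2utf8(as.character(key)))) {
    h <- (h * 31 + ch) %% m
  }
  as.integer((h * 69069 + (abs(as.numeric(seed)) %% m) * 40503 + 1) %% m)
}

# stop() with a consistent class so callers/tests can catch config errors
config_error <- function(msg) {
  abort(msg, class = "pdsentinel_config_error")
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    config_error(sprintf("`%s` must be a single finite number", name))
  }
}
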
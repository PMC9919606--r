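# internal helpers shared across modules

#' Derive a reproducible sub-seed from a base seed and a stream label
#'
#' Hashes the base seed together with any number of numeric or character
#' components into an integer below 2^31, so that independent stages of the
#' pipeline (per-participant morphology, per-session noise, per-repetition
#' folds, per-model permutations) consume disjoint, reproducible RNG streams.
#'
#' @param seed integer base seed.
#' @param ... numeric or character stream labels.
#' @return a single integer in [1, 2^31 - 2].
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.double(seed %% m)
  for (comp in list(...)) {
    if (is.character(comp)) comp <- sum(utf8ToInt(comp) * seq_along(utf8ToInt(comp)))
    for (x in as.double(comp)) {
      h <- (h * 48271 + (x %% m) + 1) %% m
    }
  }
  as.integer(h %% (m - 2) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_input("`%s` must be a finite numeric scalar", name)
  if (x < lower || (strict_lower && x <= lower) || x > upper)
    stop_input("`%s` = %g is outside its valid range", name, x)
  invisible(x)
}
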
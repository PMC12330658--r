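# Seed management: one root seed per top-level call; named child streams so
# that independent operations (labels, covariates, scores, replicates) draw
# from independent, reproducible streams.

#' Derive a child seed from a root seed and a stream tag
#'
#' Deterministically maps a root seed and a character tag to an integer seed
#' below 2^31, so that distinct operations within one simulation use
#' independent but fully reproducible random streams.
#'
#' @param seed integer root seed.
#' @param tag character stream label.
#' @return A single integer seed.
#' @examples
#' derive_seed(1, "labels")
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes)) %% 2147483647
  # 2147483629 is prime and < 2^31; arithmetic stays exact in doubles
  m <- 2147483629
  v <- ((abs(seed) %% m) * 48271) %% m
  as.integer((v + h) %% m)
}

# Evaluate expr under a given seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else suppressWarnings(rm(".Random.seed", envir = env))
  }, add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)
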
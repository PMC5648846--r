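#' Derive a child RNG seed from a master seed and a stream key
#'
#' All randomness in the package flows from one master seed; independent
#' streams (one per axon, one for synaptogenesis, one per optimizer replicate,
#' ...) are derived by hashing the master seed together with a string key.
#' This keeps every stream reproducible and independent of scheduling order,
#' which is what makes parallel growth at `s = 0` bit-identical to growing
#' each axon alone.
#'
#' @param seed Integer master seed.
#' @param key Character scalar naming the stream.
#' @return An integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @examples
#' derive_seed(1, "axon/12/primary")
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(key))
  # polynomial rolling hash over the key bytes, folded with the master seed;
  # all intermediates stay below 2^53 so double arithmetic is exact
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  h <- (h + (seed %% 2147483647) * 1103515245) %% 2147483629 + 1
  as.integer(h)
}

#' Wrap angles to the interval (-pi, pi]
#'
#' @param a Numeric vector of angles in radians.
#' @return Wrapped angles.
#' @examples
#' wrap_angle(c(0, 3 * pi, -pi))
#' @export
wrap_angle <- function(a) {
  w <- a - (2 * pi) * floor((a + pi) / (2 * pi))
  w[w <= -pi] <- pi   # closed at +pi, open at -pi
  w
}

abort_config <- function(msg) stop(msg, call. = FALSE)

# short stable hash of an R object, used to stamp outputs with the config
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10, force = TRUE)
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
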
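deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Derive a named random substream seed
#'
#' All randomness in the package flows from one user seed; independent
#' components (optimizer starts, Monte-Carlo trials, mask draws, noise) draw
#' from substreams derived deterministically from `(seed, name)` so that
#' adding one component never perturbs another.
#'
#' @param seed integer master seed.
#' @param name character label of the substream.
#' @return an integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, name) {
  h <- 0
  for (c in utf8ToInt(name)) h <- (h * 31 + c) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
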
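# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.  All stochastic operations in the package route through this
# so that identical (config, seed) pairs give bit-identical output.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
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
  force(code)
}

# Derive a child seed from a parent seed and a stream index, staying
# within the 32-bit integer range R requires.
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 7919 + 104729 * stream) %% 2147483647)
}

#' Standard channel montage
#'
#' The eight-channel frontal/parietal montage used throughout the package,
#' split into the frontal and parietal groups used for artifact statistics
#' and neurometric channel sets.
#'
#' @return Character vector of the eight channel labels, in canonical order.
#' @export
#' @examples
#' bci_channels()
bci_channels <- function() {
  c("AFz", "AF3", "AF4", "AF7", "AF8", "Pz", "P3", "P4")
}

#' @rdname bci_channels
#' @export
frontal_channels <- function() c("AFz", "AF3", "AF4", "AF7", "AF8")

#' @rdname bci_channels
#' @export
parietal_channels <- function() c("Pz", "P3", "P4")

# Half-sine blink template: `dur_s` seconds at `srate` Hz, unit peak.
blink_template <- function(srate, dur_s = 0.3) {
  n <- max(2L, round(srate * dur_s))
  sin(pi * seq(0, 1, length.out = n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pbci <- function(...) stop(..., call. = FALSE)
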
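# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Commercial ("half-up") rounding to the nearest integer, as used for all
#' reported economics figures. `base::round()` rounds half to even, which is
#' the wrong convention for currency and day counts in reports.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.4, -0.5))
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Stop with a classed condition so callers/tests can distinguish error kinds.
abort <- function(msg, class) {
  stop(structure(
    class = c(class, "ihctriage_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Derive a per-component seed from a master seed. Keeps every derived seed a
# valid 32-bit integer whatever small master seed the caller supplies.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + offset * 104729) %% 2147483647)
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

is_count <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}

stopifnot_rgb <- function(img) {
  if (length(dim(img)) != 3L || dim(img)[3] < 3L) {
    abort("expected an RGB raster (h x w x 3 array); got a single-channel or malformed input",
          "ihctriage_input_error")
  }
}
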
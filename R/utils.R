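# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed, runs \code{expr}, and restores the previous global RNG state
#' so that seeded generation inside the package does not disturb the caller's
#' random stream.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible substream seed from a master seed
#'
#' A documented splitting rule: a 31-bit multiplicative hash of the master
#' seed and a stream identifier. Identical (master, id) pairs always map to
#' the same substream seed, and distinct ids give well-separated streams.
#'
#' @param master integer master seed.
#' @param id nonnegative integer stream identifier.
#' @return An integer seed in [0, 2^31 - 1).
#' @export
substream_seed <- function(master, id) {
  m <- 2147483647 # 2^31 - 1 (Mersenne prime)
  h <- (as.numeric(master) %% m + 1) * 48271 %% m
  h <- (h * 69621 + as.numeric(id) * 16807 + 12345) %% m
  as.integer(h)
}

# next fast FFT length (multiples of 2,3,5)
next_fft_len <- function(n) {
  stats::nextn(n, factors = c(2, 3, 5))
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is_scalar_num(x) || x < lower || x > upper)
    stop_input(sprintf("`%s` must be a finite number in [%s, %s]", name,
                       format(lower), format(upper)))
  invisible(x)
}
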
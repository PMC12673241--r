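#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the previous state on exit, so package internals never disturb
#' the user's random number stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a master seed
#'
#' One master seed drives the whole pipeline; each stage gets a
#' deterministic child seed so stages can be re-run in isolation.
#'
#' @param seed Master integer seed.
#' @param label Stage label, e.g. `"tracks"`.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
deriveSeed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 1000003
  as.integer(((abs(seed) %% 2147483647) * 2654435 + h) %% 2147483646) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Local clock hour of a timestamp
#'
#' Local time is UTC plus a fixed configurable offset; daylight filtering
#' uses printed clock hours, not solar elevation.
#'
#' @param time `POSIXct` timestamps (UTC).
#' @param tzOffset Hours to add to UTC (default 1).
#' @return Integer hour of day in `[0, 23]`.
#' @export
localHour <- function(time, tzOffset = 1) {
  (as.integer(format(time, "%H", tz = "UTC")) + as.integer(tzOffset)) %% 24L
}

## Gaussian smoothing of a matrix by FFT convolution (periodic padding is
## avoided by embedding in a zero-padded domain and renormalising).
gaussSmooth <- function(m, sigmaCells) {
  if (sigmaCells <= 0) return(m)
  nx <- nrow(m); ny <- ncol(m)
  px <- 2L * nx; py <- 2L * ny
  gx <- stats::dnorm(c(0:(px %/% 2), -((px - px %/% 2 - 1):1)), sd = sigmaCells)
  gy <- stats::dnorm(c(0:(py %/% 2), -((py - py %/% 2 - 1):1)), sd = sigmaCells)
  ker <- outer(gx, gy)
  ker <- ker / sum(ker)
  pad <- matrix(0, px, py); pad[1:nx, 1:ny] <- m
  one <- matrix(0, px, py); one[1:nx, 1:ny] <- 1
  num <- Re(fft(fft(pad) * fft(ker), inverse = TRUE)) / (px * py)
  den <- Re(fft(fft(one) * fft(ker), inverse = TRUE)) / (px * py)
  (num / pmax(den, 1e-12))[1:nx, 1:ny]
}
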
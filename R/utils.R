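# Internal numerical helpers shared across modules.

#' Trapezoidal integral
#'
#' Integrate tabulated values over an increasing grid by the trapezoid rule.
#' `NaN` values in `y` propagate to the result with a warning so that
#' downstream AUC summaries flag, rather than silently drop, bad curves.
#'
#' @param y numeric values at the grid points.
#' @param x strictly increasing numeric grid, same length as `y`.
#' @return the trapezoidal integral, a single numeric value.
#' @examples
#' trapz(c(1, 3), c(0.1, 0.2))  # 0.2
#' @export
trapz <- function(y, x) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("`x` and `y` must have equal length >= 2")
  if (any(diff(x) <= 0)) stop("`x` must be strictly increasing")
  if (anyNA(y) || any(is.nan(y))) warning("NaN/NA in curve; integral is NaN")
  sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)
}

# round() in R is round-half-even; edge counts use the stated
# half-away-from-zero convention so they are reproducible across platforms.
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# Deterministic 32-bit substream seed from a base seed and integer keys.
# Keeps every derived seed in [1, 2^31 - 2] so set.seed() always accepts it.
mix_seed <- function(seed, ...) {
  m <- 2147483629
  h <- as.numeric(seed) %% m
  for (k in c(...)) h <- (h * 48271 + as.numeric(k) + 1) %% m
  as.integer(h + 1)
}

# Run code under a seed without clobbering the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
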
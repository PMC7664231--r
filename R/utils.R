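#' @importFrom rlang %||% abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom stats fft rnorm runif sd median qt approx coef
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All stochastic routines in the package route through
# this so that identical spec + seed gives bit-identical output.
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# linear detrend + mean-centre; returns residuals of an order-1 fit
detrend_linear <- function(x) {
  n <- length(x)
  t <- seq_len(n)
  tc <- t - mean(t)
  slope <- sum(tc * x) / sum(tc^2)
  x - mean(x) - slope * tc
}
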
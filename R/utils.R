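#' @useDynLib vasctort, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx coef cor.test glm lm median plogis pnorm qbeta
#'   qlnorm qnorm quantile rbinom rnorm runif sd shapiro.test t.test
#'   wilcox.test binomial uniroot optim setNames
#' @importFrom utils read.csv write.csv
NULL

#' Derive a reproducible substream seed from a master seed
#'
#' All stochastic stages draw their seeds from a single master integer through
#' named substreams, so any stage can be re-run in isolation with the same
#' randomness it saw inside a full pipeline run.
#'
#' @param master integer master seed.
#' @param stream character substream name.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(1, "rasterize") != substream_seed(1, "cohort")
substream_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stream))
  m <- 2147483647 # 2^31 - 1, Mersenne prime; arithmetic stays exact in doubles
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% m
  as.integer(((abs(master) %% m) * 48271 + h) %% m)
}

# evaluate a thunk under a temporary RNG state, restoring the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; cohort percentages here follow the
#' convention of rounding halves away from zero (93/213 -> 43.7).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

vnorm <- function(v) sqrt(sum(v^2))

# max perpendicular distance from rows of `pts` to the infinite line through
# a and b (the chord axis)
max_line_distance <- function(pts, a, b) {
  u <- (b - a) / vnorm(b - a)
  rel <- sweep(pts, 2, a)
  proj <- as.vector(rel %*% u)
  perp <- rel - outer(proj, u)
  max(sqrt(rowSums(perp^2)))
}
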
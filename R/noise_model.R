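#' Poisson-Gaussian detector noise model
#'
#' Parameterizes the mixed noise of photon-counting detectors as
#' `z = alpha * p + n`, with `p ~ Poisson(y)` the photon count at expected
#' photon flux `y`, `alpha` the detector gain (ADU/photon) and
#' `n ~ N(mu, sigma^2)` additive read-out noise (ADU). For a clean intensity
#' `y_adu = alpha * y` this gives `E[z] = y_adu + mu` and
#' `Var[z] = alpha * y_adu + sigma^2`.
#'
#' @param alpha gain in ADU/photon, > 0.
#' @param sigma Gaussian standard deviation in ADU, >= 0.
#' @param mu Gaussian offset in ADU.
#' @return an object of class `pg_model`.
#' @examples
#' pg_model(alpha = 1, sigma = 2)
#' @export
pg_model <- function(alpha = 1, sigma = 0, mu = 0) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0) {
    stop("alpha (gain) must be a single positive number", call. = FALSE)
  }
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  structure(list(alpha = alpha, sigma = sigma, mu = mu), class = "pg_model")
}

#' @export
print.pg_model <- function(x, ...) {
  cat(sprintf("<pg_model> alpha=%g ADU/photon, sigma=%g ADU, mu=%g ADU\n",
              x$alpha, x$sigma, x$mu))
  invisible(x)
}

# run code with a temporary RNG state seeded from `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# deterministic per-stage child seeds derived from one global seed
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 13 * as.numeric(k)) %% 2147483647)
}
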
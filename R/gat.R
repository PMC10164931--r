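#' Forward generalized Anscombe transform
#'
#' Stabilizes the variance of Poisson-Gaussian data so that the transformed
#' noise is approximately Gaussian with unit standard deviation:
#' `f(z) = (2/alpha) * sqrt(alpha*z + (3/8)*alpha^2 + sigma^2 - alpha*mu)`.
#' Values with non-positive radicand map to 0.
#'
#' In the moderate/high-count regime (photon means of roughly 20 and above)
#' the transformed sample variance is close to 1, which is what makes a plain
#' Gaussian denoiser applicable to raw detector counts.
#'
#' @param z numeric array/vector of intensities in ADU.
#' @param model a [pg_model()].
#' @return numeric object of the same shape, stabilized domain.
#' @examples
#' gat_forward(0, pg_model(1, 0, 0))  # 2*sqrt(3/8)
#' @export
gat_forward <- function(z, model) {
  stopifnot(inherits(model, "pg_model"))
  a <- model$alpha
  rad <- a * z + 0.375 * a^2 + model$sigma^2 - a * model$mu
  out <- z
  out[] <- ifelse(rad > 0, (2 / a) * sqrt(pmax(rad, 0)), 0)
  out
}

#' Inverse generalized Anscombe transform
#'
#' @param d stabilized values (output domain of [gat_forward()]).
#' @param model a [pg_model()].
#' @param mode `"algebraic"` inverts `gat_forward` exactly on its range;
#'   `"exact_unbiased"` applies the closed-form approximation of the exact
#'   unbiased inverse of the unit-gain Anscombe transform,
#'   `D^2/4 + sqrt(3/2)/(4 D) - 11/(8 D^2) + (5/8) sqrt(3/2) / D^3 - 1/8`,
#'   generalized to `(alpha, sigma, mu)` by the standard variable substitution
#'   `D' = (alpha/2) * D`, `y = alpha * I(D') - sigma^2/alpha + mu` evaluated on
#'   an effective unit-gain scale. The unbiased mode removes the low-count bias
#'   of the algebraic inverse.
#' @return intensities in ADU; negatives are clipped to 0.
#' @export
gat_inverse <- function(d, model, mode = c("algebraic", "exact_unbiased")) {
  stopifnot(inherits(model, "pg_model"))
  mode <- match.arg(mode)
  a <- model$alpha
  if (mode == "algebraic") {
    # invert (2/a)*sqrt(a z + 3/8 a^2 + s^2 - a mu)
    out <- (d * a / 2)^2 / a - 0.375 * a - model$sigma^2 / a + model$mu
  } else {
    # reduce to unit-gain Anscombe: D_p = f(z) is, in photon units,
    # 2*sqrt(p + 3/8 + s'^2) with p = (z - mu)/a, s' = sigma/a.
    # The exact-unbiased inverse of 2*sqrt(p + 3/8) is the closed form below;
    # the additive Gaussian variance term translates the result by -s'^2.
    dd <- pmax(d, 2 * sqrt(0.375))
    inv_pois <- dd^2 / 4 + sqrt(1.5) / (4 * dd) - 11 / (8 * dd^2) +
      (5 / 8) * sqrt(1.5) / dd^3 - 1 / 8
    p <- inv_pois - (model$sigma / a)^2
    out <- a * p + model$mu
  }
  neg <- sum(out < 0)
  if (neg > 0 && mode == "exact_unbiased") {
    # clipping at zero is the defined behaviour for sub-background values
  }
  out[out < 0] <- 0
  out
}

#' Estimate the Gaussian noise standard deviation of an image
#'
#' Robust estimator based on the median absolute deviation of a 3x3 Laplacian
#' pseudo-residual. The Laplacian annihilates locally planar image structure,
#' and the MAD makes the estimate insensitive to the sparse large residuals
#' produced by edges, so the estimate reflects the additive noise floor rather
#' than image content. A constant image returns 0 with a warning.
#'
#' @param image 2D numeric matrix, at least 16 x 16.
#' @return estimated noise standard deviation (ADU).
#' @export
estimate_noise_sigma <- function(image) {
  stopifnot(is.matrix(image))
  if (nrow(image) < 16 || ncol(image) < 16) {
    stop("image must be at least 16 x 16 for noise estimation", call. = FALSE)
  }
  if (max(image) == min(image)) {
    warning("constant image: nothing to estimate, returning 0", call. = FALSE)
    return(0)
  }
  ny <- nrow(image); nx <- ncol(image)
  i <- 2:(ny - 1); j <- 2:(nx - 1)
  r <- image[i - 1, j - 1] - 2 * image[i - 1, j] + image[i - 1, j + 1] -
    2 * image[i, j - 1] + 4 * image[i, j] - 2 * image[i, j + 1] +
    image[i + 1, j - 1] - 2 * image[i + 1, j] + image[i + 1, j + 1]
  # r ~ N(0, 36 sigma^2) for i.i.d. Gaussian noise
  stats::median(abs(r)) / (0.6744898 * 6)
}

#' Build a tiled noise-estimation image from a stack
#'
#' Picks `k = min(max_slices, n)` slices at indices
#' `round(seq(first, last, length.out = k))` spaced evenly through the slice
#' axis and arranges them in a `ceiling(sqrt(k))`-column grid mosaic
#' (zero-padded trailing cells). Estimating noise on the mosaic pools
#' information across the stack and is more accurate than a single-slice
#' estimate.
#'
#' @param stack single-channel `stack5d` (slices taken along z within t = 1,
#'   or along t when Z = 1).
#' @param max_slices maximum number of slices in the mosaic (default 10).
#' @return 2D matrix mosaic.
#' @export
build_estimation_tile <- function(stack, max_slices = 10L) {
  validate_stack5d(stack)
  d <- dim(stack$data)
  if (d[3] != 1L) stop("build_estimation_tile expects a single channel",
                       call. = FALSE)
  along_z <- d[2] >= d[1]
  n <- if (along_z) d[2] else d[1]
  k <- min(max_slices, n)
  idx <- unique(round(seq(1, n, length.out = k)))
  k <- length(idx)
  ncol_g <- ceiling(sqrt(k))
  nrow_g <- ceiling(k / ncol_g)
  mos <- matrix(0, nrow_g * d[4], ncol_g * d[5])
  for (m in seq_along(idx)) {
    gi <- (m - 1) %/% ncol_g
    gj <- (m - 1) %% ncol_g
    sl <- if (along_z) stack$data[1, idx[m], 1, , ] else stack$data[idx[m], 1, 1, , ]
    mos[gi * d[4] + seq_len(d[4]), gj * d[5] + seq_len(d[5])] <-
      matrix(sl, d[4], d[5])
  }
  mos
}

#' Linear rescale to the unit interval
#'
#' Maps `[min, max]` linearly onto `[0, 1]` and records the scale so the map
#' can be undone exactly. A constant input maps to all zeros and is flagged
#' degenerate.
#'
#' @param x numeric array with finite values.
#' @return list with `data` (rescaled), `lo`, `hi`, `degenerate`.
#' @seealso [unrescale_unit()]
#' @export
rescale_unit <- function(x) {
  if (any(!is.finite(x))) stop("rescale_unit requires finite values", call. = FALSE)
  lo <- min(x); hi <- max(x)
  if (hi <= lo) {
    y <- x; y[] <- 0
    return(list(data = y, lo = lo, hi = hi, degenerate = TRUE))
  }
  list(data = (x - lo) / (hi - lo), lo = lo, hi = hi, degenerate = FALSE)
}

#' Undo a [rescale_unit()] mapping
#' @param scaled list returned by [rescale_unit()] (optionally with its `data`
#'   replaced by filtered values of the same shape).
#' @return array on the original intensity scale.
#' @export
unrescale_unit <- function(scaled) {
  if (isTRUE(scaled$degenerate)) {
    y <- scaled$data; y[] <- scaled$lo
    return(y)
  }
  scaled$data * (scaled$hi - scaled$lo) + scaled$lo
}
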
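#' Parameters for feature-based translation estimation
#'
#' Defaults follow the common stack-alignment settings for multi-scale
#' feature registration of microscopy frames: initial blur 1.5 px, 3 steps
#' per scale octave, octaves bounded between 64 and 512 px, descriptor
#' sampled on an 8 x 8 grid, translation-only transform model.
#'
#' @param initial_blur base Gaussian blur in px.
#' @param steps_per_octave scale steps per octave.
#' @param min_image_size,max_image_size octave pyramid bounds in px.
#' @param descriptor_size descriptor grid size (bins per side).
#' @param match_ratio nearest/second-nearest distance ratio threshold.
#' @param min_inliers minimum consensus matches for a valid pair.
#' @param inlier_epsilon consensus radius in px.
#' @param peak_thresh detection threshold on the difference-of-Gaussian
#'   response (image normalized to `[0, 1]`).
#' @return object of class `sift_params`.
#' @export
sift_params <- function(initial_blur = 1.5, steps_per_octave = 3L,
                        min_image_size = 64L, max_image_size = 512L,
                        descriptor_size = 8L, match_ratio = 0.92,
                        min_inliers = 7L, inlier_epsilon = 3,
                        peak_thresh = 0.004) {
  stopifnot(min_image_size < max_image_size, steps_per_octave >= 1)
  structure(list(initial_blur = initial_blur,
                 steps_per_octave = as.integer(steps_per_octave),
                 min_image_size = as.integer(min_image_size),
                 max_image_size = as.integer(max_image_size),
                 descriptor_size = as.integer(descriptor_size),
                 match_ratio = match_ratio,
                 min_inliers = as.integer(min_inliers),
                 inlier_epsilon = inlier_epsilon,
                 peak_thresh = peak_thresh), class = "sift_params")
}

#' Per-frame contrast enhancement by saturated histogram stretching
#'
#' Clips the frame histogram at the `saturated/2` quantile on each tail and
#' maps the clipped range linearly onto `[0, target_max]`. A constant frame
#' passes through unchanged.
#'
#' @param frame 2D numeric matrix.
#' @param saturated total saturated pixel fraction (default 0.01, i.e. 0.5%
#'   per tail).
#' @param normalize if FALSE, only clip without range expansion.
#' @param target_max top of the output range (default: the frame maximum).
#' @return stretched 2D matrix.
#' @export
enhance_contrast_frame <- function(frame, saturated = 0.01, normalize = TRUE,
                                   target_max = NULL) {
  stopifnot(is.matrix(frame))
  if (max(frame) == min(frame)) return(frame)
  if (is.null(target_max)) target_max <- max(frame)
  q <- stats::quantile(frame, c(saturated / 2, 1 - saturated / 2),
                       names = FALSE)
  if (q[2] <= q[1]) return(frame)
  out <- pmin(pmax(frame, q[1]), q[2])
  if (normalize) out <- (out - q[1]) / (q[2] - q[1]) * target_max
  out
}

#' Build the registration channel of a multichannel stack
#'
#' Sums all detection channels frame by frame in 32-bit float, applies
#' [enhance_contrast_frame()] per frame over the full bit-depth range, and
#' quantizes back to the input bit depth. Concentrating the signal of every
#' channel into one maximizes the features available to drift estimation.
#'
#' @param stack a `stack5d` with `C >= 1`.
#' @param saturated saturated fraction for the contrast stretch.
#' @return single-channel integer `stack5d` with the same `(t, z, y, x)`.
#' @export
build_registration_channel <- function(stack, saturated = 0.01) {
  validate_stack5d(stack)
  d <- dim(stack$data)
  lim <- 2^stack$bit_depth - 1
  out <- array(0, c(d[1], d[2], 1L, d[4], d[5]))
  for (ti in seq_len(d[1])) for (zi in seq_len(d[2])) {
    fr <- matrix(0, d[4], d[5])
    for (ci in seq_len(d[3])) fr <- fr + matrix(stack$data[ti, zi, ci, , ],
                                                d[4], d[5])
    fr <- enhance_contrast_frame(fr, saturated = saturated, normalize = TRUE,
                                 target_max = lim)
    out[ti, zi, 1, , ] <- fr
  }
  suppressMessages(quantize_to_uint(
    stack5d(out, voxel_size = stack$voxel_size,
            frame_interval = stack$frame_interval, bit_depth = 32L,
            channel_names = "registration", is_float = TRUE),
    bit_depth = stack$bit_depth))
}

# ---- multi-scale difference-of-Gaussian keypoints + patch descriptors ----

# downsample by 2 with 2x2 block averaging
.halve <- function(img) {
  ny <- nrow(img) %/% 2L; nx <- ncol(img) %/% 2L
  0.25 * (img[2 * seq_len(ny) - 1, 2 * seq_len(nx) - 1] +
          img[2 * seq_len(ny) - 1, 2 * seq_len(nx)] +
          img[2 * seq_len(ny), 2 * seq_len(nx) - 1] +
          img[2 * seq_len(ny), 2 * seq_len(nx)])
}

# detect keypoints with sub-pixel (y, x), plus normalized patch descriptors
# sampled on a descriptor_size^2 grid; coordinates in full-resolution px
.detect_features <- function(img, params) {
  rng <- range(img)
  img <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1]) else img * 0
  scale <- 1
  while (max(dim(img)) > params$max_image_size) {
    img <- .halve(img); scale <- scale * 2
  }
  kps <- NULL; descs <- NULL
  fd <- params$descriptor_size
  repeat {
    if (min(dim(img)) < params$min_image_size) break
    s <- params$steps_per_octave
    k <- 2^(1 / s)
    sig <- params$initial_blur * k^(0:(s + 2))
    gs <- vector("list", length(sig))
    gs[[1]] <- .gauss_blur2d_cpp(img, sig[1])
    for (i in 2:length(sig)) {
      inc <- sqrt(max(sig[i]^2 - sig[i - 1]^2, 1e-6))
      gs[[i]] <- .gauss_blur2d_cpp(gs[[i - 1]], inc)
    }
    nd <- length(sig) - 1L
    dog <- array(0, c(dim(img), nd))
    for (i in seq_len(nd)) dog[, , i] <- gs[[i + 1]] - gs[[i]]
    ext <- .dog_extrema_cpp(as.numeric(dog), dim(dog), params$peak_thresh,
                            border = fd + 2L)
    if (nrow(ext) > 0) {
      for (r in seq_len(nrow(ext))) {
        y <- ext[r, 1]; x <- ext[r, 2]; si <- ext[r, 3] + 1
        g <- gs[[si]]
        step <- max(1L, round(sig[si]))
        yy <- round(y) + step * (seq_len(fd) - (fd + 1) / 2)
        xx <- round(x) + step * (seq_len(fd) - (fd + 1) / 2)
        yy <- round(yy); xx <- round(xx)
        if (min(yy) < 1 || min(xx) < 1 || max(yy) > nrow(g) ||
            max(xx) > ncol(g)) next
        p <- g[yy, xx]
        p <- p - mean(p)
        nrm <- sqrt(sum(p^2))
        if (nrm < 1e-8) next
        kps <- rbind(kps, c((y) * scale, (x) * scale))
        descs <- rbind(descs, as.numeric(p / nrm))
      }
    }
    if (min(dim(img)) %/% 2L < params$min_image_size) break
    img <- .halve(img); scale <- scale * 2
  }
  list(kp = kps, desc = descs)
}

# robust translation from feature matches between two frames;
# returns list(shift = c(dx, dy), n_inliers, ok)
.pair_translation <- function(fa, fb, frame_a, frame_b, params) {
  if (is.null(fa$kp) || is.null(fb$kp) ||
      nrow(fa$kp) < 2 || nrow(fb$kp) < 2) {
    return(list(shift = c(0, 0), n_inliers = 0L, ok = FALSE))
  }
  # unit-norm descriptors: squared distance = 2 - 2 * dot
  dots <- fa$desc %*% t(fb$desc)
  d2 <- pmax(2 - 2 * dots, 0)
  best <- apply(d2, 1, function(v) {
    o <- order(v)[1:2]; c(o[1], v[o[1]], v[o[2]])
  })
  keep <- sqrt(best[2, ]) < params$match_ratio * sqrt(pmax(best[3, ], 1e-12))
  if (sum(keep) < 2) return(list(shift = c(0, 0), n_inliers = 0L, ok = FALSE))
  ia <- which(keep); ib <- best[1, keep]
  # candidate shifts (dx, dy): position in A minus position in B
  dy <- fa$kp[ia, 1] - fb$kp[ib, 1]
  dx <- fa$kp[ia, 2] - fb$kp[ib, 2]
  n <- length(dx)
  best_n <- 0L; best_in <- NULL
  for (i in seq_len(n)) {
    inl <- which(abs(dx - dx[i]) <= params$inlier_epsilon &
                 abs(dy - dy[i]) <= params$inlier_epsilon)
    if (length(inl) > best_n) { best_n <- length(inl); best_in <- inl }
  }
  if (best_n < params$min_inliers) {
    return(list(shift = c(0, 0), n_inliers = best_n, ok = FALSE))
  }
  est <- c(mean(dx[best_in]), mean(dy[best_in]))
  est <- .refine_shift_ncc(frame_a, frame_b, est)
  list(shift = est, n_inliers = best_n, ok = TRUE)
}

# parabolic sub-pixel refinement of an integer shift by local normalized
# cross-correlation: frame_b shifted by (dx, dy) should match frame_a
.refine_shift_ncc <- function(a, b, est) {
  d0 <- round(est)
  # exclude the zero-fill band introduced by the translation itself
  m <- ceiling(max(abs(d0))) + 2
  ncc <- function(dx, dy) {
    ny <- nrow(a); nx <- ncol(a)
    ya <- (max(1, 1 + dy) + m):(min(ny, ny + dy) - m)
    xa <- (max(1, 1 + dx) + m):(min(nx, nx + dx) - m)
    if (length(ya) < 8 || length(xa) < 8 || ya[1] > ya[length(ya)] ||
        xa[1] > xa[length(xa)]) return(NA_real_)
    yb <- ya - dy; xb <- xa - dx
    va <- a[ya, xa]; vb <- b[yb, xb]
    sa <- stats::sd(va); sb <- stats::sd(vb)
    if (sa == 0 || sb == 0) return(NA_real_)
    mean((va - mean(va)) * (vb - mean(vb))) / (sa * sb)
  }
  cs <- matrix(NA_real_, 3, 3)
  for (i in -1:1) for (j in -1:1) cs[i + 2, j + 2] <- ncc(d0[1] + j, d0[2] + i)
  if (any(is.na(cs)) || which.max(cs) != 5) return(est)
  offx <- 0.5 * (cs[2, 1] - cs[2, 3]) / (cs[2, 1] - 2 * cs[2, 2] + cs[2, 3])
  offy <- 0.5 * (cs[1, 2] - cs[3, 2]) / (cs[1, 2] - 2 * cs[2, 2] + cs[3, 2])
  if (!is.finite(offx) || abs(offx) > 0.5) offx <- 0
  if (!is.finite(offy) || abs(offy) > 0.5) offy <- 0
  c(d0[1] + offx, d0[2] + offy)
}

#' Estimate per-frame translations of a single-channel series
#'
#' For each consecutive frame pair (or each frame against frame 1 in
#' fixed-reference mode): multi-scale difference-of-Gaussian keypoints with
#' sub-pixel localization, normalized patch descriptors, nearest-neighbour
#' matching with a ratio test, and a consensus translation-only fit with
#' outlier rejection, refined to sub-pixel precision by a local normalized
#' cross-correlation parabola. Pairwise shifts are composed into
#' shifts-to-reference (frame 1). A pair with fewer than `min_inliers`
#' consensus matches never aborts the series: its relative shift is set to
#' `(0, 0)` and flagged.
#'
#' @param stack single-channel `stack5d` (the registration channel).
#' @param params a [sift_params()].
#' @param axis `"t"` or `"z"` - which axis enumerates the frames.
#' @param mode `"sequential"` (pairwise, composed) or `"fixed_ref"` (every
#'   frame against frame 1).
#' @return tibble (`translation_series`) with columns `frame`, `dx`, `dy`
#'   (px; the correction mapping each frame into the frame-1 coordinate
#'   system), `n_inliers`, `flagged`.
#' @export
estimate_translations <- function(stack, params = sift_params(),
                                  axis = c("t", "z"),
                                  mode = c("sequential", "fixed_ref")) {
  validate_stack5d(stack)
  axis <- match.arg(axis); mode <- match.arg(mode)
  d <- dim(stack$data)
  if (d[3] != 1L) stop("estimate_translations expects a single channel",
                       call. = FALSE)
  n <- if (axis == "t") d[1] else d[2]
  if (n < 2L) stop("need at least 2 frames along ", axis, call. = FALSE)
  if (min(d[4], d[5]) < params$min_image_size) {
    stop("frame size is below min_image_size", call. = FALSE)
  }
  get_frame <- function(i) {
    if (axis == "t") matrix(stack$data[i, 1, 1, , ], d[4], d[5])
    else matrix(stack$data[1, i, 1, , ], d[4], d[5])
  }
  feats <- vector("list", n)
  frames <- lapply(seq_len(n), get_frame)
  for (i in seq_len(n)) feats[[i]] <- .detect_features(frames[[i]], params)

  dx <- numeric(n); dy <- numeric(n)
  ninl <- integer(n); flag <- logical(n)
  if (mode == "sequential") {
    for (i in 2:n) {
      # shift of frame i relative to frame i-1 (content displacement)
      pr <- .pair_translation(feats[[i]], feats[[i - 1]],
                              frames[[i]], frames[[i - 1]], params)
      rel <- if (pr$ok) pr$shift else c(0, 0)
      dx[i] <- dx[i - 1] + rel[1]
      dy[i] <- dy[i - 1] + rel[2]
      ninl[i] <- pr$n_inliers; flag[i] <- !pr$ok
    }
  } else {
    for (i in 2:n) {
      pr <- .pair_translation(feats[[i]], feats[[1]],
                              frames[[i]], frames[[1]], params)
      if (pr$ok) { dx[i] <- pr$shift[1]; dy[i] <- pr$shift[2] }
      ninl[i] <- pr$n_inliers; flag[i] <- !pr$ok
    }
  }
  out <- tibble::tibble(frame = seq_len(n), dx = -dx, dy = -dy,
                        n_inliers = ninl, flagged = flag)
  class(out) <- c("translation_series", class(out))
  out
}

#' Apply a translation series to every channel of a stack
#'
#' Translates frame `i` by `(dx[i], dy[i])` with bilinear interpolation and
#' zero fill; geometry, calibration and channel count are unchanged.
#'
#' @param stack a `stack5d`.
#' @param series tibble with `dx`, `dy` per frame (as from
#'   [estimate_translations()]).
#' @param axis `"t"` or `"z"`.
#' @return translated `stack5d`.
#' @export
apply_translations <- function(stack, series, axis = c("t", "z")) {
  validate_stack5d(stack)
  axis <- match.arg(axis)
  d <- dim(stack$data)
  n <- if (axis == "t") d[1] else d[2]
  if (nrow(series) != n) {
    stop("series length (", nrow(series), ") must equal frame count (", n, ")",
         call. = FALSE)
  }
  out <- array(0, d)
  for (i in seq_len(n)) for (ci in seq_len(d[3])) {
    apply_one <- function(m) .translate_bilinear_cpp(m, series$dx[i],
                                                     series$dy[i])
    if (axis == "t") {
      for (zi in seq_len(d[2])) {
        out[i, zi, ci, , ] <- apply_one(matrix(stack$data[i, zi, ci, , ],
                                               d[4], d[5]))
      }
    } else {
      for (ti in seq_len(d[1])) {
        out[ti, i, ci, , ] <- apply_one(matrix(stack$data[ti, i, ci, , ],
                                               d[4], d[5]))
      }
    }
  }
  res <- stack_like(stack, out, bit_depth = 32L, is_float = TRUE)
  if (!stack$is_float) {
    res <- suppressMessages(quantize_to_uint(res, stack$bit_depth))
  }
  res
}

#' Drift-correct a multichannel stack
#'
#' The full 2D registration workflow: build the summed, contrast-stretched
#' registration channel; estimate per-frame translations on it; apply the
#' translations to every original channel; discard the registration channel.
#'
#' @param stack a `stack5d` with at least 2 frames along `axis`.
#' @param params a [sift_params()].
#' @param axis `"t"` (time series) or `"z"` (volumetric stack).
#' @param mode see [estimate_translations()].
#' @return list with `stack` (aligned, original channels only) and `shifts`
#'   (the translation series tibble).
#' @export
register_2d <- function(stack, params = sift_params(), axis = c("t", "z"),
                        mode = c("sequential", "fixed_ref")) {
  axis <- match.arg(axis); mode <- match.arg(mode)
  reg <- build_registration_channel(stack)
  series <- estimate_translations(reg, params, axis = axis, mode = mode)
  aligned <- apply_translations(stack, series, axis = axis)
  list(stack = aligned, shifts = series)
}
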
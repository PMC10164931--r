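#' Landmark pairs for rigid registration
#'
#' A tibble of corresponding points between a moving and a reference volume,
#' in physical micrometre coordinates. Column layout follows the BigWarp
#' export dialect: `name`, `active`, moving `mx, my, mz`, fixed (reference)
#' `fx, fy, fz`.
#'
#' @param moving n x 3 matrix of moving-volume points `(x, y, z)` um.
#' @param reference n x 3 matrix of reference points `(x, y, z)` um.
#' @param names optional point labels (default `Pt-0`, `Pt-1`, ...).
#' @param active logical vector; inactive pairs are kept but ignored by
#'   [fit_rigid()].
#' @return a tibble of class `landmark_set`.
#' @export
landmark_set <- function(moving, reference, names = NULL, active = TRUE) {
  moving <- as.matrix(moving); reference <- as.matrix(reference)
  stopifnot(ncol(moving) == 3L, ncol(reference) == 3L,
            nrow(moving) == nrow(reference))
  n <- nrow(moving)
  if (is.null(names)) names <- paste0("Pt-", seq_len(n) - 1L)
  out <- tibble::tibble(
    name = names, active = rep_len(active, n),
    mx = moving[, 1], my = moving[, 2], mz = moving[, 3],
    fx = reference[, 1], fy = reference[, 2], fz = reference[, 3])
  class(out) <- c("landmark_set", class(out))
  out
}

#' Read landmarks from a BigWarp-style CSV
#'
#' Accepts the headerless 8-column export (`"Pt-0", "true", mx, my, mz, fx,
#' fy, fz`) as well as files with a header row. Coordinates are micrometres.
#'
#' @param path CSV path.
#' @return a [landmark_set()] tibble.
#' @export
read_landmarks <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", strsplit(first, ",")[[1]][3])
  df <- utils::read.csv(path, header = has_header,
                        stringsAsFactors = FALSE)
  if (ncol(df) < 8L) stop("landmark CSV needs 8 columns", call. = FALSE)
  landmark_set(
    moving = as.matrix(df[, 3:5]),
    reference = as.matrix(df[, 6:8]),
    names = as.character(df[[1]]),
    active = tolower(as.character(df[[2]])) %in% c("true", "t", "1"))
}

#' Write landmarks as a BigWarp-compatible CSV (headerless)
#' @param landmarks a [landmark_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  df <- data.frame(landmarks$name, ifelse(landmarks$active, "true", "false"),
                   landmarks$mx, landmarks$my, landmarks$mz,
                   landmarks$fx, landmarks$fy, landmarks$fz)
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = c(1, 2))
  invisible(path)
}

#' Rigid 3D transform (rotation + translation)
#'
#' Maps moving physical coordinates `(x, y, z)` um to reference coordinates:
#' `p_ref = R p_mov + t`.
#'
#' @param R 3 x 3 rotation matrix (orthonormal, `det = +1`).
#' @param t length-3 translation, um.
#' @param check validate orthonormality (default TRUE; internal callers
#'   representing a rigid+scale forward map may disable it).
#' @return object of class `rigid_transform3d`.
#' @export
rigid_transform3d <- function(R, t = c(0, 0, 0), check = TRUE) {
  R <- as.matrix(R)
  stopifnot(all(dim(R) == c(3L, 3L)), length(t) == 3L)
  if (check) {
    if (max(abs(crossprod(R) - diag(3))) > 1e-10 || abs(det(R) - 1) > 1e-10) {
      stop("R must be a proper rotation (R'R = I, det = +1)", call. = FALSE)
    }
  }
  structure(list(R = R, t = as.numeric(t), rigid = check),
            class = "rigid_transform3d")
}

#' @export
print.rigid_transform3d <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$R)) - 1) / 2))) * 180 / pi
  cat(sprintf("<rigid_transform3d> rotation %.3f deg, translation (%.3f, %.3f, %.3f) um\n",
              ang, x$t[1], x$t[2], x$t[3]))
  invisible(x)
}

#' Tidy a rigid transform into a one-row tibble
#' @param x a `rigid_transform3d`.
#' @param ... unused.
#' @return tibble with rotation angle (deg), rotation-axis components and
#'   translation.
#' @export
tidy.rigid_transform3d <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$R)) - 1) / 2)))
  axis <- c(x$R[3, 2] - x$R[2, 3], x$R[1, 3] - x$R[3, 1], x$R[2, 1] - x$R[1, 2])
  nrm <- sqrt(sum(axis^2))
  axis <- if (nrm > 1e-12) axis / nrm else c(0, 0, 1)
  tibble::tibble(angle_deg = ang * 180 / pi,
                 axis_x = axis[1], axis_y = axis[2], axis_z = axis[3],
                 tx_um = x$t[1], ty_um = x$t[2], tz_um = x$t[3])
}

# active landmark matrices
.active_points <- function(landmarks) {
  lm <- landmarks[landmarks$active, , drop = FALSE]
  list(m = cbind(lm$mx, lm$my, lm$mz), r = cbind(lm$fx, lm$fy, lm$fz))
}

#' Least-squares rigid fit from landmark pairs
#'
#' Estimates the rigid transform minimizing
#' `sum ||R m_i + t - r_i||^2` over active pairs by the SVD (Kabsch)
#' procedure: centroid alignment, cross-covariance of the centered pairs,
#' singular value decomposition with determinant correction, translation from
#' the centroids.
#'
#' @param landmarks a [landmark_set()] with >= 3 active non-collinear pairs.
#' @return a [rigid_transform3d()] with attribute `"report"` (tibble of
#'   per-pair residuals and RMS, see [landmark_residuals()]).
#' @export
fit_rigid <- function(landmarks) {
  pts <- .active_points(landmarks)
  n <- nrow(pts$m)
  if (n < 3L) {
    stop("degenerate configuration: at least 3 active landmark pairs needed",
         call. = FALSE)
  }
  mbar <- colMeans(pts$m); rbar <- colMeans(pts$r)
  M <- sweep(pts$m, 2, mbar); Rf <- sweep(pts$r, 2, rbar)
  sv_m <- svd(M)$d
  if (sv_m[2] < 1e-9 * max(sv_m[1], 1)) {
    stop("degenerate configuration: active moving points are collinear",
         call. = FALSE)
  }
  H <- crossprod(M, Rf)             # 3x3 cross-covariance
  s <- svd(H)
  dsign <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, dsign)) %*% t(s$u)
  t <- rbar - as.numeric(R %*% mbar)
  xf <- rigid_transform3d(R, t)
  attr(xf, "report") <- landmark_residuals(landmarks, xf)
  xf
}

#' Per-pair landmark residuals under a transform
#'
#' @param landmarks a [landmark_set()].
#' @param xform a [rigid_transform3d()].
#' @return tibble with `name`, `residual_um` per active pair; the RMS residual
#'   is attached as attribute `"rms"`.
#' @export
landmark_residuals <- function(landmarks, xform) {
  pts <- .active_points(landmarks)
  pred <- t(xform$R %*% t(pts$m)) + matrix(xform$t, nrow(pts$m), 3, byrow = TRUE)
  res <- sqrt(rowSums((pred - pts$r)^2))
  out <- tibble::tibble(name = landmarks$name[landmarks$active],
                        residual_um = res)
  attr(out, "rms") <- sqrt(mean(res^2))
  out
}

#' Resample a volume through a rigid transform
#'
#' Pull-resampling: for each voxel centre of the reference grid (physical
#' coordinates), the moving volume is sampled at the inverse-transformed
#' position by trilinear interpolation per channel and time point; positions
#' outside the moving volume give 0. Anisotropic voxels are handled through
#' physical coordinates.
#'
#' @param moving a `stack5d`.
#' @param xform moving-to-reference [rigid_transform3d()].
#' @param reference_geometry list with `extents` (z, y, x) and `voxel_size`
#'   (z, y, x um); defaults to the moving stack's own geometry.
#' @return `stack5d` on the reference grid.
#' @export
resample_volume <- function(moving, xform, reference_geometry = NULL) {
  validate_stack5d(moving)
  d <- dim(moving$data)
  if (is.null(reference_geometry)) {
    reference_geometry <- list(extents = d[c(2, 4, 5)],
                               voxel_size = moving$voxel_size)
  }
  ext <- as.integer(reference_geometry$extents)
  voxo <- as.numeric(reference_geometry$voxel_size)
  stopifnot(all(voxo > 0), all(moving$voxel_size > 0))
  A <- t(xform$R)                       # inverse map: reference -> moving
  b <- -as.numeric(A %*% xform$t)
  if (!isTRUE(xform$rigid)) {           # general invertible forward map
    A <- solve(xform$R)
    b <- -as.numeric(A %*% xform$t)
  }
  out <- array(0, c(d[1], ext[1], d[3], ext[2], ext[3]))
  for (ti in seq_len(d[1])) for (ci in seq_len(d[3])) {
    vol <- array(moving$data[ti, , ci, , ], d[c(2, 4, 5)])
    rs <- .affine_resample_cpp(as.numeric(vol), d[c(2, 4, 5)],
                               moving$voxel_size, ext, voxo, A, b)
    out[ti, , ci, , ] <- array(rs, ext)
  }
  stack5d(out, voxel_size = voxo, frame_interval = moving$frame_interval,
          bit_depth = moving$bit_depth, channel_names = moving$channel_names,
          is_float = moving$is_float)
}

#' Landmark-based rigid registration of a serial session
#'
#' Fits the rigid transform from the landmark pairs, then resamples the
#' moving stack onto the reference grid. Landmark counts between 10 and 20
#' are the practical sweet spot for 512 x 512 datasets; fewer than 3 active
#' pairs is an error.
#'
#' @param moving,reference calibrated `stack5d` objects.
#' @param landmarks a [landmark_set()] (moving vs reference, um).
#' @return list with `aligned` (moving resampled onto the reference grid),
#'   `transform` (the fitted [rigid_transform3d()]), and `report` (per-pair
#'   residuals with RMS attribute).
#' @export
register_serial <- function(moving, reference, landmarks) {
  validate_stack5d(moving); validate_stack5d(reference)
  xf <- fit_rigid(landmarks)
  d <- dim(reference$data)
  aligned <- resample_volume(moving, xf,
                             list(extents = d[c(2, 4, 5)],
                                  voxel_size = reference$voxel_size))
  list(aligned = aligned, transform = xf, report = attr(xf, "report"))
}

# 3D normalized cross-correlation shift (a -> b) via zero-padded FFTs with
# masked-overlap normalization; integer peak within +-max_shift plus per-axis
# quadratic refinement. Returns (dz, dy, dx) in voxels with b(p) ~ a(p - s).
.cc_shift3d <- function(a, b, max_shift = NULL) {
  d <- dim(a)
  if (is.null(max_shift)) max_shift <- pmax(3L, d %/% 4L)
  max_shift <- pmin(rep_len(max_shift, 3L), d - 1L)
  dd <- 2L * d
  pad <- function(x) {
    o <- array(0, dd)
    o[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- x
    o
  }
  m <- array(1, d)
  Fa <- stats::fft(pad(a)); Fb <- stats::fft(pad(b))
  Fa2 <- stats::fft(pad(a^2)); Fb2 <- stats::fft(pad(b^2))
  Fm <- stats::fft(pad(m))
  xc <- function(X, Y) Re(stats::fft(Conj(X) * Y, inverse = TRUE)) / prod(dd)
  N <- pmax(xc(Fm, Fm), 1)
  C <- xc(Fa, Fb)
  Sa <- xc(Fa, Fm); Sb <- xc(Fm, Fb)
  Saa <- xc(Fa2, Fm); Sbb <- xc(Fm, Fb2)
  va <- pmax(Saa - Sa^2 / N, 0); vb <- pmax(Sbb - Sb^2 / N, 0)
  ncc <- (C - Sa * Sb / N) / sqrt(pmax(va * vb, 1e-12))
  ncc[N < 0.05 * prod(d)] <- -Inf               # require substantial overlap
  at <- function(dz, dy, dx) {
    ncc[(dz %% dd[1]) + 1L, (dy %% dd[2]) + 1L, (dx %% dd[3]) + 1L]
  }
  best <- -Inf; pk <- c(0L, 0L, 0L)
  for (dz in -max_shift[1]:max_shift[1])
    for (dy in -max_shift[2]:max_shift[2])
      for (dx in -max_shift[3]:max_shift[3]) {
        v <- at(dz, dy, dx)
        if (v > best) { best <- v; pk <- c(dz, dy, dx) }
      }
  s <- as.numeric(pk)
  for (ax in 1:3) {
    e <- c(0L, 0L, 0L); e[ax] <- 1L
    cm <- at(pk[1] - e[1], pk[2] - e[2], pk[3] - e[3])
    cp <- at(pk[1] + e[1], pk[2] + e[2], pk[3] + e[3])
    denom <- cm - 2 * best + cp
    if (is.finite(cm) && is.finite(cp) && abs(denom) > 1e-12) {
      off <- 0.5 * (cm - cp) / denom
      s[ax] <- s[ax] + max(min(off, 0.5), -0.5)
    }
  }
  s
}

#' Translation alignment of replicate volumes
#'
#' Aligns each replicate to the first by a single 3D translation maximizing
#' the (FFT-based) cross-correlation, with quadratic sub-voxel refinement of
#' the integer peak, then resamples trilinearly. This is the alignment step
#' that precedes ground-truth generation by averaging.
#'
#' @param replicates list of >= 2 `stack5d` objects with identical geometry
#'   (single time point each).
#' @return list with `aligned` (list of `stack5d`, first entry untouched) and
#'   `offsets` (tibble `replicate, dz_vox, dy_vox, dx_vox` of the recovered
#'   shifts of each replicate relative to the first).
#' @export
align_replicates_translation <- function(replicates) {
  stopifnot(is.list(replicates), length(replicates) >= 2L)
  ref <- replicates[[1]]
  validate_stack5d(ref)
  d <- dim(ref$data)
  for (k in seq_along(replicates)) {
    if (!all(dim(replicates[[k]]$data) == d)) {
      stop("replicate ", k, " geometry differs from replicate 1", call. = FALSE)
    }
  }
  # correlate on the channel-summed volume
  sumvol <- function(s) {
    v <- array(0, d[c(2, 4, 5)])
    for (ci in seq_len(d[3])) v <- v + array(s$data[1, , ci, , ], d[c(2, 4, 5)])
    v
  }
  v0 <- sumvol(ref)
  n <- length(replicates)
  offs <- matrix(0, n, 3)
  aligned <- vector("list", n)
  aligned[[1]] <- ref
  vox <- ref$voxel_size
  for (k in 2:n) {
    s <- .cc_shift3d(v0, sumvol(replicates[[k]]))   # (dz, dy, dx) voxels
    offs[k, ] <- s
    shift_um <- s * vox                             # physical (z, y, x)
    out <- ref$data * 0
    for (ci in seq_len(d[3])) {
      vol <- array(replicates[[k]]$data[1, , ci, , ], d[c(2, 4, 5)])
      # b(p) = a(p - s): sample b at p + s to recover a's frame
      rs <- .affine_resample_cpp(as.numeric(vol), d[c(2, 4, 5)], vox,
                                 d[c(2, 4, 5)], vox, diag(3),
                                 c(shift_um[3], shift_um[2], shift_um[1]))
      out[1, , ci, , ] <- array(rs, d[c(2, 4, 5)])
    }
    aligned[[k]] <- stack_like(ref, out, bit_depth = 32L, is_float = TRUE)
  }
  list(aligned = aligned,
       offsets = tibble::tibble(replicate = seq_len(n), dz_vox = offs[, 1],
                                dy_vox = offs[, 2], dx_vox = offs[, 3]))
}
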
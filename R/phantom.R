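#' Specification of a synthetic renal intravital phantom
#'
#' Describes a deterministic phantom volume emulating the structural content
#' of renal intravital 2-photon data across three detection channels:
#' an endothelial network (thin random-walk filaments, bright), tubular
#' autofluorescence (hollow tubes with scattered bright puncta, intermediate)
#' and capsular collagen fibrils (oriented filaments confined to the top
#' slices over dim tubular autofluorescence). Channel amplitudes are chosen
#' so that, under the default acquisition noise, the per-channel raw PSNR
#' ladder mirrors a typical renal validation acquisition: endothelial best,
#' fibril channel worst (its signal is bright but sparse and fine).
#'
#' The default geometry is `(t, z, c, y, x) = (25, 45, 3, 256, 256)`: 25
#' replicate time points of a 45-slice, 3-channel volume, with voxel size
#' `(1.2, 1.15, 1.15)` um matching a ~295 um field of view.
#'
#' @param extents integer length-5 `(t, z, c, y, x)`.
#' @param voxel_size `(z, y, x)` in um/voxel.
#' @param frame_interval seconds between time points (default 5).
#' @param baseline background level in ADU.
#' @param amplitudes per-channel peak structure amplitude in ADU
#'   (endothelial, tubule, fibril order; recycled/truncated to C).
#' @param n_filaments,n_tubes,n_puncta,n_fibrils structure counts.
#' @param decay_tau optional time constant (s) for a mono-exponential
#'   intensity decay of channel 1 across frames (vascular dye washout); `NULL`
#'   for a static phantom.
#' @param seed integer; identical spec + seed gives bit-identical phantoms.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(extents = c(t = 25L, z = 45L, c = 3L, y = 256L, x = 256L),
                         voxel_size = c(1.2, 1.15, 1.15),
                         frame_interval = 5,
                         baseline = 20,
                         amplitudes = c(1200, 500, 350),
                         n_filaments = 12L, n_tubes = 4L, n_puncta = 25L,
                         n_fibrils = 30L, decay_tau = NULL, seed = 1L) {
  extents <- as.integer(extents)
  if (length(extents) != 5L || any(extents < 1L)) {
    stop("extents must be 5 positive integers (t, z, c, y, x)", call. = FALSE)
  }
  if (baseline < 0 || any(amplitudes < 0)) {
    stop("intensity levels must be non-negative", call. = FALSE)
  }
  structure(list(
    extents = extents, voxel_size = as.numeric(voxel_size),
    frame_interval = frame_interval, baseline = baseline,
    amplitudes = rep_len(amplitudes, extents[3]),
    n_filaments = n_filaments, n_tubes = n_tubes, n_puncta = n_puncta,
    n_fibrils = n_fibrils, decay_tau = decay_tau, seed = as.integer(seed)
  ), class = "phantom_spec")
}

# add an isotropic Gaussian blob into vol (z, y, x) at 1-based center
.splat <- function(vol, zc, yc, xc, amp, sg) {
  d <- dim(vol)
  r <- ceiling(3 * sg)
  zl <- max(1, round(zc) - r); zh <- min(d[1], round(zc) + r)
  yl <- max(1, round(yc) - r); yh <- min(d[2], round(yc) + r)
  xl <- max(1, round(xc) - r); xh <- min(d[3], round(xc) + r)
  if (zl > zh || yl > yh || xl > xh) return(vol)
  zi <- zl:zh; yi <- yl:yh; xi <- xl:xh
  gz <- exp(-0.5 * ((zi - zc) / sg)^2)
  gy <- exp(-0.5 * ((yi - yc) / sg)^2)
  gx <- exp(-0.5 * ((xi - xc) / sg)^2)
  vol[zi, yi, xi] <- vol[zi, yi, xi, drop = FALSE] + amp * (gz %o% gy %o% gx)
  vol
}

# bounded 3D random walk polyline splatted as a filament
.draw_filament <- function(vol, amp, sg, n_steps, z_range = NULL) {
  d <- dim(vol)
  zlim <- if (is.null(z_range)) c(1, d[1]) else z_range
  p <- c(stats::runif(1, zlim[1], zlim[2]), stats::runif(1, 1, d[2]),
         stats::runif(1, 1, d[3]))
  v <- stats::rnorm(3); v[1] <- v[1] * 0.3  # mostly in-plane
  v <- v / sqrt(sum(v^2))
  for (s in seq_len(n_steps)) {
    vol <- .splat(vol, p[1], p[2], p[3], amp, sg)
    v <- v + stats::rnorm(3, sd = 0.25); v[1] <- v[1] * 0.6
    v <- v / sqrt(sum(v^2))
    p <- p + v
    p[1] <- min(max(p[1], zlim[1]), zlim[2])
    p[2] <- min(max(p[2], 2), d[2] - 1)
    p[3] <- min(max(p[3], 2), d[3] - 1)
  }
  vol
}

# hollow tube: smooth centerline with a ring of wall splats
.draw_tube <- function(vol, amp, wall_sg, radius, n_steps) {
  d <- dim(vol)
  zlo <- min(2, d[1]); zhi <- max(d[1] - 1, zlo)
  ylo <- min(radius + 2, d[2] - 1); yhi <- max(d[2] - radius - 1, ylo)
  xlo <- min(radius + 2, d[3] - 1); xhi <- max(d[3] - radius - 1, xlo)
  p <- c(stats::runif(1, zlo, zhi), stats::runif(1, ylo, yhi),
         stats::runif(1, xlo, xhi))
  th <- stats::runif(1, 0, 2 * pi)
  v <- c(0.1 * stats::rnorm(1), sin(th), cos(th))
  v <- v / sqrt(sum(v^2))
  ring <- seq(0, 2 * pi, length.out = 13L)[-13L]
  for (s in seq_len(n_steps)) {
    # orthonormal wall-ring basis perpendicular to the local direction
    a <- c(v[2] * 0 - v[3] * 1, v[3] * 0 - v[1] * 0, v[1] * 1 - v[2] * 0)
    if (sum(a^2) < 1e-6) a <- c(0, -v[3], v[2])
    a <- a / sqrt(sum(a^2))
    b <- c(v[2] * a[3] - v[3] * a[2], v[3] * a[1] - v[1] * a[3],
           v[1] * a[2] - v[2] * a[1])
    b <- b / sqrt(sum(b^2))
    for (t in ring) {
      q <- p + radius * (cos(t) * a + sin(t) * b)
      vol <- .splat(vol, q[1], q[2], q[3], amp, wall_sg)
    }
    v <- v + stats::rnorm(3, sd = 0.08); v[1] <- v[1] * 0.5
    v <- v / sqrt(sum(v^2))
    p <- p + 1.5 * v
    p <- pmin(pmax(p, c(zlo, ylo, xlo)), c(zhi, yhi, xhi))
  }
  vol
}

#' Generate a clean (noise-free) phantom stack
#'
#' Deterministic in `(spec, spec$seed)`. Channel recipes: channel 1 =
#' filamentous endothelial network, channel 2 = hollow tubules plus exactly
#' `n_puncta` isolated bright puncta (well separated, each a clear local
#' maximum), channel 3 = oriented fibrils confined to the top slices over dim
#' tubular autofluorescence spanning the volume. Further
#' channels repeat the filament recipe at the corresponding amplitude. The
#' volume is constant across time points unless `decay_tau` is set, in which
#' case channel 1 decays as `exp(-t / tau)` above baseline.
#'
#' @param spec a [phantom_spec()].
#' @return float `stack5d` (32-bit, non-negative).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  e <- spec$extents
  with_seed(spec$seed, {
    vols <- vector("list", e[3])
    zeros <- array(0, c(e[2], e[4], e[5]))
    # structure cross-sections in physical units, converted to voxels:
    # capillary-scale endothelial segments ~8 um FWHM, thin cellular
    # processes ~2.8 um, tubular epithelial wall ~6 um, lysosomal puncta
    # ~3 um, capsular fibrils ~2.4 um
    pxl <- mean(spec$voxel_size[2:3])
    sg_capillary <- 8 / 2.355 / pxl
    sg_process <- 2.8 / 2.355 / pxl
    sg_wall <- 6 / 2.355 / pxl
    sg_punctum <- 3 / 2.355 / pxl
    sg_fibril <- 2.4 / 2.355 / pxl
    # smooth parenchymal autofluorescence bed filling the volume: coarse
    # random field upsampled trilinearly (tissue fills the field of view in
    # renal intravital data; frames are not line art on black)
    make_bed <- function() {
      cz <- max(2, ceiling(e[2] / 6)); cy <- max(2, ceiling(e[4] / 8))
      cx <- max(2, ceiling(e[5] / 8))
      coarse <- array(stats::runif(cz * cy * cx), c(cz, cy, cx))
      up <- .affine_resample_cpp(
        as.numeric(coarse), c(cz, cy, cx), c(1, 1, 1), c(e[2], e[4], e[5]),
        c((cz - 1) / max(e[2] - 1, 1), (cy - 1) / max(e[4] - 1, 1),
          (cx - 1) / max(e[5] - 1, 1)), diag(3), c(0, 0, 0))
      array(up, c(e[2], e[4], e[5]))
    }
    # draw one structure on a scratch volume, normalize to its peak amplitude,
    # and combine by voxelwise maximum so overlaps never pile up
    add_struct <- function(vol, draw, peak_amp) {
      tmp <- draw(zeros)
      mx <- max(tmp)
      if (mx > 0) vol <- pmax(vol, tmp * (peak_amp / mx))
      vol
    }
    for (ci in seq_len(e[3])) {
      vol <- zeros
      amp <- spec$amplitudes[ci]
      recipe <- if (ci == 2L && e[3] >= 2L) "tubule"
                else if (ci == 3L) "fibril" else "filament"
      if (recipe == "filament") {
        for (k in seq_len(spec$n_filaments)) {
          sgk <- if (k %% 3L == 0L) sg_process else sg_capillary
          vol <- add_struct(vol, function(v)
            .draw_filament(v, 1, sg = sgk,
                           n_steps = 6L * max(e[4], e[5]) %/% 4L),
            amp * stats::runif(1, 0.6, 1))
        }
      } else if (recipe == "tubule") {
        for (k in seq_len(spec$n_tubes)) {
          vol <- add_struct(vol, function(v)
            .draw_tube(v, 1, wall_sg = sg_wall, radius = max(5, e[5] %/% 10),
                       n_steps = max(e[4], e[5])),
            amp * stats::runif(1, 0.4, 0.6))
        }
        # well-separated bright puncta: rejection-sample centres
        centers <- matrix(numeric(0), 0, 3)
        margin <- 4
        rlim <- function(n) c(min(margin, n), max(n - margin + 1, min(margin, n)))
        zr <- rlim(e[2]); yr <- rlim(e[4]); xr <- rlim(e[5])
        # minimum separation keeps each punctum an isolated local maximum;
        # relaxed progressively (never below 7) if the volume is too crowded
        sep <- 9; tries <- 0L
        while (nrow(centers) < spec$n_puncta) {
          cand <- c(stats::runif(1, zr[1], zr[2]),
                    stats::runif(1, yr[1], yr[2]),
                    stats::runif(1, xr[1], xr[2]))
          if (nrow(centers) == 0 ||
              min(sqrt(colSums((t(centers) - cand)^2))) > sep) {
            centers <- rbind(centers, cand)
          } else {
            tries <- tries + 1L
            if (tries > 2000L) {
              if (sep <= 7) {
                stop("cannot place ", spec$n_puncta, " separated puncta in a ",
                     paste(e[c(2, 4, 5)], collapse = "x"),
                     " volume; reduce n_puncta", call. = FALSE)
              }
              sep <- sep - 1; tries <- 0L
            }
          }
        }
        for (k in seq_len(nrow(centers))) {
          ck <- centers[k, ]
          vol <- add_struct(vol, function(v)
            .splat(v, ck[1], ck[2], ck[3], 1, sg = sg_punctum),
            amp * stats::runif(1, 1.6, 2.0))
        }
      } else {
        # capsular fibrils confined to the top slices, over dim tubular
        # autofluorescence present throughout the volume
        ztop <- c(1, max(1, min(6, e[2])))
        for (k in seq_len(spec$n_fibrils)) {
          vol <- add_struct(vol, function(v)
            .draw_filament(v, 1, sg = sg_fibril,
                           n_steps = max(e[4], e[5]) %/% 2L, z_range = ztop),
            amp * stats::runif(1, 0.7, 1))
        }
        for (k in seq_len(max(1L, spec$n_tubes))) {
          vol <- add_struct(vol, function(v)
            .draw_tube(v, 1, wall_sg = sg_wall, radius = max(5, e[5] %/% 10),
                       n_steps = max(e[4], e[5])),
            amp * stats::runif(1, 0.35, 0.5))
        }
      }
      vols[[ci]] <- spec$baseline + 0.35 * amp * make_bed() + vol
    }
    data <- array(0, e)
    tfac <- rep(1, e[1])
    if (!is.null(spec$decay_tau)) {
      tt <- (seq_len(e[1]) - 1) * spec$frame_interval
      tfac <- exp(-tt / spec$decay_tau)
    }
    for (ti in seq_len(e[1])) for (ci in seq_len(e[3])) {
      v <- vols[[ci]]
      if (ci == 1L && !is.null(spec$decay_tau)) {
        v <- spec$baseline + (v - spec$baseline) * tfac[ti]
      }
      data[ti, , ci, , ] <- v
    }
    stack5d(data, voxel_size = spec$voxel_size,
            frame_interval = spec$frame_interval, bit_depth = 32L,
            channel_names = c("endothelial", "tubule", "fibril",
                              paste0("ch", seq_len(max(0, e[3] - 3)) + 3))[seq_len(e[3])],
            is_float = TRUE)
  })
}

#' Corrupt a clean stack with Poisson-Gaussian noise
#'
#' Draws `z = alpha * p + n`, `p ~ Poisson(y / alpha)`, `n ~ N(mu, sigma^2)`
#' voxelwise, where `y` is the clean intensity in ADU, so that
#' `E[z] = y + mu` and `Var[z] = alpha * y + sigma^2`. Deterministic given
#' `seed`.
#'
#' @param stack clean non-negative `stack5d`.
#' @param model a [pg_model()].
#' @param seed integer seed.
#' @return noisy float `stack5d` of identical geometry and calibration.
#' @export
corrupt <- function(stack, model, seed = 1L) {
  validate_stack5d(stack)
  stopifnot(inherits(model, "pg_model"))
  if (min(stack$data) < 0) stop("clean stack must be non-negative", call. = FALSE)
  with_seed(seed, {
    n <- length(stack$data)
    p <- stats::rpois(n, lambda = as.numeric(stack$data) / model$alpha)
    g <- stats::rnorm(n, mean = model$mu, sd = model$sigma)
    noisy <- array(model$alpha * p + g, dim(stack$data))
    stack_like(stack, noisy, bit_depth = 32L, is_float = TRUE)
  })
}

#' Gradual drift trajectory
#'
#' Per-frame `(dx, dy)` shifts in pixels that are zero before `onset` and then
#' accumulate linearly with optional random waviness, emulating the slow
#' mechanical drift that sets in partway through a recording.
#'
#' @param n_frames number of frames.
#' @param onset 1-based frame index at which drift begins.
#' @param per_frame length-2 `(dx, dy)` increment per frame after onset, px.
#' @param wobble_sd sd of white positional wobble added to every frame, px.
#' @param seed seed for the wobble.
#' @return tibble with columns `frame`, `dx`, `dy`.
#' @export
drift_trajectory <- function(n_frames, onset = ceiling(n_frames / 2),
                             per_frame = c(0.4, -0.25), wobble_sd = 0,
                             seed = 1L) {
  ramp <- pmax(seq_len(n_frames) - onset, 0)
  dx <- ramp * per_frame[1]
  dy <- ramp * per_frame[2]
  if (wobble_sd > 0) {
    with_seed(seed, {
      dx <- dx + stats::rnorm(n_frames, sd = wobble_sd)
      dy <- dy + stats::rnorm(n_frames, sd = wobble_sd)
    })
  }
  tibble::tibble(frame = seq_len(n_frames), dx = dx, dy = dy)
}

#' Inject a known drift into a stack
#'
#' Translates frame `i` (every channel) by `(dx[i], dy[i])` with bilinear
#' interpolation and zero fill, along the time axis or the slice axis. Used to
#' build registration test cases with known ground truth.
#'
#' @param stack a `stack5d`.
#' @param traj tibble/data frame with `dx`, `dy` (px), one row per frame along
#'   `axis`.
#' @param axis `"t"` or `"z"`.
#' @return drifted `stack5d` (float); the trajectory is attached as attribute
#'   `"true_trajectory"`.
#' @export
inject_drift <- function(stack, traj, axis = c("t", "z")) {
  validate_stack5d(stack)
  axis <- match.arg(axis)
  d <- dim(stack$data)
  n <- if (axis == "t") d[1] else d[2]
  if (nrow(traj) != n) {
    stop("trajectory length (", nrow(traj), ") must match the ", axis,
         " extent (", n, ")", call. = FALSE)
  }
  out <- array(0, d)
  for (i in seq_len(n)) {
    for (ci in seq_len(d[3])) {
      if (axis == "t") {
        for (zi in seq_len(d[2])) {
          out[i, zi, ci, , ] <- .translate_bilinear_cpp(
            matrix(stack$data[i, zi, ci, , ], d[4], d[5]),
            traj$dx[i], traj$dy[i])
        }
      } else {
        for (ti in seq_len(d[1])) {
          out[ti, i, ci, , ] <- .translate_bilinear_cpp(
            matrix(stack$data[ti, i, ci, , ], d[4], d[5]),
            traj$dx[i], traj$dy[i])
        }
      }
    }
  }
  res <- stack_like(stack, out, bit_depth = 32L, is_float = TRUE)
  attr(res, "true_trajectory") <- traj
  res
}

#' Rigid inter-session motion (with optional shrinkage)
#'
#' @param rot_z,rot_y rotation angles in degrees about the z and y axes.
#' @param translation length-3 `(x, y, z)` translation in um.
#' @param shrink length-3 per-axis `(x, y, z)` scale factors in `(0, 1]`
#'   (1 = no shrinkage).
#' @return object of class `session_transform`.
#' @export
session_transform <- function(rot_z = 0, rot_y = 0, translation = c(0, 0, 0),
                              shrink = c(1, 1, 1)) {
  if (any(shrink <= 0) || any(shrink > 1)) {
    stop("shrink factors must lie in (0, 1]", call. = FALSE)
  }
  if (!all(is.finite(c(rot_z, rot_y, translation)))) {
    stop("rotations and translation must be finite", call. = FALSE)
  }
  structure(list(rot_z = rot_z, rot_y = rot_y,
                 translation = as.numeric(translation),
                 shrink = as.numeric(shrink)), class = "session_transform")
}

# rotation matrix (xyz coords): Rz(a) then Ry(b), degrees
.session_rotation <- function(xf) {
  a <- xf$rot_z * pi / 180; b <- xf$rot_y * pi / 180
  Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3,
               byrow = TRUE)
  Ry %*% Rz
}

#' Synthesize a serial-session pair with known alignment
#'
#' Builds a clean reference volume from `spec` (single time point) and a
#' moving volume observing the same scene after a rigid inter-session motion
#' (optionally with anisotropic shrinkage): the forward map from moving to
#' reference physical coordinates is `F(m) = R (s * m) + t`. Exact landmark
#' correspondences are sampled on bright structures; with `shrink = 1` the
#' returned [rigid_transform3d()] is exactly this forward map, so fitting the
#' landmarks must recover it.
#'
#' @param spec a [phantom_spec()] (its t extent is forced to 1).
#' @param xform a [session_transform()].
#' @param n_landmarks number of landmark pairs to sample (default 15).
#' @return list with `reference` and `moving` (`stack5d`), `landmarks`
#'   (a landmark tibble, see [landmark_set()]), and `transform` (the true
#'   moving-to-reference [rigid_transform3d()]).
#' @export
make_serial_pair <- function(spec, xform, n_landmarks = 15L) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(xform, "session_transform"))
  e <- spec$extents; e[1] <- 1L
  spec1 <- spec; spec1$extents <- e
  ref <- make_phantom(spec1)
  d <- dim(ref$data)
  R <- .session_rotation(xform)
  S <- diag(xform$shrink)
  tvec <- xform$translation
  # rotate about the volume centre so the scene stays in the field of view
  ctr <- c((d[5] - 1) * ref$voxel_size[3], (d[4] - 1) * ref$voxel_size[2],
           (d[2] - 1) * ref$voxel_size[1]) / 2
  b <- tvec + ctr - R %*% S %*% ctr
  A <- R %*% S                      # F(m) = A m + b : moving -> reference
  vox <- ref$voxel_size
  moving_data <- array(0, d)
  for (ci in seq_len(d[3])) {
    vol <- array(ref$data[1, , ci, , ], d[c(2, 4, 5)])
    mv <- .affine_resample_cpp(as.numeric(vol), d[c(2, 4, 5)], vox,
                               d[c(2, 4, 5)], vox, A, as.numeric(b))
    moving_data[1, , ci, , ] <- array(mv, d[c(2, 4, 5)])
  }
  moving <- stack_like(ref, moving_data)

  # landmarks on bright structures (all channels pooled), mapped exactly into
  # moving coordinates; the separation requirement relaxes if the scene is
  # too sparse for the requested count
  vol1 <- array(0, d[c(2, 4, 5)])
  for (ci in seq_len(d[3])) {
    ch <- array(ref$data[1, , ci, , ], d[c(2, 4, 5)])
    vol1 <- vol1 + ch / max(ch)
  }
  thr <- stats::quantile(vol1, 0.98)
  idx <- which(vol1 >= thr, arr.ind = TRUE)  # (z, y, x) indices
  Ainv <- solve(A)
  lm_m <- matrix(0, 0, 3); lm_r <- matrix(0, 0, 3)
  with_seed(child_seed(spec$seed, 7L), {
    ord <- sample(nrow(idx))
    for (sep in c(5, 2.5, 1, 0) * max(vox)) {
      for (i in ord) {
        if (nrow(lm_r) >= n_landmarks) break
        p <- c((idx[i, 3] - 1) * vox[3], (idx[i, 2] - 1) * vox[2],
               (idx[i, 1] - 1) * vox[1])             # reference (x, y, z) um
        m <- as.numeric(Ainv %*% (p - b))            # moving (x, y, z) um
        in_bounds <- all(m >= 0) && m[1] <= (d[5] - 1) * vox[3] &&
          m[2] <= (d[4] - 1) * vox[2] && m[3] <= (d[2] - 1) * vox[1]
        far <- nrow(lm_r) == 0 ||
          min(sqrt(colSums((t(lm_r) - p)^2))) > sep
        if (in_bounds && far) {
          lm_r <- rbind(lm_r, p); lm_m <- rbind(lm_m, m)
        }
      }
      if (nrow(lm_r) >= n_landmarks) break
    }
    if (nrow(lm_r) < n_landmarks) {
      stop("could not place ", n_landmarks, " landmarks inside both volumes",
           call. = FALSE)
    }
  })
  lm <- landmark_set(moving = lm_m, reference = lm_r)
  true_xf <- rigid_transform3d(R %*% S, as.numeric(b),
                               check = all(xform$shrink == 1))
  list(reference = ref, moving = moving, landmarks = lm, transform = true_xf)
}

#' Generate the replicate validation set
#'
#' Emulates repeated imaging of one volume: `n` noisy replicates of the clean
#' phantom, each first shifted by a small random 3D offset (at most `jitter`
#' um per axis, trilinear resampling) and then corrupted with Poisson-Gaussian
#' noise. The clean volume and the true offsets are returned for oracle
#' checks.
#'
#' @param spec a [phantom_spec()] (its t extent is forced to 1; one replicate
#'   corresponds to one time point of the validation acquisition).
#' @param n number of replicates (default 25).
#' @param model a [pg_model()].
#' @param jitter maximum absolute offset per axis in um (default 0).
#' @param seed integer master seed (expanded to per-replicate child seeds).
#' @return list with `replicates` (list of n integer `stack5d`), `clean`
#'   (float `stack5d`), and `offsets` (tibble `replicate, dx_um, dy_um,
#'   dz_um`).
#' @export
make_validation_replicates <- function(spec, n = 25L,
                                       model = pg_model(alpha = 4, sigma = 10),
                                       jitter = 0, seed = 1L) {
  stopifnot(n >= 2)
  e <- spec$extents; e[1] <- 1L
  spec1 <- spec; spec1$extents <- e
  clean <- make_phantom(spec1)
  d <- dim(clean$data)
  vox <- clean$voxel_size
  offs <- with_seed(child_seed(seed, 1L), {
    matrix(stats::runif(3L * n, -jitter, jitter), n, 3)  # (x, y, z) um
  })
  reps <- vector("list", n)
  for (k in seq_len(n)) {
    if (jitter > 0) {
      shifted <- array(0, d)
      for (ci in seq_len(d[3])) {
        vol <- array(clean$data[1, , ci, , ], d[c(2, 4, 5)])
        # content moves by +off: sample input at p - off
        sv <- .affine_resample_cpp(as.numeric(vol), d[c(2, 4, 5)], vox,
                                   d[c(2, 4, 5)], vox, diag(3),
                                   -offs[k, ])
        shifted[1, , ci, , ] <- array(sv, d[c(2, 4, 5)])
      }
      base <- stack_like(clean, shifted)
    } else {
      base <- clean
    }
    noisy <- corrupt(base, model, seed = child_seed(seed, 100L + k))
    reps[[k]] <- suppressMessages(quantize_to_uint(noisy, 16L))
  }
  list(replicates = reps, clean = clean,
       offsets = tibble::tibble(replicate = seq_len(n), dx_um = offs[, 1],
                                dy_um = offs[, 2], dz_um = offs[, 3]))
}
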
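test_that("fit_rigid solves textbook configurations", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(2, 3, 1))
  # identical point sets: identity
  id <- fit_rigid(landmark_set(pts, pts))
  expect_equal(id$R, diag(3), tolerance = 1e-12)
  expect_equal(id$t, c(0, 0, 0), tolerance = 1e-12)
  # 90 degree rotation about z
  mv <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, 0, 0))
  rf <- rbind(c(0, 1, 0), c(-1, 0, 0), c(0, 0, 1), c(0, 0, 0))
  xf <- fit_rigid(landmark_set(mv, rf))
  expect_equal(xf$R, matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE),
               tolerance = 1e-12)
  expect_equal(xf$t, c(0, 0, 0), tolerance = 1e-12)
})

test_that("fit_rigid rejects degenerate landmark configurations", {
  two <- matrix(rnorm(6), 2, 3)
  expect_error(fit_rigid(landmark_set(two, two)), "at least 3")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(fit_rigid(landmark_set(line, line)), "collinear")
  # inactive pairs are excluded from the count
  pts <- matrix(rnorm(12), 4, 3)
  lm <- landmark_set(pts, pts, active = c(TRUE, TRUE, FALSE, FALSE))
  expect_error(fit_rigid(lm), "at least 3")
})

test_that("exact correspondences recover random rigid motions", {
  set.seed(30)
  for (i in 1:25) {
    R <- oracle_random_rotation()
    t <- rnorm(3, 0, 20)
    n <- sample(4:12, 1)
    mv <- matrix(rnorm(3 * n, 0, 30), n, 3)
    rf <- t(R %*% t(mv)) + matrix(t, n, 3, byrow = TRUE)
    fit <- fit_rigid(landmark_set(mv, rf))
    expect_lt(norm(fit$R - R, "F"), 1e-6)
    expect_lt(max(abs(fit$t - t)), 1e-6)
    expect_lt(max(abs(crossprod(fit$R) - diag(3))), 1e-10)
    expect_equal(det(fit$R), 1, tolerance = 1e-10)
  }
})

test_that("swapping moving and reference returns the inverse transform", {
  set.seed(31)
  R <- oracle_random_rotation(); t <- rnorm(3, 0, 5)
  mv <- matrix(rnorm(30, 0, 10), 10, 3)
  rf <- t(R %*% t(mv)) + matrix(t, 10, 3, byrow = TRUE)
  fwd <- fit_rigid(landmark_set(mv, rf))
  bwd <- fit_rigid(landmark_set(rf, mv))
  expect_equal(bwd$R, t(fwd$R), tolerance = 1e-9)
  expect_equal(bwd$t, as.numeric(-t(fwd$R) %*% fwd$t), tolerance = 1e-9)
})

test_that("noisy landmarks give a near-optimal small-angle-error fit", {
  set.seed(32)
  R <- oracle_random_rotation(); t <- c(4, -7, 2)
  mv <- matrix(runif(45, 0, 200), 15, 3)
  rf <- t(R %*% t(mv)) + matrix(t, 15, 3, byrow = TRUE) +
    matrix(rnorm(45, 0, 0.5), 15, 3)
  fit <- fit_rigid(landmark_set(mv, rf))
  # rotation angle error under 1 degree
  ang <- acos(pmin(1, (sum(diag(t(fit$R) %*% R)) - 1) / 2)) * 180 / pi
  expect_lt(ang, 1)
  # objective within 1e-9 of a brute-force numeric minimization
  obj_fit <- sum((t(fit$R %*% t(mv)) +
                    matrix(fit$t, 15, 3, byrow = TRUE) - rf)^2)
  obj_opt <- oracle_rigid_objective(mv, rf)
  expect_lt(obj_fit - obj_opt, 1e-9 * max(1, obj_opt))
})

test_that("landmark residuals report per-pair distances and RMS", {
  pts <- matrix(rnorm(15), 5, 3)
  lm <- landmark_set(pts, pts)
  res0 <- landmark_residuals(lm, rigid_transform3d(diag(3)))
  expect_equal(res0$residual_um, rep(0, 5))
  off <- landmark_set(matrix(c(0, 0, 0), 1, 3, byrow = TRUE),
                      matrix(c(2, 0, 0), 1, 3, byrow = TRUE))
  expect_equal(landmark_residuals(off, rigid_transform3d(diag(3)))$residual_um, 2)
  set.seed(33)
  lm2 <- landmark_set(matrix(rnorm(30), 10, 3), matrix(rnorm(30), 10, 3))
  rr <- landmark_residuals(lm2, rigid_transform3d(diag(3), c(1, 2, 3)))
  expect_equal(attr(rr, "rms"), sqrt(mean(rr$residual_um^2)))
})

test_that("resample_volume handles identity, voxel shifts and out-of-range", {
  set.seed(34)
  vol <- array(runif(6 * 10 * 12, 0, 100), c(6, 10, 12))
  s <- zyx_stack(vol, voxel_size = c(2, 1, 1))
  s$voxel_size <- c(2, 1, 1)
  idr <- resample_volume(s, rigid_transform3d(diag(3)))
  expect_equal(idr$data, s$data, tolerance = 1e-12)
  # integer-voxel pure translation relocates exactly: shift +2 voxels in x
  tr <- resample_volume(s, rigid_transform3d(diag(3), t = c(2, 0, 0)))
  expect_equal(tr$data[1, , 1, , 3:12], s$data[1, , 1, , 1:10])
  expect_true(all(tr$data[1, , 1, , 1:2] == 0))
  # transform far outside the volume: all zero
  far <- resample_volume(s, rigid_transform3d(diag(3), t = c(1e5, 0, 0)))
  expect_true(all(far$data == 0))
})

test_that("landmark CSV round trips in the BigWarp dialect", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  lm <- landmark_set(matrix(rnorm(30), 10, 3), matrix(rnorm(30), 10, 3),
                     active = c(rep(TRUE, 8), FALSE, TRUE))
  write_landmarks(lm, tmp)
  back <- read_landmarks(tmp)
  expect_equal(back$mx, lm$mx)
  expect_equal(back$fz, lm$fz)
  expect_equal(back$active, lm$active)
  expect_equal(back$name, lm$name)
})

test_that("serial registration aligns the phantom to its reference", {
  spec <- desk_spec(extents = c(1L, 16L, 3L, 96L, 96L), seed = 5)
  sp <- make_serial_pair(spec, session_transform(rot_z = 10,
                                                 translation = c(3, -2, 1)),
                         n_landmarks = 15)
  # correlate lightly smoothed volumes: the comparison should measure
  # alignment, not the interpolation loss of the thinnest structures
  smooth_ch1 <- function(s) {
    d <- dim(s$data)
    out <- array(0, d[c(2, 4, 5)])
    for (z in seq_len(d[2])) {
      out[z, , ] <- ivmproc:::.gauss_blur2d_cpp(
        matrix(s$data[1, z, 1, , ], d[4], d[5]), 1.5)
    }
    out
  }
  refv <- smooth_ch1(sp$reference)
  pre <- cor(as.numeric(smooth_ch1(sp$moving)), as.numeric(refv))
  reg <- register_serial(sp$moving, sp$reference, sp$landmarks)
  raw_aligned <- array(reg$aligned$data[1, , 1, , ], dim(refv))
  alv <- smooth_ch1(reg$aligned)
  valid <- raw_aligned > 0           # inside the resampled field of view
  # mean per-slice correlation: in-plane alignment, robust to the slice-mean
  # blending a sub-voxel z translation causes
  per_slice <- sapply(seq_len(dim(refv)[1]), function(z) {
    v <- valid[z, , ]
    cor(as.numeric(alv[z, , ][v]), as.numeric(refv[z, , ][v]))
  })
  post <- mean(per_slice)
  expect_gt(post, 0.95)
  expect_gt(post, pre)
  expect_lt(attr(reg$report, "rms"), 1e-6)
})

test_that("replicate translation alignment recovers known offsets", {
  spec <- desk_spec(extents = c(1L, 10L, 3L, 48L, 48L), seed = 36)
  clean <- make_phantom(spec)
  d <- dim(clean$data)
  shift_stack <- function(s, dz, dy, dx) {
    out <- s$data * 0
    vox <- s$voxel_size
    for (ci in 1:d[3]) {
      vol <- array(s$data[1, , ci, , ], d[c(2, 4, 5)])
      sv <- ivmproc:::.affine_resample_cpp(
        as.numeric(vol), d[c(2, 4, 5)], vox, d[c(2, 4, 5)], vox, diag(3),
        -c(dx * vox[3], dy * vox[2], dz * vox[1]))
      out[1, , ci, , ] <- array(sv, d[c(2, 4, 5)])
    }
    stack5d(out, voxel_size = s$voxel_size, bit_depth = 32, is_float = TRUE)
  }
  moved <- shift_stack(clean, 3, -1, 2)
  al <- align_replicates_translation(list(clean, moved))
  expect_lt(max(abs(al$offsets[2, c("dz_vox", "dy_vox", "dx_vox")] -
                      c(3, -1, 2))), 0.5)
  # identical replicates: zero offsets
  al0 <- align_replicates_translation(list(clean, clean))
  expect_equal(as.numeric(al0$offsets[2, -1]), c(0, 0, 0), tolerance = 1e-6)
  # offsets from the validation generator are recovered
  v <- make_validation_replicates(spec, n = 3, model = pg_model(1, 2),
                                  jitter = 2, seed = 37)
  alv <- align_replicates_translation(v$replicates)
  for (k in 2:3) {
    got_vox <- as.numeric(alv$offsets[k, c("dx_vox", "dy_vox", "dz_vox")])
    rel_um <- as.numeric(v$offsets[k, c("dx_um", "dy_um", "dz_um")]) -
      as.numeric(v$offsets[1, c("dx_um", "dy_um", "dz_um")])
    want_vox <- rel_um / clean$voxel_size[c(3, 2, 1)]
    expect_lt(max(abs(got_vox - want_vox)), 0.5)
  }
  expect_error(align_replicates_translation(list(clean)), "2")
})
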
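test_that("contrast enhancement follows the saturated-quantile rule", {
  const <- matrix(3, 8, 8)
  expect_equal(enhance_contrast_frame(const), const)
  # uniform 0..999: 1% total saturation clips at the 0.5%/99.5% quantiles
  set.seed(1)
  fr <- matrix(sample(0:999, 64 * 64, TRUE), 64)
  out <- enhance_contrast_frame(fr, saturated = 0.01, target_max = 999)
  q <- quantile(fr, c(0.005, 0.995), names = FALSE)
  expect_true(all(out[fr <= q[1]] == 0))
  expect_true(all(out[fr >= q[2]] == 999))
  mid <- fr > q[1] & fr < q[2]
  expect_equal(out[mid], (fr[mid] - q[1]) / (q[2] - q[1]) * 999)
  # already full-range two-valued frame is unchanged
  tv <- matrix(c(0, 999), 50, 50)
  expect_equal(enhance_contrast_frame(tv, target_max = 999), tv)
})

test_that("registration channel sums channels and keeps geometry", {
  arr <- array(0, c(1, 1, 2, 2, 2))
  arr[1, 1, 1, , ] <- matrix(c(1, 3, 2, 4), 2)   # [[1,2],[3,4]]
  arr[1, 1, 2, , ] <- matrix(c(4, 2, 3, 1), 2)   # [[4,3],[2,1]]
  s <- stack5d(arr, bit_depth = 16)
  reg <- build_registration_channel(s)
  expect_equal(dim(reg), c(1, 1, 1, 2, 2))
  # sum is constant 5 -> degenerate histogram passes through the stretch
  expect_true(all(reg$data == 5))
  # channel order must not matter (addition commutes)
  s_rev <- merge_channels(rev(split_channels(s)))
  expect_equal(build_registration_channel(s_rev)$data, reg$data)
})

test_that("translation estimation recovers known shifts on textured frames", {
  spec <- desk_spec(extents = c(1L, 1L, 3L, 128L, 128L), seed = 11)
  ph <- suppressMessages(quantize_to_uint(make_phantom(spec), 16))
  fr0 <- matrix(ph$data[1, 1, 1, , ], 128)
  shifted <- translate_px(fr0, 5, -3)
  # cross-check the pair with the independent phase-correlation oracle
  orc <- oracle_phase_shift(fr0, shifted)
  expect_equal(as.numeric(orc), c(5, -3))
  arr <- array(0, c(2, 1, 1, 128, 128))
  arr[1, 1, 1, , ] <- fr0; arr[2, 1, 1, , ] <- shifted
  est <- estimate_translations(stack5d(arr, bit_depth = 32, is_float = TRUE),
                               axis = "t")
  expect_lt(abs(est$dx[2] + 5), 0.1)
  expect_lt(abs(est$dy[2] - 3), 0.1)
  # identical frames give zero shifts
  arr0 <- array(0, c(2, 1, 1, 128, 128))
  arr0[1, 1, 1, , ] <- fr0; arr0[2, 1, 1, , ] <- fr0
  same <- stack5d(arr0, bit_depth = 32, is_float = TRUE)
  est0 <- estimate_translations(same, axis = "t")
  expect_equal(est0$dx, c(0, 0))
  expect_equal(est0$dy, c(0, 0))
})

test_that("uncorrelated noise frames fall back to flagged zero shifts", {
  set.seed(13)
  arr <- array(runif(2 * 96 * 96) * 100, c(2, 1, 1, 96, 96))
  s <- stack5d(arr, bit_depth = 32, is_float = TRUE)
  est <- estimate_translations(s, axis = "t")
  expect_true(est$flagged[2])
  expect_equal(c(est$dx[2], est$dy[2]), c(0, 0))
})

test_that("applying the negated trajectory undoes an injected drift", {
  # dim wide structures: interpolation error must stay well below 1 ADU
  spec <- desk_spec(extents = c(5L, 1L, 3L, 64L, 64L), seed = 14,
                    amplitudes = c(120, 50, 14))
  ph <- make_phantom(spec)
  traj <- drift_trajectory(5, onset = 2, per_frame = c(1.5, -1))
  drifted <- inject_drift(ph, traj, axis = "t")
  undone <- apply_translations(drifted, tibble::tibble(dx = -traj$dx,
                                                       dy = -traj$dy),
                               axis = "t")
  # interior region restored to within interpolation error
  err <- abs(undone$data[, 1, , 10:55, 10:55] - ph$data[, 1, , 10:55, 10:55])
  expect_lt(mean(err), 0.5)
  # all-zero series is the identity
  zs <- tibble::tibble(dx = numeric(5), dy = numeric(5))
  expect_equal(apply_translations(ph, zs, "t")$data, ph$data)
  expect_error(apply_translations(ph, zs[1:3, ], "t"), "must equal")
})

test_that("register_2d improves frame correlation on a drifted Tseries", {
  spec <- desk_spec(extents = c(8L, 1L, 3L, 96L, 96L), seed = 15)
  noisy <- suppressMessages(quantize_to_uint(
    corrupt(make_phantom(spec), pg_model(2, 4), seed = 6), 16))
  traj <- drift_trajectory(8, onset = 4, per_frame = c(2, -1.5))
  drifted <- suppressMessages(quantize_to_uint(
    inject_drift(noisy, traj, axis = "t"), 16))
  res <- register_2d(drifted, axis = "t")
  expect_equal(dim(res$stack), dim(drifted))    # registration channel removed
  corr_of <- function(s) cor(as.numeric(s$data[1, 1, 1, , ]),
                             as.numeric(s$data[8, 1, 1, , ]))
  expect_gt(corr_of(res$stack), corr_of(drifted))
  # recovered corrections match the negated trajectory
  expect_lt(max(abs(res$shifts$dx + traj$dx)), 0.5)
  expect_lt(max(abs(res$shifts$dy + traj$dy)), 0.5)
})

test_that("z-stack registration reduces axial waviness in the xz reslice", {
  spec <- desk_spec(extents = c(1L, 10L, 3L, 96L, 96L), seed = 16)
  ph <- suppressMessages(quantize_to_uint(make_phantom(spec), 16))
  set.seed(17)
  traj <- tibble::tibble(dx = rnorm(10, 0, 2), dy = rnorm(10, 0, 2))
  traj[1, ] <- list(0, 0)
  wavy <- suppressMessages(quantize_to_uint(inject_drift(ph, traj, axis = "z"), 16))
  res <- register_2d(wavy, axis = "z")
  # high-frequency energy along z of the xz reslice must drop
  zenergy <- function(s) {
    xz <- reslice_xz(s, 1, 1, 48)
    mean(diff(xz)^2)
  }
  expect_lt(zenergy(res$stack), zenergy(wavy))
})
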
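test_that("gat_forward matches its closed form and stabilizes variance", {
  m <- pg_model(alpha = 1, sigma = 0, mu = 0)
  expect_equal(gat_forward(0, m), 2 * sqrt(3 / 8), tolerance = 1e-12)
  # radicand <= 0 clamps to 0
  m2 <- pg_model(alpha = 2, sigma = 0, mu = 50)
  expect_equal(gat_forward(0, m2), 0)
  # variance ~ 1 across photon means (moderate/high counts)
  set.seed(314)
  mpg <- pg_model(1, 2, 0)
  for (y in c(20, 100, 500, 2000)) {
    z <- rpois(1e4, y) + rnorm(1e4, 0, 2)
    expect_gt(var(gat_forward(z, mpg)), 0.9)
    expect_lt(var(gat_forward(z, mpg)), 1.1)
  }
})

test_that("gat_inverse inverts algebraically and debiases in unbiased mode", {
  m <- pg_model(1.7, 3.1, 5)
  z <- c(0, 1, 10, 1000)
  expect_equal(gat_inverse(gat_forward(z, m), m, "algebraic"), z,
               tolerance = 1e-9)
  # exact-unbiased inverse of the mean stabilized value recovers the Poisson
  # mean at low counts where the algebraic inverse is biased
  set.seed(99)
  m0 <- pg_model(1, 0, 0)
  D <- mean(gat_forward(rpois(1e5, 20), m0))
  expect_lt(abs(gat_inverse(D, m0, "exact_unbiased") - 20) / 20, 0.01)
  D1 <- mean(gat_forward(rpois(1e5, 1), m0))
  bias_alg <- abs(gat_inverse(D1, m0, "algebraic") - 1)
  bias_unb <- abs(gat_inverse(D1, m0, "exact_unbiased") - 1)
  expect_gt(bias_alg, bias_unb)
  # below the transform's minimum -> 0
  expect_equal(gat_inverse(0, m0, "exact_unbiased"), 0)
  expect_error(gat_inverse(1, m0, "nope"))
})

test_that("noise sigma estimation is robust to image structure", {
  set.seed(5)
  flat <- matrix(rnorm(512^2, 100, 10), 512)
  est <- estimate_noise_sigma(flat)
  expect_gt(est, 9); expect_lt(est, 11)
  expect_lt(abs(est - oracle_sigma_haar(flat)) / est, 0.1)
  # noise-free step edge: structure must be rejected
  step <- matrix(0, 128, 128); step[, 65:128] <- 1000
  expect_lt(estimate_noise_sigma(step), 1)
  expect_warning(s0 <- estimate_noise_sigma(matrix(5, 64, 64)), "constant")
  expect_equal(s0, 0)
  expect_error(estimate_noise_sigma(matrix(0, 8, 8)), "16 x 16")
})

test_that("estimation tile picks evenly spaced slices on a square grid", {
  arr <- array(0, c(1, 45, 1, 6, 6))
  for (z in 1:45) arr[1, z, 1, , ] <- z
  s <- stack5d(arr, bit_depth = 32, is_float = TRUE)
  tile <- build_estimation_tile(s, 10)
  # 4-column grid, 3 rows, last two cells zero-padded
  expect_equal(dim(tile), c(3 * 6, 4 * 6))
  got <- unique(as.numeric(tile))
  expect_setequal(setdiff(got, 0), c(1, 6, 11, 16, 21, 25, 30, 35, 40, 45))
  # 8 slices, max 10 -> all 8 in a 3x3 grid with one empty cell
  arr8 <- array(1, c(1, 8, 1, 4, 4))
  tile8 <- build_estimation_tile(stack5d(arr8, bit_depth = 32, is_float = TRUE), 10)
  expect_equal(dim(tile8), c(12, 12))
  expect_equal(sum(tile8 == 0), 16)  # one empty 4x4 cell
  # single slice passes through
  one <- stack5d(array(matrix(1:16, 4), c(1, 1, 1, 4, 4)), bit_depth = 32,
                 is_float = TRUE)
  expect_equal(build_estimation_tile(one, 10), matrix(1:16, 4))
})

test_that("rescale_unit maps to [0,1] and inverts exactly", {
  x <- c(2, 3, 6)
  sc <- rescale_unit(x)
  expect_equal(sc$data, (x - 2) / 4)
  expect_equal(unrescale_unit(sc), x, tolerance = 1e-12)
  const <- rescale_unit(rep(7, 5))
  expect_true(const$degenerate)
  expect_equal(const$data, rep(0, 5))
  expect_equal(unrescale_unit(const), rep(7, 5))
})

test_that("chunk_plan reproduces the overlapping-chunk layout", {
  plan <- chunk_plan(25, 10, 5)
  expect_equal(plan$start, c(1, 6, 11, 16))
  expect_equal(plan$stop, c(10, 15, 20, 25))
  # keep-ranges partition 1..25
  frames <- unlist(Map(seq, plan$keep_start, plan$keep_stop))
  expect_equal(sort(frames), 1:25)
  # short stack: one chunk
  p7 <- chunk_plan(7, 10, 5)
  expect_equal(nrow(p7), 1)
  expect_equal(c(p7$start, p7$stop, p7$keep_start, p7$keep_stop), c(1, 7, 1, 7))
})

test_that("chunk keep-ranges always partition the frame axis", {
  set.seed(20)
  for (i in 1:50) {
    len <- sample(2:12, 1)
    ov <- sample(0:(len - 1), 1)
    n <- sample(1:60, 1)
    plan <- chunk_plan(n, len, ov)
    frames <- unlist(Map(seq, plan$keep_start, plan$keep_stop))
    expect_equal(sort(frames), seq_len(n))
    expect_true(all(plan$keep_start >= plan$start))
    expect_true(all(plan$keep_stop <= plan$stop))
  }
})

test_that("median3d equals the brute-force oracle and removes impulses", {
  const <- stack5d(array(7, c(1, 4, 1, 6, 6)), bit_depth = 32, is_float = TRUE)
  expect_equal(median3d(const, 2)$data, const$data)
  imp <- array(10, c(6, 8, 8)); imp[3, 4, 4] <- 5000
  f <- median3d(zyx_stack(imp), 2)
  expect_equal(f$data[1, 3, 1, 4, 4], 10)
  set.seed(8)
  vol <- array(runif(16 * 16 * 8, 0, 100), c(8, 16, 16))
  for (r in 1:2) {
    got <- array(median3d(zyx_stack(vol), r)$data[1, , 1, , ], c(8, 16, 16))
    expect_equal(got, oracle_median3d(vol, r))
  }
})

test_that("collaborative filter denoises while preserving signal", {
  set.seed(21)
  truth <- matrix(0.2, 64, 64); truth[20:40, 10:30] <- 0.7
  # noise-free piecewise-constant image passes through nearly unchanged
  clean_out <- collaborative_filter(truth, noise_std = 0.05)
  expect_lt(mean(abs(clean_out - truth)), 0.01)
  # known noise is strongly attenuated
  noisy <- truth + matrix(rnorm(64^2, 0, 0.08), 64)
  den <- collaborative_filter(pmin(pmax(noisy, 0), 1), noise_std = 0.08)
  expect_gt(sd(noisy - truth) / sd(den - truth), 3)
  # determinism
  expect_identical(den, collaborative_filter(pmin(pmax(noisy, 0), 1),
                                             noise_std = 0.08))
  expect_warning(collaborative_filter(truth * 10, 1), "\\[0, 1\\]")
})

test_that("vst pipeline with identity backend is a near-identity map", {
  spec <- desk_spec(extents = c(1L, 6L, 2L, 32L, 32L), seed = 6)
  noisy <- suppressMessages(quantize_to_uint(
    corrupt(make_phantom(spec), pg_model(2, 5), seed = 3), 16))
  out <- suppressMessages(
    denoise_vst(noisy, vst_config(filter_backend = "identity"),
                method = "vst3d"))
  expect_lte(max(abs(out$data - noisy$data)), 1)
  expect_equal(dim(out), dim(noisy))
  expect_equal(out$channel_names, noisy$channel_names)
  expect_equal(out$bit_depth, noisy$bit_depth)
})

test_that("vst denoising improves PSNR over the noisy input", {
  spec <- desk_spec(extents = c(1L, 10L, 3L, 48L, 48L), seed = 9)
  clean <- make_phantom(spec)
  gt <- suppressMessages(quantize_to_uint(clean, 16))
  noisy <- suppressMessages(quantize_to_uint(
    corrupt(clean, validation_model(), seed = 5), 16))
  den <- suppressMessages(denoise_vst(noisy, method = "vst3d"))
  for (ci in 1:3) {
    p_raw <- image_metrics(matrix(gt$data[1, 5, ci, , ], 48),
                           matrix(noisy$data[1, 5, ci, , ], 48))$psnr_db
    p_den <- image_metrics(matrix(gt$data[1, 5, ci, , ], 48),
                           matrix(den$data[1, 5, ci, , ], 48))$psnr_db
    expect_gt(p_den, p_raw)
  }
  expect_error(denoise_vst(clean), "integer")
})
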
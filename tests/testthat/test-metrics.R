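test_that("image_metrics matches hand computations", {
  ref <- matrix(100, 10, 10)
  m <- image_metrics(ref, matrix(90, 10, 10))
  expect_equal(m$rmse, 10)
  expect_equal(m$psnr_db, 20)      # 10*log10(100^2 / 100)
  expect_equal(m$mae, 10)
  m2 <- image_metrics(matrix(0, 4, 4), matrix(3, 4, 4), peak_value = 255)
  expect_equal(m2$mae, 3)
  same <- image_metrics(ref, ref)
  expect_true(same$identical)
  expect_equal(same$psnr_db, Inf)
  expect_equal(same$rmse, 0)
  expect_error(image_metrics(ref, matrix(0, 3, 3)), "shapes differ")
})

test_that("RMSE/MAE are translation invariant; PSNR follows its peak", {
  set.seed(40)
  a <- matrix(runif(64, 0, 100), 8)
  b <- a + matrix(rnorm(64), 8)
  m1 <- image_metrics(a, b)
  m2 <- image_metrics(a + 50, b + 50)
  expect_equal(m1$rmse, m2$rmse)
  expect_equal(m1$mae, m2$mae)
  # fixed-peak mode is invariant to the shared offset too
  p1 <- image_metrics(a, b, peak_value = 255)
  p2 <- image_metrics(a + 50, b + 50, peak_value = 255)
  expect_equal(p1$psnr_db, p2$psnr_db)
})

test_that("ground-truth averaging obeys the noise-averaging law", {
  spec <- desk_spec(extents = c(1L, 8L, 1L, 64L, 64L), seed = 41)
  clean <- make_phantom(spec)
  set.seed(42)
  n <- 25
  reps <- lapply(seq_len(n), function(k) {
    stack5d(clean$data + array(rnorm(length(clean$data), 0, 20),
                               dim(clean$data)),
            voxel_size = clean$voxel_size, bit_depth = 32, is_float = TRUE)
  })
  gt <- generate_ground_truth(reps)
  mse_gt <- mean((gt$data - clean$data)^2)
  mse_one <- mean((reps[[1]]$data - clean$data)^2)
  gain <- 10 * log10(mse_one / mse_gt)
  expect_lt(abs(gain - 10 * log10(n)), 0.5)
  # voxel means approach clean values at the sqrt(n) rate
  expect_lt(mean(abs(gt$data - clean$data)), 3 * 20 / sqrt(n))
  # identical replicates average to themselves
  gt0 <- generate_ground_truth(list(clean, clean))
  q <- suppressMessages(quantize_to_uint(clean, 16))
  expect_equal(gt0$data, q$data)
  expect_error(generate_ground_truth(list(clean)), "2")
})

test_that("benchmark emits one row per method, channel, timepoint and slice", {
  spec <- desk_spec(extents = c(1L, 4L, 2L, 32L, 32L), seed = 43)
  v <- make_validation_replicates(spec, n = 3, model = pg_model(1, 4),
                                  jitter = 0, seed = 44)
  gt <- suppressMessages(quantize_to_uint(v$clean, 16))
  rep <- suppressMessages(benchmark_denoisers(
    v$replicates, gt, list(median3d = function(s) denoise_vst(s, method = "median3d"))))
  # 2 methods (raw + median3d) x 3 timepoints x 4 slices x 2 channels
  expect_equal(nrow(rep$rows), 2 * 3 * 4 * 2)
  expect_equal(sum(rep$rows$method == "raw" & rep$rows$channel == "endothelial"),
               3 * 4)
  expect_equal(unique(rep$summary$n), 12)
  # raw rows reproduce direct image_metrics calls
  r1 <- rep$rows[rep$rows$method == "raw" & rep$rows$timepoint == 2 &
                   rep$rows$slice == 3 & rep$rows$channel == "tubule", ]
  direct <- image_metrics(matrix(gt$data[1, 3, 2, , ], 32),
                          matrix(v$replicates[[2]]$data[1, 3, 2, , ], 32))
  expect_equal(r1$psnr_db, direct$psnr_db)
  expect_equal(r1$rmse, direct$rmse)
})

test_that("raw PSNR decreases monotonically with the noise level", {
  spec <- desk_spec(extents = c(1L, 6L, 3L, 48L, 48L), seed = 45)
  clean <- make_phantom(spec)
  gt <- suppressMessages(quantize_to_uint(clean, 16))
  mean_psnr <- sapply(c(4, 10, 25), function(sg) {
    noisy <- suppressMessages(quantize_to_uint(
      corrupt(clean, pg_model(1, sg), seed = 46), 16))
    mean(sapply(1:6, function(z) image_metrics(
      matrix(gt$data[1, z, 1, , ], 48), matrix(noisy$data[1, z, 1, , ], 48))$psnr_db))
  })
  expect_true(all(diff(mean_psnr) < 0))
})

test_that("ROI union uses OR semantics and the time course tracks decay", {
  m1 <- matrix(FALSE, 8, 8); m1[2:5, 2:5] <- TRUE
  m2 <- matrix(FALSE, 8, 8); m2[4:7, 4:7] <- TRUE
  rs <- roi_set(list(m1, m2))
  expect_equal(sum(rs$union), sum(m1) + sum(m2) - sum(m1 & m2))
  # constant frames -> constant trace equal to the value
  arr <- array(0, c(4, 1, 1, 8, 8))
  for (ti in 1:4) arr[ti, 1, 1, , ] <- 10 * ti
  s <- stack5d(arr, bit_depth = 32, is_float = TRUE, frame_interval = 2)
  tc <- roi_timecourse(s, rs, channel = 1)
  expect_equal(tc$mean_intensity, c(10, 20, 30, 40))
  expect_equal(tc$time_s, c(0, 2, 4, 6))
  expect_error(roi_timecourse(s, roi_set(list(matrix(FALSE, 8, 8))), 1),
               "empty")
  # drift breaks a decaying vascular trace; registration restores monotone decay
  spec <- desk_spec(extents = c(8L, 1L, 3L, 96L, 96L), seed = 47,
                    decay_tau = 40)
  ph <- make_phantom(spec)
  mask <- matrix(ph$data[1, 1, 1, , ] > 300, 96, 96)
  # keep the ROI away from the zero-fill band the drift will introduce
  interior <- matrix(FALSE, 96, 96); interior[20:77, 20:77] <- TRUE
  mask <- mask & interior
  expect_gt(sum(mask), 50)
  rois <- roi_set(list(mask))
  traj <- drift_trajectory(8, onset = 4, per_frame = c(3, 2))
  drifted <- inject_drift(ph, traj, axis = "t")
  tr_clean <- roi_timecourse(ph, rois, 1)$mean_intensity
  tr_drift <- roi_timecourse(drifted, rois, 1)$mean_intensity
  reg <- register_2d(suppressMessages(quantize_to_uint(drifted, 16)),
                     axis = "t")
  tr_reg <- roi_timecourse(reg$stack, rois, 1)$mean_intensity
  expect_true(all(diff(tr_clean) < 0))          # clean decay is monotone
  expect_false(all(diff(tr_drift) < 0) &&
                 max(abs(tr_drift - tr_clean)) < 10)  # drift corrupts the trace
  expect_lt(max(abs(tr_reg - tr_clean) / tr_clean), 0.1)
})
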
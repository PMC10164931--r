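test_that("stack5d enforces its invariants", {
  expect_error(stack5d(array(0, c(2, 2))), "5-dimensional")
  expect_error(stack5d(array(0, c(1, 1, 1, 4, 4)), voxel_size = c(0, 1, 1)),
               "voxel_size")
  expect_error(stack5d(array(-1, c(1, 1, 1, 4, 4))), "\\[0, 65535\\]")
  expect_error(stack5d(array(70000, c(1, 1, 1, 4, 4)), bit_depth = 16),
               "\\[0, 65535\\]")
  expect_error(stack5d(array(0, c(1, 1, 2, 4, 4)), channel_names = "one"),
               "channel_names")
  s <- stack5d(array(70000, c(1, 1, 1, 4, 4)), bit_depth = 32, is_float = TRUE)
  expect_true(is_stack5d(s))
  expect_equal(dim(s), c(1, 1, 1, 4, 4))
})

test_that("split and merge channels are mutually inverse", {
  set.seed(42)
  for (rep in 1:5) {
    d <- c(sample(1:3, 1), sample(1:4, 1), sample(1:4, 1),
           sample(4:9, 1), sample(4:9, 1))
    s <- stack5d(array(sample(0:255, prod(d), TRUE), d), bit_depth = 8,
                 voxel_size = runif(3, 0.5, 3))
    parts <- split_channels(s)
    expect_length(parts, d[3])
    for (ci in seq_len(d[3])) {
      expect_equal(parts[[ci]]$data[, , 1, , ], s$data[, , ci, , ])
    }
    back <- merge_channels(parts)
    expect_equal(back$data, s$data)
    expect_equal(back$channel_names, s$channel_names)
  }
})

test_that("merge_channels rejects mismatched geometry, naming the input", {
  a <- stack5d(array(0, c(1, 2, 1, 4, 4)))
  b <- stack5d(array(0, c(1, 2, 1, 5, 4)))
  expect_error(merge_channels(list(a, b)), "input 2")
  c2 <- stack5d(array(0, c(1, 2, 2, 4, 4)))
  expect_error(merge_channels(list(a, c2)), "not single-channel")
})

test_that("quantize_to_uint rounds half away from zero and clips", {
  f <- stack5d(array(c(99.5, -3.2, 70000, 0.5, 1.49, 2.5, 10, 0),
                     c(1, 1, 1, 2, 4)),
               bit_depth = 32, is_float = TRUE)
  q <- suppressMessages(quantize_to_uint(f, 16))
  expect_equal(as.numeric(q$data), c(100, 0, 65535, 1, 1, 3, 10, 0))
  expect_equal(attr(q, "clipped"), 2)
  # idempotent on in-range integer-valued floats
  g <- stack5d(array(c(0, 5, 255), c(1, 1, 1, 1, 3)), bit_depth = 32,
               is_float = TRUE)
  expect_equal(as.numeric(quantize_to_uint(g, 8)$data), c(0, 5, 255))
  expect_error(quantize_to_uint(q, 16), "float")
})

test_that("reslice_xz extracts the axial cross-section", {
  d <- c(1, 5, 1, 4, 6)
  arr <- array(0, d)
  for (z in 1:5) arr[1, z, 1, , ] <- z
  s <- stack5d(arr, bit_depth = 32, is_float = TRUE)
  xz <- reslice_xz(s, t = 1, c = 1, y = 2)
  expect_equal(dim(xz), c(5, 6))
  for (z in 1:5) expect_true(all(xz[z, ] == z))
  # degenerate single-slice stack gives a 1 x W strip equal to row y
  s2 <- stack5d(array(matrix(1:24, 4, 6), c(1, 1, 1, 4, 6)), bit_depth = 32,
                is_float = TRUE)
  expect_equal(as.numeric(reslice_xz(s2, 1, 1, 3)),
               as.numeric(s2$data[1, 1, 1, 3, ]))
  expect_error(reslice_xz(s, y = 9), "out of range")
})

test_that("TIFF write/read round trip preserves data and calibration", {
  tmp <- withr::local_tempdir()
  s <- stack5d(array(as.numeric(sample(0:65535, 2 * 3 * 2 * 8 * 8, TRUE)),
                     c(2, 3, 2, 8, 8)),
               voxel_size = c(2, 0.5, 0.5), frame_interval = 5,
               bit_depth = 16, channel_names = c("red", "green"))
  p <- file.path(tmp, "s.tif")
  write_stack(s, p)
  r <- read_stack(p)
  expect_identical(r$data, s$data)
  expect_equal(r$voxel_size, s$voxel_size)
  expect_equal(r$frame_interval, s$frame_interval)
  expect_equal(r$channel_names, s$channel_names)
  expect_equal(r$bit_depth, s$bit_depth)

  # 32-bit float stacks keep is_float and round-trip to float precision
  f <- stack5d(array(rnorm(128) * 500, c(1, 2, 1, 8, 8)), bit_depth = 32,
               is_float = TRUE)
  pf <- file.path(tmp, "f.tif")
  write_stack(f, pf)
  rf <- read_stack(pf)
  expect_true(rf$is_float)
  expect_lt(max(abs(rf$data - f$data)), diff(range(f$data)) * 1e-6)
})

test_that("read_stack handles degenerate and error cases", {
  tmp <- withr::local_tempdir()
  # bare single-page 8x8 TIFF -> (1,1,1,8,8)
  plain <- file.path(tmp, "plain.tif")
  tiff::writeTIFF(matrix(runif(64), 8), plain, bits.per.sample = 8)
  p <- read_stack(plain)
  expect_equal(dim(p), c(1, 1, 1, 8, 8))
  expect_error(read_stack(file.path(tmp, "missing.tif")), "does not exist")
  # ambiguous page count vs hint
  multi <- file.path(tmp, "multi.tif")
  tiff::writeTIFF(list(matrix(0, 4, 4), matrix(0, 4, 4), matrix(0, 4, 4)),
                  multi, bits.per.sample = 8)
  expect_error(read_stack(multi, axis_hint = c(t = 2, z = 2)),
               "axis ambiguity")
  expect_error(write_stack(stack5d(array(0, c(1, 1, 1, 2, 2))),
                           file.path(tmp, "no/such/dir/x.tif")),
               "parent directory")
})
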
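# Desk-scale phantom configurations shared by the tests. Geometry keeps the
# validation study's 45-slice / 25-time-point shape where that shape matters,
# with a 64 x 64 (~74 um) field of view; structure counts match that smaller
# field (a ~74 um window shows a couple of tubules, a handful of capillary
# segments, a few lysosomes).

desk_spec <- function(extents = c(1L, 12L, 3L, 64L, 64L), seed = 1L, ...) {
  phantom_spec(extents = extents, n_filaments = 6L, n_tubes = 2L,
               n_puncta = 5L, n_fibrils = 10L, seed = seed, ...)
}

# the "intentionally noisy" validation acquisition: high gain, strong read noise
validation_model <- function() pg_model(alpha = 4, sigma = 10)

# small helper: single-channel float stack from a (z, y, x) array
zyx_stack <- function(vol, ...) {
  d <- dim(vol)
  stack5d(array(vol, c(1, d[1], 1, d[2], d[3])), bit_depth = 32L,
          is_float = TRUE, ...)
}

translate_px <- function(img, dx, dy) {
  ivmproc:::.translate_bilinear_cpp(img, dx, dy)
}

mean_psnr_by_channel <- function(report, method) {
  s <- report$summary
  stats::setNames(s$mean_psnr[s$method == method], s$channel[s$method == method])
}
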
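#' Read a multi-page TIFF stack
#'
#' Reads a (multi-page) TIFF written by [write_stack()] or by acquisition
#' software, returning a canonical `(t, z, c, y, x)` [stack5d()]. Calibration
#' (voxel size, frame interval, channel names, axis extents) is taken from the
#' JSON sidecar `<path>.json` when present; without a sidecar the pages are
#' interpreted as a plain z-stack with 1 um voxels and a warning is emitted.
#'
#' @param path TIFF file path.
#' @param axis_hint optional named integer vector giving the extents of the
#'   page-interleaved axes in storage order, e.g. `c(t = 5, z = 10, c = 3)`
#'   (slowest first; pages are stored t-major, then z, then c). Overrides the
#'   sidecar. Required when the page count is ambiguous and no sidecar exists.
#' @return a `stack5d`.
#' @export
read_stack <- function(path, axis_hint = NULL) {
  if (!file.exists(path)) {
    stop("cannot read image: file does not exist: ", path, call. = FALSE)
  }
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, info = TRUE),
    error = function(e) stop("unreadable or unsupported TIFF: ", path,
                             " (", conditionMessage(e), ")", call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  bits <- attr(pages[[1]], "bits.per.sample")
  if (is.null(bits)) bits <- 16L
  npage <- length(pages)

  meta <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::fromJSON(sidecar, simplifyVector = TRUE)
  }

  if (!is.null(axis_hint)) {
    ext <- c(t = 1L, z = 1L, c = 1L)
    ext[names(axis_hint)] <- as.integer(axis_hint)
  } else if (!is.null(meta) && !is.null(meta$extents_tzc)) {
    ext <- c(t = meta$extents_tzc[1], z = meta$extents_tzc[2],
             c = meta$extents_tzc[3])
  } else {
    if (npage > 1L) {
      warning("no calibration sidecar for ", path,
              "; assuming a single-channel z-stack with 1 um voxels",
              call. = FALSE)
    }
    ext <- c(t = 1L, z = npage, c = 1L)
  }
  if (prod(ext) != npage) {
    stop("axis ambiguity: ", npage, " pages cannot be arranged as t=",
         ext["t"], " z=", ext["z"], " c=", ext["c"],
         "; pass axis_hint", call. = FALSE)
  }

  d1 <- dim(pages[[1]])
  ny <- d1[1]; nx <- d1[2]
  out <- array(0, c(ext[["t"]], ext[["z"]], ext[["c"]], ny, nx))
  k <- 1L
  # page order: t slowest, then z, then c fastest; readTIFF scales the
  # stored integers into [0, 1]
  for (ti in seq_len(ext[["t"]])) for (zi in seq_len(ext[["z"]]))
    for (ci in seq_len(ext[["c"]])) {
      out[ti, zi, ci, , ] <- pages[[k]]
      k <- k + 1L
    }

  is_float <- isTRUE(meta$is_float)
  if (is_float) {
    # float stacks are stored range-scaled on the uint32 grid
    lo <- meta$float_range[1]; hi <- meta$float_range[2]
    out <- out * (hi - lo) + lo
    bits <- 32L
  } else {
    out <- round(out * (2^bits - 1))
  }
  vox <- if (!is.null(meta$voxel_size_um)) as.numeric(meta$voxel_size_um) else c(1, 1, 1)
  fi <- if (!is.null(meta$frame_interval_s)) meta$frame_interval_s else 0
  cn <- if (!is.null(meta$channel_names)) meta$channel_names else NULL
  if (is.null(meta) && npage == 1L && is.null(axis_hint)) {
    # quiet default for plain 2D images
  }
  stack5d(out, voxel_size = vox, frame_interval = fi,
          bit_depth = as.integer(bits), channel_names = cn,
          is_float = is_float)
}

#' Write a stack as multi-page TIFF plus JSON sidecar
#'
#' Pages are written t-major (then z, then c). Calibration, channel names and
#' axis extents go to `<path>.json`. 8/16-bit stacks round-trip bit-exactly
#' through [read_stack()]; 32-bit float stacks are stored range-scaled over the
#' uint32 grid and round-trip to within `range * 2^-32`.
#'
#' @param stack a valid `stack5d`.
#' @param path output TIFF path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  validate_stack5d(stack)
  if (!dir.exists(dirname(path))) {
    stop("cannot write: parent directory does not exist: ", dirname(path),
         call. = FALSE)
  }
  d <- dim(stack$data)
  meta <- list(
    extents_tzc = d[1:3],
    voxel_size_um = stack$voxel_size,
    frame_interval_s = stack$frame_interval,
    channel_names = stack$channel_names,
    bit_depth = stack$bit_depth,
    is_float = stack$is_float
  )
  if (stack$is_float) {
    lo <- min(stack$data); hi <- max(stack$data)
    if (hi <= lo) hi <- lo + 1
    meta$float_range <- c(lo, hi)
    norm <- (stack$data - lo) / (hi - lo)
    bits <- 32L
  } else {
    norm <- stack$data / (2^stack$bit_depth - 1)
    bits <- as.integer(stack$bit_depth)
  }
  pages <- vector("list", prod(d[1:3]))
  k <- 1L
  for (ti in seq_len(d[1])) for (zi in seq_len(d[2])) for (ci in seq_len(d[3])) {
    pages[[k]] <- matrix(norm[ti, zi, ci, , ], nrow = d[4], ncol = d[5])
    k <- k + 1L
  }
  ok <- tryCatch(
    tiff::writeTIFF(pages, path, bits.per.sample = bits, reduce = FALSE),
    error = function(e) stop("cannot write TIFF to ", path, " (",
                             conditionMessage(e), ")", call. = FALSE))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
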
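# Independent oracles used to cross-check the package implementation.
# These deliberately use different algorithms/code paths than the package.

# brute-force truncated-window 3D median (triple loop)
oracle_median3d <- function(vol, r) {
  d <- dim(vol)
  out <- vol
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    zz <- max(1, z - r):min(d[1], z + r)
    yy <- max(1, y - r):min(d[2], y + r)
    xx <- max(1, x - r):min(d[3], x + r)
    out[z, y, x] <- stats::median(vol[zz, yy, xx])
  }
  out
}

# phase-correlation translation estimate between two equally sized frames:
# returns (dx, dy) such that b ~ a shifted by (dx, dy)
oracle_phase_shift <- function(a, b) {
  Fa <- stats::fft(a - mean(a)); Fb <- stats::fft(b - mean(b))
  R <- Fb * Conj(Fa)
  R <- R / pmax(Mod(R), 1e-12)
  cc <- Re(stats::fft(R, inverse = TRUE))
  pk <- which.max(cc)
  idx <- arrayInd(pk, dim(a)) - 1L          # (row lag, col lag)
  lag <- idx
  for (i in 1:2) if (lag[i] > dim(a)[i] / 2) lag[i] <- lag[i] - dim(a)[i]
  c(dx = lag[2], dy = lag[1])
}

# Haar HH-subband MAD noise estimator (independent of the package's
# Laplacian-based estimator)
oracle_sigma_haar <- function(img) {
  ny <- 2 * (nrow(img) %/% 2); nx <- 2 * (ncol(img) %/% 2)
  i <- seq(1, ny, by = 2); j <- seq(1, nx, by = 2)
  hh <- (img[i, j] - img[i, j + 1] - img[i + 1, j] + img[i + 1, j + 1]) / 2
  stats::median(abs(hh)) / 0.6744898
}

# count connected components (26-neighborhood) of a logical 3D array
oracle_count_components <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0L)
  comp <- integer(nrow(idx)); cur <- 0L
  for (i in seq_len(nrow(idx))) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      queue <- i; comp[i] <- cur
      while (length(queue)) {
        j <- queue[1]; queue <- queue[-1]
        nb <- which(comp == 0L &
                    abs(idx[, 1] - idx[j, 1]) <= 1 &
                    abs(idx[, 2] - idx[j, 2]) <= 1 &
                    abs(idx[, 3] - idx[j, 3]) <= 1)
        comp[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  cur
}

# numeric minimization of the rigid objective over (axis-angle, translation),
# as an optimizer-based cross-check of the closed-form SVD fit
oracle_rigid_objective <- function(moving, reference) {
  rotvec_to_R <- function(w) {
    th <- sqrt(sum(w^2))
    if (th < 1e-12) return(diag(3))
    k <- w / th
    K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
                byrow = TRUE)
    diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  }
  obj <- function(p) {
    R <- rotvec_to_R(p[1:3])
    pred <- t(R %*% t(moving)) + matrix(p[4:6], nrow(moving), 3, byrow = TRUE)
    sum((pred - reference)^2)
  }
  fit <- stats::optim(rep(0, 6), obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  fit$value
}

# hand-rolled bilinear sample of img at fractional (row, col), zero outside
oracle_bilinear <- function(img, r, c) {
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  g <- function(rr, cc) {
    if (rr < 1 || rr > nrow(img) || cc < 1 || cc > ncol(img)) 0 else img[rr, cc]
  }
  (1 - fr) * (1 - fc) * g(r0, c0) + (1 - fr) * fc * g(r0, c0 + 1) +
    fr * (1 - fc) * g(r0 + 1, c0) + fr * fc * g(r0 + 1, c0 + 1)
}

# random proper rotation matrix
oracle_random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}
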
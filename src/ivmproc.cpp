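#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------- utilities

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// orthonormal DCT-II matrix, row-major n*n
static std::vector<double> dct_matrix(int n) {
  std::vector<double> D(n * n);
  const double pi = 3.14159265358979323846;
  for (int k = 0; k < n; ++k) {
    double s = (k == 0) ? std::sqrt(1.0 / n) : std::sqrt(2.0 / n);
    for (int i = 0; i < n; ++i)
      D[k * n + i] = s * std::cos(pi * (i + 0.5) * k / n);
  }
  return D;
}

// in-place orthonormal Walsh-Hadamard along a stride-1 vector of length k (power of 2)
static void hadamard(double* v, int k) {
  for (int len = 1; len < k; len <<= 1)
    for (int i = 0; i < k; i += len << 1)
      for (int j = i; j < i + len; ++j) {
        double a = v[j], b = v[j + len];
        v[j] = a + b; v[j + len] = a - b;
      }
  double s = 1.0 / std::sqrt((double)k);
  for (int i = 0; i < k; ++i) v[i] *= s;
}

// ------------------------------------------------------- bilinear translate

// shift image content by (+dx, +dy): out(y, x) = img(y - dy, x - dx), zero fill
// [[Rcpp::export(name = ".translate_bilinear_cpp")]]
NumericMatrix translate_bilinear_cpp(NumericMatrix img, double dx, double dy) {
  int ny = img.nrow(), nx = img.ncol();
  NumericMatrix out(ny, nx);
  for (int x = 0; x < nx; ++x) {
    double sx = x - dx;
    int x0 = (int)std::floor(sx);
    double fx = sx - x0;
    for (int y = 0; y < ny; ++y) {
      double sy = y - dy;
      int y0 = (int)std::floor(sy);
      double fy = sy - y0;
      double acc = 0.0;
      for (int oy = 0; oy <= 1; ++oy) {
        int yy = y0 + oy;
        if (yy < 0 || yy >= ny) continue;
        double wy = oy ? fy : 1.0 - fy;
        if (wy == 0.0) continue;
        for (int ox = 0; ox <= 1; ++ox) {
          int xx = x0 + ox;
          if (xx < 0 || xx >= nx) continue;
          double wx = ox ? fx : 1.0 - fx;
          acc += wy * wx * img(yy, xx);
        }
      }
      out(y, x) = acc;
    }
  }
  return out;
}

// ------------------------------------------------------------- median 3D

// vol: (z, y, x) column-major; truncated neighborhood at borders
// [[Rcpp::export(name = ".median3d_cpp")]]
NumericVector median3d_cpp(NumericVector vol, IntegerVector dims, int r) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  NumericVector out(vol.size());
  std::vector<double> buf;
  buf.reserve((2 * r + 1) * (2 * r + 1) * (2 * r + 1));
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        buf.clear();
        for (int xx = std::max(0, x - r); xx <= std::min(nx - 1, x + r); ++xx)
          for (int yy = std::max(0, y - r); yy <= std::min(ny - 1, y + r); ++yy)
            for (int zz = std::max(0, z - r); zz <= std::min(nz - 1, z + r); ++zz)
              buf.push_back(vol[zz + (size_t)nz * (yy + (size_t)ny * xx)]);
        size_t n = buf.size(), m = n / 2;
        std::nth_element(buf.begin(), buf.begin() + m, buf.end());
        double med = buf[m];
        if (n % 2 == 0) {
          double lo = *std::max_element(buf.begin(), buf.begin() + m);
          med = 0.5 * (med + lo);
        }
        out[z + (size_t)nz * (y + (size_t)ny * x)] = med;
      }
  return out;
}

// ------------------------------------------------------- separable gaussian

// reflect border; truncated at 3 sigma
// [[Rcpp::export(name = ".gauss_blur2d_cpp")]]
NumericMatrix gauss_blur2d_cpp(NumericMatrix img, double sigma) {
  int ny = img.nrow(), nx = img.ncol();
  if (sigma <= 0) return clone(img);
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double& v : k) v /= s;
  NumericMatrix tmp(ny, nx), out(ny, nx);
  auto refl = [](int i, int n) {
    while (i < 0 || i >= n) { if (i < 0) i = -i - 1; if (i >= n) i = 2 * n - i - 1; }
    return i;
  };
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      double acc = 0;
      for (int i = -r; i <= r; ++i) acc += k[i + r] * img(refl(y + i, ny), x);
      tmp(y, x) = acc;
    }
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      double acc = 0;
      for (int i = -r; i <= r; ++i) acc += k[i + r] * tmp(y, refl(x + i, nx));
      out(y, x) = acc;
    }
  return out;
}

// ------------------------------------------------ DoG extrema (sub-pixel xy)

// dog: ny x nx x ns array (column-major). Returns matrix (y, x, s, value),
// 0-based sub-pixel y/x from a 2D quadratic fit at the extremum.
// [[Rcpp::export(name = ".dog_extrema_cpp")]]
NumericMatrix dog_extrema_cpp(NumericVector dog, IntegerVector dims,
                              double thresh, int border) {
  int ny = dims[0], nx = dims[1], ns = dims[2];
  auto at = [&](int y, int x, int s) {
    return dog[y + (size_t)ny * (x + (size_t)nx * s)];
  };
  std::vector<double> rows;
  for (int s = 1; s < ns - 1; ++s)
    for (int x = border; x < nx - border; ++x)
      for (int y = border; y < ny - border; ++y) {
        double v = at(y, x, s);
        if (std::fabs(v) < thresh) continue;
        bool mx = true, mn = true;
        for (int ds = -1; ds <= 1 && (mx || mn); ++ds)
          for (int dx = -1; dx <= 1; ++dx)
            for (int dy = -1; dy <= 1; ++dy) {
              if (!ds && !dx && !dy) continue;
              double w = at(y + dy, x + dx, s + ds);
              if (w >= v) mx = false;
              if (w <= v) mn = false;
            }
        if (!mx && !mn) continue;
        // 2D quadratic refinement in (y, x)
        double gy = 0.5 * (at(y + 1, x, s) - at(y - 1, x, s));
        double gx = 0.5 * (at(y, x + 1, s) - at(y, x - 1, s));
        double hyy = at(y + 1, x, s) - 2 * v + at(y - 1, x, s);
        double hxx = at(y, x + 1, s) - 2 * v + at(y, x - 1, s);
        double hxy = 0.25 * (at(y + 1, x + 1, s) - at(y + 1, x - 1, s)
                           - at(y - 1, x + 1, s) + at(y - 1, x - 1, s));
        double det = hyy * hxx - hxy * hxy;
        double oy = 0, ox = 0;
        if (std::fabs(det) > 1e-12) {
          oy = -(hxx * gy - hxy * gx) / det;
          ox = -(hyy * gx - hxy * gy) / det;
          if (std::fabs(oy) > 1.0) oy = 0;
          if (std::fabs(ox) > 1.0) ox = 0;
        }
        // edge response rejection (principal curvature ratio)
        double tr = hyy + hxx;
        if (det <= 0 || tr * tr / det > 12.1) continue;  // (r+1)^2/r, r = 10
        rows.push_back(y + oy); rows.push_back(x + ox);
        rows.push_back((double)s); rows.push_back(v);
      }
  int n = rows.size() / 4;
  NumericMatrix out(n, 4);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 4; ++j) out(i, j) = rows[4 * i + j];
  return out;
}

// ----------------------------------------------------- affine 3D resampling

// For each output voxel center p_out (physical xyz, 0-based index * voxel),
// sample input at q = A p + b by trilinear interpolation; zero outside.
// vol: (z, y, x) column-major; vox vectors are (z, y, x) um.
// [[Rcpp::export(name = ".affine_resample_cpp")]]
NumericVector affine_resample_cpp(NumericVector vol, IntegerVector dims_in,
                                  NumericVector vox_in, IntegerVector dims_out,
                                  NumericVector vox_out, NumericMatrix A,
                                  NumericVector b) {
  int nzi = dims_in[0], nyi = dims_in[1], nxi = dims_in[2];
  int nzo = dims_out[0], nyo = dims_out[1], nxo = dims_out[2];
  NumericVector out((size_t)nzo * nyo * nxo);
  for (int x = 0; x < nxo; ++x) {
    double px = x * vox_out[2];
    for (int y = 0; y < nyo; ++y) {
      double py = y * vox_out[1];
      for (int z = 0; z < nzo; ++z) {
        double pz = z * vox_out[0];
        double qx = A(0, 0) * px + A(0, 1) * py + A(0, 2) * pz + b[0];
        double qy = A(1, 0) * px + A(1, 1) * py + A(1, 2) * pz + b[1];
        double qz = A(2, 0) * px + A(2, 1) * py + A(2, 2) * pz + b[2];
        double ix = qx / vox_in[2], iy = qy / vox_in[1], iz = qz / vox_in[0];
        int x0 = (int)std::floor(ix), y0 = (int)std::floor(iy),
            z0 = (int)std::floor(iz);
        double fx = ix - x0, fy = iy - y0, fz = iz - z0;
        double acc = 0;
        for (int oz = 0; oz <= 1; ++oz) {
          int zz = z0 + oz; if (zz < 0 || zz >= nzi) continue;
          double wz = oz ? fz : 1 - fz; if (wz == 0) continue;
          for (int oy = 0; oy <= 1; ++oy) {
            int yy = y0 + oy; if (yy < 0 || yy >= nyi) continue;
            double wy = oy ? fy : 1 - fy; if (wy == 0) continue;
            for (int ox = 0; ox <= 1; ++ox) {
              int xx = x0 + ox; if (xx < 0 || xx >= nxi) continue;
              double wx = ox ? fx : 1 - fx;
              acc += wz * wy * wx *
                vol[zz + (size_t)nzi * (yy + (size_t)nyi * xx)];
            }
          }
        }
        out[z + (size_t)nzo * (y + (size_t)nyo * x)] = acc;
      }
    }
  }
  return out;
}

// ------------------------------------- collaborative filtering, 2D (8x8)

struct Cand { double d; int y, x; };

// two-stage block-matching patch filter; img in [0,1] domain, sigma = noise std
// [[Rcpp::export(name = ".bm_filter2d_cpp")]]
NumericMatrix bm_filter2d_cpp(NumericMatrix img, double sigma, int patch,
                              int step, int search, int maxk, double lambda) {
  int ny = img.nrow(), nx = img.ncol();
  int np = patch * patch;
  std::vector<double> D = dct_matrix(patch);
  if (ny < patch || nx < patch) return clone(img);

  // reference positions: stride grid plus flush-right/bottom
  std::vector<int> ys, xs;
  for (int y = 0; y + patch <= ny; y += step) ys.push_back(y);
  if (ys.back() != ny - patch) ys.push_back(ny - patch);
  for (int x = 0; x + patch <= nx; x += step) xs.push_back(x);
  if (xs.back() != nx - patch) xs.push_back(nx - patch);

  int half = search / 2;

  auto dct2 = [&](const double* src, double* dst) {
    double tmp[64 * 4];
    // rows: dst0 = D * P
    for (int k = 0; k < patch; ++k)
      for (int j = 0; j < patch; ++j) {
        double a = 0;
        for (int i = 0; i < patch; ++i) a += D[k * patch + i] * src[i * patch + j];
        tmp[k * patch + j] = a;
      }
    // cols: dst = tmp * D^T
    for (int i = 0; i < patch; ++i)
      for (int k = 0; k < patch; ++k) {
        double a = 0;
        for (int j = 0; j < patch; ++j) a += tmp[i * patch + j] * D[k * patch + j];
        dst[i * patch + k] = a;
      }
  };
  auto idct2 = [&](const double* src, double* dst) {
    double tmp[64 * 4];
    for (int i = 0; i < patch; ++i)       // D^T * C
      for (int j = 0; j < patch; ++j) {
        double a = 0;
        for (int k = 0; k < patch; ++k) a += D[k * patch + i] * src[k * patch + j];
        tmp[i * patch + j] = a;
      }
    for (int i = 0; i < patch; ++i)       // tmp * D
      for (int j = 0; j < patch; ++j) {
        double a = 0;
        for (int k = 0; k < patch; ++k) a += tmp[i * patch + k] * D[k * patch + j];
        dst[i * patch + j] = a;
      }
  };
  auto extract = [&](const NumericMatrix& m, int y, int x, double* p) {
    for (int i = 0; i < patch; ++i)
      for (int j = 0; j < patch; ++j) p[i * patch + j] = m(y + i, x + j);
  };

  auto run_stage = [&](const NumericMatrix& matchsrc, const NumericMatrix& noisy,
                       const NumericMatrix* pilot, NumericMatrix& num,
                       NumericMatrix& den) {
    std::vector<Cand> cand;
    std::vector<double> gN(maxk * np), gP(maxk * np), col(maxk);
    std::vector<double> pbuf(np), cN(np), cP(np);
    const double* msrc = &matchsrc[0];
    for (int yi : ys) for (int xi : xs) {
      // --- match within search window on matchsrc (best-k with early abort)
      cand.clear();
      double ref[64 * 4];
      extract(matchsrc, yi, xi, ref);
      int y0 = clampi(yi - half, 0, ny - patch), y1 = clampi(yi + half, 0, ny - patch);
      int x0 = clampi(xi - half, 0, nx - patch), x1 = clampi(xi + half, 0, nx - patch);
      double worst = std::numeric_limits<double>::infinity();
      for (int xx = x0; xx <= x1; ++xx)
        for (int yy = y0; yy <= y1; ++yy) {
          double d = 0;
          const double* base = msrc + yy + (size_t)ny * xx;
          for (int j = 0; j < patch && d < worst; ++j) {
            const double* colp = base + (size_t)ny * j;
            const double* refp = ref + j;
            for (int i = 0; i < patch; ++i) {
              double e = colp[i] - refp[(size_t)i * patch];
              d += e * e;
            }
          }
          if (d >= worst) continue;
          Cand c{d, yy, xx};
          if ((int)cand.size() < maxk) {
            cand.push_back(c);
            std::push_heap(cand.begin(), cand.end(),
                           [](const Cand& a, const Cand& b) { return a.d < b.d; });
            if ((int)cand.size() == maxk) worst = cand.front().d;
          } else {
            std::pop_heap(cand.begin(), cand.end(),
                          [](const Cand& a, const Cand& b) { return a.d < b.d; });
            cand.back() = c;
            std::push_heap(cand.begin(), cand.end(),
                           [](const Cand& a, const Cand& b) { return a.d < b.d; });
            worst = cand.front().d;
          }
        }
      int kk = (int)cand.size();
      std::sort(cand.begin(), cand.end(),
                [](const Cand& a, const Cand& b) { return a.d < b.d; });
      int K = 1; while (K * 2 <= kk) K *= 2;

      // --- group transform
      for (int g = 0; g < K; ++g) {
        extract(noisy, cand[g].y, cand[g].x, pbuf.data());
        dct2(pbuf.data(), &gN[g * np]);
        if (pilot) {
          extract(*pilot, cand[g].y, cand[g].x, pbuf.data());
          dct2(pbuf.data(), &gP[g * np]);
        }
      }
      double wgt;
      if (!pilot) {
        int nret = 0;
        double th = lambda * sigma;
        for (int c = 0; c < np; ++c) {
          for (int g = 0; g < K; ++g) col[g] = gN[g * np + c];
          hadamard(col.data(), K);
          for (int g = 0; g < K; ++g) {
            if (std::fabs(col[g]) < th) col[g] = 0; else ++nret;
          }
          hadamard(col.data(), K);
          for (int g = 0; g < K; ++g) gN[g * np + c] = col[g];
        }
        wgt = 1.0 / std::max(1, nret);
      } else {
        double sw2 = 0;
        std::vector<double> colP(maxk);
        for (int c = 0; c < np; ++c) {
          for (int g = 0; g < K; ++g) { col[g] = gN[g * np + c]; colP[g] = gP[g * np + c]; }
          hadamard(col.data(), K);
          hadamard(colP.data(), K);
          for (int g = 0; g < K; ++g) {
            double e2 = colP[g] * colP[g];
            double W = e2 / (e2 + sigma * sigma);
            col[g] *= W; sw2 += W * W;
          }
          hadamard(col.data(), K);
          for (int g = 0; g < K; ++g) gN[g * np + c] = col[g];
        }
        wgt = 1.0 / (sw2 * sigma * sigma + 1e-10);
      }
      // --- aggregate
      for (int g = 0; g < K; ++g) {
        idct2(&gN[g * np], pbuf.data());
        for (int i = 0; i < patch; ++i)
          for (int j = 0; j < patch; ++j) {
            num(cand[g].y + i, cand[g].x + j) += wgt * pbuf[i * patch + j];
            den(cand[g].y + i, cand[g].x + j) += wgt;
          }
      }
    }
  };

  NumericMatrix num1(ny, nx), den1(ny, nx);
  run_stage(img, img, nullptr, num1, den1);
  NumericMatrix est1(ny, nx);
  for (int x = 0; x < nx; ++x) for (int y = 0; y < ny; ++y)
    est1(y, x) = den1(y, x) > 0 ? num1(y, x) / den1(y, x) : img(y, x);

  NumericMatrix num2(ny, nx), den2(ny, nx);
  run_stage(est1, img, &est1, num2, den2);
  NumericMatrix out(ny, nx);
  for (int x = 0; x < nx; ++x) for (int y = 0; y < ny; ++y)
    out(y, x) = den2(y, x) > 0 ? num2(y, x) / den2(y, x) : est1(y, x);
  return out;
}

// ------------------------------------- collaborative filtering, 3D (4x4x4)

struct Cand3 { double d; int z, y, x; };

// vol: (z, y, x) column-major in [0,1]; cube patches, Hadamard along group
// [[Rcpp::export(name = ".bm_filter3d_cpp")]]
NumericVector bm_filter3d_cpp(NumericVector vol, IntegerVector dims,
                              double sigma, int patch, int step, int search_xy,
                              int search_z, int maxk, double lambda) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  int np = patch * patch * patch;
  std::vector<double> D = dct_matrix(patch);
  if (nz < patch || ny < patch || nx < patch) {
    // fall back to 2D filtering slice by slice
    NumericVector out((size_t)nz * ny * nx);
    for (int z = 0; z < nz; ++z) {
      NumericMatrix sl(ny, nx);
      for (int x = 0; x < nx; ++x) for (int y = 0; y < ny; ++y)
        sl(y, x) = vol[z + (size_t)nz * (y + (size_t)ny * x)];
      NumericMatrix f = bm_filter2d_cpp(sl, sigma, 8, 3, 39, maxk, lambda);
      for (int x = 0; x < nx; ++x) for (int y = 0; y < ny; ++y)
        out[z + (size_t)nz * (y + (size_t)ny * x)] = f(y, x);
    }
    return out;
  }

  auto vat = [&](int z, int y, int x) -> double {
    return vol[z + (size_t)nz * (y + (size_t)ny * x)];
  };
  std::vector<int> zs, ys, xs;
  for (int z = 0; z + patch <= nz; z += step) zs.push_back(z);
  if (zs.back() != nz - patch) zs.push_back(nz - patch);
  for (int y = 0; y + patch <= ny; y += step) ys.push_back(y);
  if (ys.back() != ny - patch) ys.push_back(ny - patch);
  for (int x = 0; x + patch <= nx; x += step) xs.push_back(x);
  if (xs.back() != nx - patch) xs.push_back(nx - patch);
  int hxy = search_xy / 2, hz = search_z / 2;

  // separable 3D DCT on a cube c[z + patch*(y + patch*x)] along each axis
  auto dct3 = [&](double* c, bool inverse) {
    double tmp[64];
    for (int axis = 0; axis < 3; ++axis) {
      int s1 = axis == 0 ? 1 : (axis == 1 ? patch : patch * patch);
      for (int u = 0; u < patch; ++u)
        for (int v = 0; v < patch; ++v) {
          int base;
          if (axis == 0) base = patch * (u + patch * v);
          else if (axis == 1) base = u + patch * patch * v;
          else base = u + patch * v;
          for (int k = 0; k < patch; ++k) {
            double a = 0;
            for (int i = 0; i < patch; ++i)
              a += (inverse ? D[i * patch + k] : D[k * patch + i]) * c[base + i * s1];
            tmp[k] = a;
          }
          for (int k = 0; k < patch; ++k) c[base + k * s1] = tmp[k];
        }
    }
  };
  auto extract = [&](const double* src, int z, int y, int x, double* p) {
    for (int xx = 0; xx < patch; ++xx)
      for (int yy = 0; yy < patch; ++yy)
        for (int zz = 0; zz < patch; ++zz)
          p[zz + patch * (yy + patch * xx)] =
            src[(z + zz) + (size_t)nz * ((y + yy) + (size_t)ny * (x + xx))];
  };

  std::vector<double> num((size_t)nz * ny * nx), den((size_t)nz * ny * nx);
  std::vector<double> est((size_t)nz * ny * nx);
  std::vector<Cand3> cand;
  std::vector<double> gN(maxk * np), gP(maxk * np), col(maxk), colP(maxk),
    pbuf(np), ref(np);

  auto run_stage = [&](const double* matchsrc, const double* noisy,
                       const double* pilot, std::vector<double>& num,
                       std::vector<double>& den) {
    for (int zi : zs) for (int yi : ys) for (int xi : xs) {
      cand.clear();
      extract(matchsrc, zi, yi, xi, ref.data());
      int z0 = clampi(zi - hz, 0, nz - patch), z1 = clampi(zi + hz, 0, nz - patch);
      int y0 = clampi(yi - hxy, 0, ny - patch), y1 = clampi(yi + hxy, 0, ny - patch);
      int x0 = clampi(xi - hxy, 0, nx - patch), x1 = clampi(xi + hxy, 0, nx - patch);
      auto cmp = [](const Cand3& a, const Cand3& b) { return a.d < b.d; };
      double worst = std::numeric_limits<double>::infinity();
      for (int xx = x0; xx <= x1; ++xx)
        for (int yy = y0; yy <= y1; ++yy)
          for (int zz = z0; zz <= z1; ++zz) {
            double d = 0;
            for (int px = 0; px < patch && d < worst; ++px)
              for (int py = 0; py < patch; ++py) {
                const double* colp = matchsrc + (zz) + (size_t)nz *
                  ((yy + py) + (size_t)ny * (xx + px));
                const double* refp = ref.data() + patch * (py + patch * px);
                for (int pz = 0; pz < patch; ++pz) {
                  double e = colp[pz] - refp[pz];
                  d += e * e;
                }
              }
            if (d >= worst) continue;
            Cand3 c{d, zz, yy, xx};
            if ((int)cand.size() < maxk) {
              cand.push_back(c);
              std::push_heap(cand.begin(), cand.end(), cmp);
              if ((int)cand.size() == maxk) worst = cand.front().d;
            } else {
              std::pop_heap(cand.begin(), cand.end(), cmp);
              cand.back() = c;
              std::push_heap(cand.begin(), cand.end(), cmp);
              worst = cand.front().d;
            }
          }
      int kk = (int)cand.size();
      std::sort(cand.begin(), cand.end(), cmp);
      int K = 1; while (K * 2 <= kk) K *= 2;
      for (int g = 0; g < K; ++g) {
        extract(noisy, cand[g].z, cand[g].y, cand[g].x, &gN[g * np]);
        dct3(&gN[g * np], false);
        if (pilot) {
          extract(pilot, cand[g].z, cand[g].y, cand[g].x, &gP[g * np]);
          dct3(&gP[g * np], false);
        }
      }
      double wgt;
      if (!pilot) {
        int nret = 0;
        double th = lambda * sigma;
        for (int c = 0; c < np; ++c) {
          for (int g = 0; g < K; ++g) col[g] = gN[g * np + c];
          hadamard(col.data(), K);
          for (int g = 0; g < K; ++g) {
            if (std::fabs(col[g]) < th) col[g] = 0; else ++nret;
          }
          hadamard(col.data(), K);
          for (int g = 0; g < K; ++g) gN[g * np + c] = col[g];
        }
        wgt = 1.0 / std::max(1, nret);
      } else {
        double sw2 = 0;
        for (int c = 0; c < np; ++c) {
          for (int g = 0; g < K; ++g) { col[g] = gN[g * np + c]; colP[g] = gP[g * np + c]; }
          hadamard(col.data(), K);
          hadamard(colP.data(), K);
          for (int g = 0; g < K; ++g) {
            double e2 = colP[g] * colP[g];
            double W = e2 / (e2 + sigma * sigma);
            col[g] *= W; sw2 += W * W;
          }
          hadamard(col.data(), K);
          for (int g = 0; g < K; ++g) gN[g * np + c] = col[g];
        }
        wgt = 1.0 / (sw2 * sigma * sigma + 1e-10);
      }
      for (int g = 0; g < K; ++g) {
        std::copy(&gN[g * np], &gN[g * np] + np, pbuf.data());
        dct3(pbuf.data(), true);
        for (int px = 0; px < patch; ++px)
          for (int py = 0; py < patch; ++py)
            for (int pz = 0; pz < patch; ++pz) {
              size_t idx = (cand[g].z + pz) + (size_t)nz *
                ((cand[g].y + py) + (size_t)ny * (cand[g].x + px));
              num[idx] += wgt * pbuf[pz + patch * (py + patch * px)];
              den[idx] += wgt;
            }
      }
    }
  };

  const double* raw = &vol[0];
  run_stage(raw, raw, nullptr, num, den);
  for (size_t i = 0; i < est.size(); ++i)
    est[i] = den[i] > 0 ? num[i] / den[i] : raw[i];
  std::fill(num.begin(), num.end(), 0.0);
  std::fill(den.begin(), den.end(), 0.0);
  run_stage(est.data(), raw, est.data(), num, den);
  NumericVector out((size_t)nz * ny * nx);
  for (size_t i = 0; i < (size_t)out.size(); ++i)
    out[i] = den[i] > 0 ? num[i] / den[i] : est[i];
  return out;
}
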
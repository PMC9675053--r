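// Numeric kernels: structure factors on arbitrary q sets, expected-pattern
// batches over orientations, the ideal reciprocal-space volume, EMC
// expand/E-step/M-step/compress, and trilinear rotate-resample utilities.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::mat33 quat_to_mat(double w, double x, double y, double z) {
  arma::mat33 R;
  R(0,0) = 1 - 2*(y*y + z*z); R(0,1) = 2*(x*y - w*z);     R(0,2) = 2*(x*z + w*y);
  R(1,0) = 2*(x*y + w*z);     R(1,1) = 1 - 2*(x*x + z*z); R(1,2) = 2*(y*z - w*x);
  R(2,0) = 2*(x*z - w*y);     R(2,1) = 2*(y*z + w*x);     R(2,2) = 1 - 2*(x*x + y*y);
  return R;
}

// F(q) = sum_i f_{e(i)}(|q|) exp(i q.r_i); fmat holds f per q-row and element
// [[Rcpp::export]]
arma::cx_vec sf_cpp(const arma::mat& coords, const arma::ivec& eidx,
                    const arma::mat& fmat, const arma::mat& q) {
  const arma::uword nq = q.n_rows, na = coords.n_rows, ne = fmat.n_cols;
  arma::mat re(nq, ne, arma::fill::zeros), im(nq, ne, arma::fill::zeros);
  for (arma::uword a = 0; a < na; ++a) {
    const int e = eidx(a);
    const double rx = coords(a,0), ry = coords(a,1), rz = coords(a,2);
    for (arma::uword p = 0; p < nq; ++p) {
      const double ph = q(p,0)*rx + q(p,1)*ry + q(p,2)*rz;
      re(p, e) += std::cos(ph);
      im(p, e) += std::sin(ph);
    }
  }
  arma::cx_vec F(nq, arma::fill::zeros);
  for (arma::uword e = 0; e < ne; ++e)
    for (arma::uword p = 0; p < nq; ++p)
      F(p) += std::complex<double>(fmat(p,e)*re(p,e), fmat(p,e)*im(p,e));
  return F;
}

// |F(R_k q_p)|^2 for each pixel p and orientation k (npix x npat)
// [[Rcpp::export]]
arma::mat ipatterns_cpp(const arma::mat& coords, const arma::ivec& eidx,
                        const arma::mat& fmat, const arma::mat& qpix,
                        const arma::mat& quats) {
  const arma::uword npix = qpix.n_rows, na = coords.n_rows,
    ne = fmat.n_cols, npat = quats.n_rows;
  arma::mat out(npix, npat);
  arma::mat re(npix, ne), im(npix, ne);
  for (arma::uword k = 0; k < npat; ++k) {
    arma::mat33 R = quat_to_mat(quats(k,0), quats(k,1), quats(k,2), quats(k,3));
    re.zeros(); im.zeros();
    // rotated pixel q (|q| unchanged, so fmat stays valid)
    arma::mat qr = qpix * R.t();
    for (arma::uword a = 0; a < na; ++a) {
      const int e = eidx(a);
      const double rx = coords(a,0), ry = coords(a,1), rz = coords(a,2);
      for (arma::uword p = 0; p < npix; ++p) {
        const double ph = qr(p,0)*rx + qr(p,1)*ry + qr(p,2)*rz;
        re(p, e) += std::cos(ph);
        im(p, e) += std::sin(ph);
      }
    }
    for (arma::uword p = 0; p < npix; ++p) {
      double fr = 0.0, fi = 0.0;
      for (arma::uword e = 0; e < ne; ++e) {
        fr += fmat(p,e)*re(p,e);
        fi += fmat(p,e)*im(p,e);
      }
      out(p, k) = fr*fr + fi*fi;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// |F(q)|^2 on a centered cubic grid; cm rows: Z, a1..a4, b1..b4, c
// [[Rcpp::export]]
arma::cube ideal_volume_cpp(const arma::mat& coords, const arma::ivec& eidx,
                            const arma::mat& cm, const int edge,
                            const double voxel) {
  const arma::uword na = coords.n_rows, ne = cm.n_rows;
  const double c0 = (edge + 1.0) / 2.0;
  arma::cube out(edge, edge, edge);
  std::vector<double> fe(ne);
  for (int kz = 0; kz < edge; ++kz) {
    const double qz = (kz + 1 - c0) * voxel;
    for (int ky = 0; ky < edge; ++ky) {
      const double qy = (ky + 1 - c0) * voxel;
      for (int kx = 0; kx < edge; ++kx) {
        const double qx = (kx + 1 - c0) * voxel;
        const double s2 = (qx*qx + qy*qy + qz*qz) / (16.0 * M_PI * M_PI);
        for (arma::uword e = 0; e < ne; ++e)
          fe[e] = cm(e,9) + cm(e,1)*std::exp(-cm(e,5)*s2)
                          + cm(e,2)*std::exp(-cm(e,6)*s2)
                          + cm(e,3)*std::exp(-cm(e,7)*s2)
                          + cm(e,4)*std::exp(-cm(e,8)*s2);
        double fr = 0.0, fi = 0.0;
        for (arma::uword a = 0; a < na; ++a) {
          const double ph = qx*coords(a,0) + qy*coords(a,1) + qz*coords(a,2);
          const double f = fe[eidx(a)];
          fr += f*std::cos(ph);
          fi += f*std::sin(ph);
        }
        out(kx, ky, kz) = fr*fr + fi*fi;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

static inline double trilinear(const arma::cube& vol, double x, double y,
                               double z, bool& ok) {
  // 1-based coordinates
  const int n1 = vol.n_rows, n2 = vol.n_cols, n3 = vol.n_slices;
  if (x < 1.0 || y < 1.0 || z < 1.0 || x > n1 || y > n2 || z > n3) {
    ok = false;
    return 0.0;
  }
  ok = true;
  int i = (int)std::floor(x); if (i >= n1) i = n1 - 1;
  int j = (int)std::floor(y); if (j >= n2) j = n2 - 1;
  int k = (int)std::floor(z); if (k >= n3) k = n3 - 1;
  const double fx = x - i, fy = y - j, fz = z - k;
  const int i0 = i - 1, j0 = j - 1, k0 = k - 1;
  double v = 0.0;
  v += vol(i0,   j0,   k0  ) * (1-fx)*(1-fy)*(1-fz);
  v += vol(i0+1, j0,   k0  ) * fx*(1-fy)*(1-fz);
  v += vol(i0,   j0+1, k0  ) * (1-fx)*fy*(1-fz);
  v += vol(i0,   j0,   k0+1) * (1-fx)*(1-fy)*fz;
  v += vol(i0+1, j0+1, k0  ) * fx*fy*(1-fz);
  v += vol(i0+1, j0,   k0+1) * fx*(1-fy)*fz;
  v += vol(i0,   j0+1, k0+1) * (1-fx)*fy*fz;
  v += vol(i0+1, j0+1, k0+1) * fx*fy*fz;
  return v;
}

// tomograms: W(j, p) = trilinear(vol, R_j * qg_p + center)
// [[Rcpp::export]]
arma::mat expand_cpp(const arma::cube& vol, const arma::mat& quats,
                     const arma::mat& qg, const double center) {
  const arma::uword nrot = quats.n_rows, npix = qg.n_rows;
  const int n1 = vol.n_rows, n2 = vol.n_cols, n3 = vol.n_slices;
  const double* vp = vol.memptr();
  const long s2 = n1, s3 = (long)n1 * n2;
  arma::mat W(nrot, npix);
  std::vector<arma::mat33> Rs(nrot);
  for (arma::uword j = 0; j < nrot; ++j)
    Rs[j] = quat_to_mat(quats(j,0), quats(j,1), quats(j,2), quats(j,3));
  // pixel-outer loop: each pixel fills one contiguous column of W, and the
  // (small) model cube stays cache-resident for the scattered reads
  for (arma::uword p = 0; p < npix; ++p) {
    const double gx = qg(p,0), gy = qg(p,1), gz = qg(p,2);
    double* wc = W.colptr(p);
    for (arma::uword j = 0; j < nrot; ++j) {
      const arma::mat33& R = Rs[j];
      const double x = R(0,0)*gx + R(0,1)*gy + R(0,2)*gz + center;
      const double y = R(1,0)*gx + R(1,1)*gy + R(1,2)*gz + center;
      const double z = R(2,0)*gx + R(2,1)*gy + R(2,2)*gz + center;
      if (x < 1.0 || y < 1.0 || z < 1.0 || x > n1 || y > n2 || z > n3)
        stop("scattering vector of pixel %d leaves the model grid under rotation %d",
             (int)p + 1, (int)j + 1);
      int i = (int)x, jj = (int)y, kk = (int)z;
      if (i >= n1) i = n1 - 1;   // exact upper-boundary hit
      if (jj >= n2) jj = n2 - 1;
      if (kk >= n3) kk = n3 - 1;
      const double fx = x - i, fy = y - jj, fz = z - kk;
      const double* b = vp + (i - 1) + (long)(jj - 1) * s2 + (long)(kk - 1) * s3;
      const double c00 = b[0] + fx * (b[1] - b[0]);
      const double c10 = b[s2] + fx * (b[s2 + 1] - b[s2]);
      const double c01 = b[s3] + fx * (b[s3 + 1] - b[s3]);
      const double c11 = b[s2 + s3] + fx * (b[s2 + s3 + 1] - b[s2 + s3]);
      const double c0 = c00 + fy * (c10 - c00);
      const double c1 = c01 + fy * (c11 - c01);
      wc[j] = c0 + fz * (c1 - c0);
    }
    if (p % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return W;
}

// dense-times-sparse product C += f(D) * S, accumulated in rotation blocks:
// the block of D is packed into a contiguous buffer (optionally
// log-transformed on the fly) so the inner loops run on L2-resident memory
template <typename real_t>
static void block_accum_t(arma::mat& C, const arma::mat& D, const arma::sp_mat& S,
                          const bool take_log) {
  const arma::uword nrot = D.n_rows, npix = D.n_cols, ncol = S.n_cols;
  const arma::uword B = 64;
  std::vector<real_t> Dp(B * npix), Cp(B * ncol);
  for (arma::uword b0 = 0; b0 < nrot; b0 += B) {
    const arma::uword bs = std::min(B, nrot - b0);
    for (arma::uword p = 0; p < npix; ++p) {
      const double* src = D.colptr(p) + b0;
      real_t* dst = &Dp[p * bs];
      if (take_log)
        for (arma::uword j = 0; j < bs; ++j)
          dst[j] = (real_t)std::log(src[j] < 1e-100 ? 1e-100 : src[j]);
      else
        for (arma::uword j = 0; j < bs; ++j) dst[j] = (real_t)src[j];
    }
    std::fill(Cp.begin(), Cp.begin() + bs * ncol, (real_t)0);
    const double* sv = S.values;
    const arma::uword* sr = S.row_indices;
    const arma::uword* sc = S.col_ptrs;
    for (arma::uword k = 0; k < ncol; ++k) {
      real_t* __restrict__ ck = &Cp[k * bs];
      for (arma::uword idx = sc[k]; idx < sc[k + 1]; ++idx) {
        const real_t val = (real_t)sv[idx];
        const real_t* __restrict__ dp = &Dp[sr[idx] * bs];
        for (arma::uword j = 0; j < bs; ++j) ck[j] += val * dp[j];
      }
    }
    for (arma::uword k = 0; k < ncol; ++k) {
      double* dst = C.colptr(k) + b0;
      const real_t* src = &Cp[k * bs];
      for (arma::uword j = 0; j < bs; ++j) dst[j] += (double)src[j];
    }
    Rcpp::checkUserInterrupt();
  }
}

// problems small enough to keep exact-arithmetic EM properties run in
// double; large ones use the cache-friendly single-precision path (photon
// counts are small integers, log-likelihoods ~1e3, far above float noise)
static void block_accum(arma::mat& C, const arma::mat& D, const arma::sp_mat& S,
                        const bool take_log) {
  if (D.n_elem <= 8000000) block_accum_t<double>(C, D, S, take_log);
  else block_accum_t<float>(C, D, S, take_log);
}

// E step: log P(K_k | W_j) = sum_p [K log W - W]; responsibilities with
// annealing beta, plus the beta = 1 mixture log-likelihood per pattern
// [[Rcpp::export]]
List emc_estep_cpp(const arma::mat& W, const arma::sp_mat& K,
                   const double beta, const arma::vec& logw) {
  const arma::uword nrot = W.n_rows, npat = K.n_cols;
  arma::vec sumW = arma::sum(W, 1);
  arma::mat L(nrot, npat, arma::fill::zeros);
  block_accum(L, W, K, true);   // L = log(W) * K, log fused into packing
  L.each_col() -= sumW;
  L.each_col() += logw;
  arma::vec loglik(npat);
  for (arma::uword k = 0; k < npat; ++k) {
    double* lc = L.colptr(k);
    double m = lc[0];
    for (arma::uword j = 1; j < nrot; ++j) if (lc[j] > m) m = lc[j];
    if (!std::isfinite(m))
      stop("all orientation likelihoods underflowed for pattern %d", (int)k + 1);
    double s1 = 0.0, sb = 0.0;
    for (arma::uword j = 0; j < nrot; ++j) s1 += std::exp(lc[j] - m);
    loglik(k) = m + std::log(s1);
    // responsibilities overwrite L in place
    for (arma::uword j = 0; j < nrot; ++j) {
      lc[j] = std::exp(beta * (lc[j] - m));
      sb += lc[j];
    }
    for (arma::uword j = 0; j < nrot; ++j) lc[j] /= sb;
  }
  return List::create(_["P"] = L, _["loglik"] = loglik);
}

// M step: numerator_j(p) = sum_k P_jk K_k(p); n_j = sum_k P_jk
// [[Rcpp::export]]
List emc_mstep_cpp(const arma::mat& P, const arma::sp_mat& Kt) {
  // Kt: npat x npix
  const arma::uword nrot = P.n_rows, npix = Kt.n_cols;
  arma::mat numer(nrot, npix, arma::fill::zeros);
  block_accum(numer, P, Kt, false);
  arma::vec nj = arma::sum(P, 1);
  // tomogram update in place: rows with no responsibility mass are flagged
  // by nj ~ 0 and resolved by the caller
  for (arma::uword p = 0; p < npix; ++p) {
    double* nc = numer.colptr(p);
    for (arma::uword j = 0; j < nrot; ++j)
      nc[j] /= (nj(j) > 1e-300 ? nj(j) : 1.0);
  }
  return List::create(_["numer"] = numer, _["nj"] = nj);
}

// scatter tomograms back onto the grid with trilinear weights, each
// tomogram weighted by its pattern occupancy nj
// [[Rcpp::export]]
List compress_cpp(const arma::mat& W, const arma::vec& nj,
                  const arma::mat& quats, const arma::mat& qg,
                  const double center, const int edge) {
  const arma::uword nrot = quats.n_rows, npix = qg.n_rows;
  arma::cube num(edge, edge, edge, arma::fill::zeros);
  arma::cube den(edge, edge, edge, arma::fill::zeros);
  std::vector<arma::mat33> Rs(nrot);
  for (arma::uword j = 0; j < nrot; ++j)
    Rs[j] = quat_to_mat(quats(j,0), quats(j,1), quats(j,2), quats(j,3));
  // pixel-outer loop: contiguous reads of W's columns, cache-resident
  // scattered writes into the small accumulation cubes
  for (arma::uword p = 0; p < npix; ++p) {
    const double gx = qg(p,0), gy = qg(p,1), gz = qg(p,2);
    const double* wc = W.colptr(p);
    for (arma::uword j = 0; j < nrot; ++j) {
      const double wj = nj(j);
      if (wj <= 0) continue;
      const arma::mat33& R = Rs[j];
      const double x = R(0,0)*gx + R(0,1)*gy + R(0,2)*gz + center;
      const double y = R(1,0)*gx + R(1,1)*gy + R(1,2)*gz + center;
      const double z = R(2,0)*gx + R(2,1)*gy + R(2,2)*gz + center;
      int i = (int)std::floor(x), jj = (int)std::floor(y), kk = (int)std::floor(z);
      if (i < 1 || jj < 1 || kk < 1 || i >= edge || jj >= edge || kk >= edge)
        continue;
      const double fx = x - i, fy = y - jj, fz = z - kk;
      const double val = wc[j];
      const int i0 = i - 1, j0 = jj - 1, k0 = kk - 1;
      const double w000 = wj*(1-fx)*(1-fy)*(1-fz), w100 = wj*fx*(1-fy)*(1-fz),
        w010 = wj*(1-fx)*fy*(1-fz), w001 = wj*(1-fx)*(1-fy)*fz,
        w110 = wj*fx*fy*(1-fz), w101 = wj*fx*(1-fy)*fz,
        w011 = wj*(1-fx)*fy*fz, w111 = wj*fx*fy*fz;
      num(i0,   j0,   k0  ) += w000*val; den(i0,   j0,   k0  ) += w000;
      num(i0+1, j0,   k0  ) += w100*val; den(i0+1, j0,   k0  ) += w100;
      num(i0,   j0+1, k0  ) += w010*val; den(i0,   j0+1, k0  ) += w010;
      num(i0,   j0,   k0+1) += w001*val; den(i0,   j0,   k0+1) += w001;
      num(i0+1, j0+1, k0  ) += w110*val; den(i0+1, j0+1, k0  ) += w110;
      num(i0+1, j0,   k0+1) += w101*val; den(i0+1, j0,   k0+1) += w101;
      num(i0,   j0+1, k0+1) += w011*val; den(i0,   j0+1, k0+1) += w011;
      num(i0+1, j0+1, k0+1) += w111*val; den(i0+1, j0+1, k0+1) += w111;
    }
    if (p % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["num"] = num, _["den"] = den);
}

// resample vol at M * x for every voxel offset x (about center); out-of-grid
// voxels become NaN
// [[Rcpp::export]]
arma::cube rotate_resample_cpp(const arma::cube& vol, const arma::mat& M,
                               const double center) {
  const int edge = vol.n_rows;
  arma::cube out(edge, edge, edge);
  for (int kz = 0; kz < edge; ++kz) {
    const double z0 = kz + 1 - center;
    for (int ky = 0; ky < edge; ++ky) {
      const double y0 = ky + 1 - center;
      for (int kx = 0; kx < edge; ++kx) {
        const double x0 = kx + 1 - center;
        const double x = M(0,0)*x0 + M(0,1)*y0 + M(0,2)*z0 + center;
        const double y = M(1,0)*x0 + M(1,1)*y0 + M(1,2)*z0 + center;
        const double z = M(2,0)*x0 + M(2,1)*y0 + M(2,2)*z0 + center;
        bool ok;
        const double v = trilinear(vol, x, y, z, ok);
        out(kx, ky, kz) = ok ? v : NA_REAL;
      }
    }
  }
  return out;
}

// Pearson correlation between ref values at voxel offsets `pts` and vol
// sampled at R_j * pts, for every quaternion; out-of-grid samples excluded
// [[Rcpp::export]]
arma::vec corr_quats_cpp(const arma::cube& vol, const arma::mat& pts,
                         const arma::vec& refvals, const arma::mat& quats,
                         const double center) {
  const arma::uword nq = quats.n_rows, m = pts.n_rows;
  arma::vec out(nq);
  for (arma::uword j = 0; j < nq; ++j) {
    arma::mat33 R = quat_to_mat(quats(j,0), quats(j,1), quats(j,2), quats(j,3));
    double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
    arma::uword n = 0;
    for (arma::uword p = 0; p < m; ++p) {
      const double x = R(0,0)*pts(p,0) + R(0,1)*pts(p,1) + R(0,2)*pts(p,2) + center;
      const double y = R(1,0)*pts(p,0) + R(1,1)*pts(p,1) + R(1,2)*pts(p,2) + center;
      const double z = R(2,0)*pts(p,0) + R(2,1)*pts(p,1) + R(2,2)*pts(p,2) + center;
      bool ok;
      const double v = trilinear(vol, x, y, z, ok);
      if (!ok || !std::isfinite(v)) continue;
      const double r = refvals(p);
      sx += v; sy += r; sxx += v*v; syy += r*r; sxy += v*r;
      ++n;
    }
    if (n < 10) { out(j) = -2.0; continue; }
    const double cov = sxy - sx*sy/n;
    const double vx = sxx - sx*sx/n, vy = syy - sy*sy/n;
    out(j) = (vx > 0 && vy > 0) ? cov / std::sqrt(vx*vy) : -2.0;
    if (j % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// general trilinear sampling at absolute 1-based points
// [[Rcpp::export]]
arma::vec trilinear_cpp(const arma::cube& vol, const arma::mat& pts) {
  arma::vec out(pts.n_rows);
  for (arma::uword p = 0; p < pts.n_rows; ++p) {
    bool ok;
    const double v = trilinear(vol, pts(p,0), pts(p,1), pts(p,2), ok);
    out(p) = ok ? v : NA_REAL;
  }
  return out;
}

// ---- in-place radix-2 FFT machinery for the HIO engine -------------------

static void fft1d_strided(std::complex<double>* a, const int n, const long stride,
                          const std::vector<std::complex<double>>& tw,
                          const bool inverse) {
  // bit-reversal permutation
  for (int i = 1, j = 0; i < n; ++i) {
    int bit = n >> 1;
    for (; j & bit; bit >>= 1) j ^= bit;
    j ^= bit;
    if (i < j) std::swap(a[(long)i * stride], a[(long)j * stride]);
  }
  for (int len = 2; len <= n; len <<= 1) {
    const int step = n / len;
    for (int i = 0; i < n; i += len) {
      for (int k = 0; k < len / 2; ++k) {
        std::complex<double> w = tw[(long)k * step];
        if (inverse) w = std::conj(w);
        std::complex<double>& u = a[(long)(i + k) * stride];
        std::complex<double>& v = a[(long)(i + k + len / 2) * stride];
        const std::complex<double> t = v * w;
        v = u - t;
        u += t;
      }
    }
  }
}

static void fft3d(std::vector<std::complex<double>>& a, const int n,
                  const std::vector<std::complex<double>>& tw,
                  const bool inverse) {
  const long n2 = (long)n * n;
  std::vector<std::complex<double>> buf(n);
  // axis 0 (stride 1)
  for (long s = 0; s < n2; ++s) fft1d_strided(&a[s * n], n, 1, tw, inverse);
  // axes 1 and 2: gather each line into a contiguous buffer (the strided
  // butterflies would touch a new cache line per element)
  for (long z = 0; z < n; ++z)
    for (long x = 0; x < n; ++x) {
      std::complex<double>* base = &a[z * n2 + x];
      for (int y = 0; y < n; ++y) buf[y] = base[(long)y * n];
      fft1d_strided(buf.data(), n, 1, tw, inverse);
      for (int y = 0; y < n; ++y) base[(long)y * n] = buf[y];
    }
  for (long y = 0; y < n; ++y)
    for (long x = 0; x < n; ++x) {
      std::complex<double>* base = &a[y * n + x];
      for (int z = 0; z < n; ++z) buf[z] = base[z * n2];
      fft1d_strided(buf.data(), n, 1, tw, inverse);
      for (int z = 0; z < n; ++z) base[z * n2] = buf[z];
    }
}

// hybrid input-output iterations (plus optional error-reduction finish) on a
// power-of-two cubic grid, all in wrapped (DFT-native) layout
// [[Rcpp::export]]
List hio_cpp(const arma::vec& mw, const arma::uvec& midx, const arma::uvec& vout,
             const int edge, const int n_hio, const int n_er,
             const double beta, const bool positivity, const arma::vec& x0) {
  if ((edge & (edge - 1)) != 0) stop("edge must be a power of two");
  const long n3 = (long)edge * edge * edge;
  std::vector<std::complex<double>> tw(edge / 2);
  for (int k = 0; k < edge / 2; ++k)
    tw[k] = std::polar(1.0, -2.0 * M_PI * k / edge);
  std::vector<std::complex<double>> G(n3);
  std::vector<double> x(n3), xp(n3);
  std::vector<char> insupp(n3, 1);
  for (arma::uword t = 0; t < vout.n_elem; ++t) insupp[vout(t)] = 0;
  for (long i = 0; i < n3; ++i) x[i] = x0(i);
  const double inv_n3 = 1.0 / (double)n3;
  for (int it = 0; it < n_hio + n_er; ++it) {
    for (long i = 0; i < n3; ++i) G[i] = std::complex<double>(x[i], 0.0);
    fft3d(G, edge, tw, false);
    for (arma::uword t = 0; t < midx.n_elem; ++t) {
      const long i = midx(t);
      const double mag = std::abs(G[i]);
      G[i] = (mag > 0) ? G[i] * (mw(t) / mag)
                       : std::complex<double>(mw(t), 0.0);
    }
    fft3d(G, edge, tw, true);
    for (long i = 0; i < n3; ++i) xp[i] = G[i].real() * inv_n3;
    if (it < n_hio) {
      // single pass so the feedback term reads the pre-update iterate
      for (long i = 0; i < n3; ++i) {
        const bool viol = !insupp[i] || (positivity && xp[i] < 0);
        x[i] = viol ? x[i] - beta * xp[i] : xp[i];
      }
    } else {
      for (long i = 0; i < n3; ++i) x[i] = (xp[i] > 0) ? xp[i] : 0.0;
      for (arma::uword t = 0; t < vout.n_elem; ++t) x[vout(t)] = 0.0;
    }
    Rcpp::checkUserInterrupt();
  }
  // final residual
  for (long i = 0; i < n3; ++i) G[i] = std::complex<double>(x[i], 0.0);
  fft3d(G, edge, tw, false);
  double num = 0.0, den = 0.0;
  for (arma::uword t = 0; t < midx.n_elem; ++t) {
    const double d = std::abs(G[midx(t)]) - mw(t);
    num += d * d;
    den += mw(t) * mw(t);
  }
  arma::vec xr(n3);
  for (long i = 0; i < n3; ++i) xr(i) = x[i];
  return List::create(_["x"] = xr, _["error"] = std::sqrt(num / den));
}
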
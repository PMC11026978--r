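// Sliding-block low-rank recovery core.
//
// A local k x k x k spatial block across all channel-volume columns is
// reshaped to an M x N matrix (M <= N), its singular spectrum is computed
// through the eigendecomposition of S S^T, each requested strategy shrinks
// the spectrum, and the recovered blocks are aggregated voxel-wise with
// weights 1 / (1 + rank).  All strategies share one eigendecomposition per
// block, so sweeping several strategies costs little more than one.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// strategy codes shared with R (see strategy_code() in R/shrinkage.R)
enum Strategy { ST_MP_PCA = 0, ST_TSVD = 1, ST_HARD = 2, ST_SOFT = 3,
                ST_FRO = 4, ST_OP = 5, ST_NUC = 6 };
// estimator codes: 0 = MP-median (Gavish-Donoho), 1 = simultaneous MP fit

static inline double z_of_y(double y, double delta) {
  const double thr = 1.0 + std::sqrt(delta);
  if (y < thr) return 0.0;
  const double a = y * y - delta - 1.0;
  double disc = a * a - 4.0 * delta;
  if (disc < 0.0) disc = 0.0; // analytically >= 0 above the bulk edge
  return std::sqrt(0.5 * (a + std::sqrt(disc)));
}

static inline double hard_level(double delta) {
  return std::sqrt(2.0 * (delta + 1.0) +
                   8.0 * delta / ((delta + 1.0) +
                                  std::sqrt(delta * delta + 14.0 * delta + 1.0)));
}

static double eta_of_y(double y, double delta, int strategy, double yhard) {
  const double thr = 1.0 + std::sqrt(delta);
  switch (strategy) {
  case ST_TSVD:
    return (y >= thr) ? y : 0.0;
  case ST_HARD:
    return (y >= yhard) ? y : 0.0;
  case ST_SOFT:
    return (y >= thr) ? (y - thr) : 0.0;
  case ST_FRO: {
    if (y < thr) return 0.0;
    const double a = y * y - delta - 1.0;
    double disc = a * a - 4.0 * delta;
    if (disc < 0.0) disc = 0.0;
    return std::sqrt(disc) / y;
  }
  case ST_OP:
    return z_of_y(y, delta);
  case ST_NUC: {
    const double z = z_of_y(y, delta);
    if (z <= 0.0) return 0.0;
    const double z2 = z * z;
    const double lhs = z2 * z2;
    const double rhs = delta + std::sqrt(delta) * y * z;
    return (lhs >= rhs) ? (lhs - rhs) / (z2 * y) : 0.0;
  }
  }
  return 0.0;
}

// Simultaneous estimation of the signal count P and the noise variance from
// the eigenvalues of S S^T (ascending, raw scale).  Scans the candidate bulk
// from below: a bulk of the p+1 smallest eigenvalues is accepted while its
// Marchenko-Pastur width estimate (lam_max - lam_min) / (4 sqrt(gamma)) stays
// below its mean; the largest accepted bulk gives the noise variance and
// P = M - bulk size.
static void mp_fit(const arma::vec &lam_asc, int ncols, int &P, double &sigsq) {
  const int m = (int)lam_asc.n_elem;
  if (m == 0 || lam_asc(m - 1) <= 0.0) { P = 0; sigsq = 0.0; return; }
  const double lmin = std::max(lam_asc(0), 0.0) / ncols;
  double clam = 0.0;
  int cutoff = 0;
  sigsq = 0.0;
  for (int p = 0; p < m; ++p) {
    const double lam = std::max(lam_asc(p), 0.0) / ncols;
    clam += lam;
    const double gam = (double)(p + 1) / ncols;
    const double s_mean = clam / (p + 1);
    const double s_rng = (lam - lmin) / (4.0 * std::sqrt(gam));
    if (s_rng < s_mean) { cutoff = p + 1; sigsq = s_mean; }
  }
  P = m - cutoff;
  if (P >= m) P = m - 1; // degenerate cap
}

// [[Rcpp::export]]
List mp_fit_cpp(NumericVector lambda_asc, int ncols) {
  arma::vec lam(lambda_asc.begin(), lambda_asc.size());
  int P; double sigsq;
  mp_fit(lam, ncols, P, sigsq);
  return List::create(_["P"] = P, _["sigsq"] = sigsq);
}

static inline double median_of(arma::vec v) { // by value: sorted in place
  v = arma::sort(v);
  const arma::uword m = v.n_elem;
  return (m % 2 == 1) ? v(m / 2) : 0.5 * (v(m / 2 - 1) + v(m / 2));
}

// data: nx*ny*nz*q real array (x fastest), q = C*V columns per voxel.
// Returns per-strategy denoised arrays plus aggregated sigma and rank maps.
// sigma_fixed > 0 uses a global noise level instead of per-block estimates.
// Voxels covered by no block (possible for stride > 1) pass through.
// [[Rcpp::export]]
List denoise_core_cpp(NumericVector data, IntegerVector dims, int k, int stride,
                      IntegerVector strategies, IntegerVector estimators,
                      double delta_med, double sigma_fixed,
                      IntegerVector out_dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], q = dims[3];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const int k3 = k * k * k;
  const bool rows_spatial = (k3 <= q);
  const int m = rows_spatial ? k3 : q;
  const int n = rows_spatial ? q : k3;
  const double delta = (double)m / n;
  const double yhard = hard_level(delta);
  const int nstrat = strategies.size();
  const double *src = REAL(data);

  if (nx < k || ny < k || nz < k)
    stop("block edge k = %d exceeds the image extent", k);
  if (m < 2)
    stop("signal matrix would have fewer than 2 rows (M = %d): insufficient redundancy", m);

  std::vector<NumericVector> acc(nstrat), sig_acc(nstrat), rank_acc(nstrat),
      wsum(nstrat);
  for (int j = 0; j < nstrat; ++j) {
    acc[j] = NumericVector(nvox * q);
    sig_acc[j] = NumericVector(nvox);
    rank_acc[j] = NumericVector(nvox);
    wsum[j] = NumericVector(nvox);
  }

  arma::mat S(m, n), K(m, m), T(m, n), Shat(m, n);
  arma::vec eval, g(m), svals(m);
  arma::mat evec;

  long nblocks = 0;
  for (int z0 = 0; z0 + k <= nz; z0 += stride) {
    for (int y0 = 0; y0 + k <= ny; y0 += stride) {
      for (int x0 = 0; x0 + k <= nx; x0 += stride) {
        if ((nblocks & 63) == 0) Rcpp::checkUserInterrupt();
        ++nblocks;
        // gather block: r indexes the k^3 spatial offsets, v the q columns
        for (int v = 0; v < q; ++v) {
          const double *col = src + (R_xlen_t)v * nvox;
          int r = 0;
          for (int dz = 0; dz < k; ++dz)
            for (int dy = 0; dy < k; ++dy) {
              const double *row =
                  col + ((R_xlen_t)(z0 + dz) * ny + (y0 + dy)) * nx + x0;
              for (int dx = 0; dx < k; ++dx, ++r) {
                if (rows_spatial) S(r, v) = row[dx];
                else              S(v, r) = row[dx];
              }
            }
        }
        K = S * S.t();
        arma::eig_sym(eval, evec, K); // ascending
        for (int i = 0; i < m; ++i)
          svals(i) = std::sqrt(std::max(eval(i), 0.0));
        T = evec.t() * S; // component scores, shared across strategies

        for (int j = 0; j < nstrat; ++j) {
          const int strat = strategies[j];
          int rank = 0;
          double sig = 0.0;
          if (strat == ST_MP_PCA) {
            int P; double sigsq;
            mp_fit(eval, n, P, sigsq);
            sig = std::sqrt(std::max(sigsq, 0.0));
            // retain the fitted signal components unchanged; additionally
            // retain any eigenvalue at or above the (M - P)-scaled variance
            // threshold (keeps the degenerate noise-free branch lossless)
            const double thr = (m - P) * sigsq;
            for (int i = 0; i < m; ++i) {
              const bool top = (m - 1 - i) < P; // descending index < P
              const bool keep = top || (sigsq > 0.0 && eval(i) / n >= thr) ||
                                (sigsq == 0.0 && svals(i) > 0.0);
              g(i) = keep ? 1.0 : 0.0;
              if (keep && svals(i) > 0.0) ++rank;
            }
          } else {
            if (sigma_fixed > 0.0) {
              sig = sigma_fixed;
            } else if (estimators[j] == 1) {
              int P; double sigsq;
              mp_fit(eval, n, P, sigsq);
              sig = std::sqrt(std::max(sigsq, 0.0));
            } else {
              sig = median_of(svals) / std::sqrt(n * delta_med);
            }
            if (sig <= 0.0) { // noise-free block: pass through unchanged
              for (int i = 0; i < m; ++i) {
                g(i) = 1.0;
                if (svals(i) > 0.0) ++rank;
              }
            } else {
              const double scale = sig * std::sqrt((double)n);
              for (int i = 0; i < m; ++i) {
                if (svals(i) <= 0.0) { g(i) = 0.0; continue; }
                const double y = svals(i) / scale;
                const double shat = scale * eta_of_y(y, delta, strat, yhard);
                g(i) = shat / svals(i);
                if (shat > 0.0) ++rank;
              }
            }
          }
          // reconstruct from the retained components only: with r nonzero
          // gains this costs O(m r n) instead of O(m^2 n)
          arma::uvec keep = arma::find(g != 0.0);
          if ((int)keep.n_elem == m) {
            Shat = evec * (arma::diagmat(g) * T);
          } else if (keep.n_elem == 0) {
            Shat.zeros();
          } else {
            arma::mat Tk = T.rows(keep);
            Tk.each_col() %= g.elem(keep);
            Shat = evec.cols(keep) * Tk;
          }
          const double w = 1.0 / (1.0 + rank);

          double *dst = REAL(acc[j]);
          for (int v = 0; v < q; ++v) {
            double *col = dst + (R_xlen_t)v * nvox;
            int r = 0;
            for (int dz = 0; dz < k; ++dz)
              for (int dy = 0; dy < k; ++dy) {
                double *row =
                    col + ((R_xlen_t)(z0 + dz) * ny + (y0 + dy)) * nx + x0;
                for (int dx = 0; dx < k; ++dx, ++r)
                  row[dx] += w * (rows_spatial ? Shat(r, v) : Shat(v, r));
              }
          }
          double *sd = REAL(sig_acc[j]);
          double *rd = REAL(rank_acc[j]);
          double *wd = REAL(wsum[j]);
          for (int dz = 0; dz < k; ++dz)
            for (int dy = 0; dy < k; ++dy) {
              const R_xlen_t base =
                  ((R_xlen_t)(z0 + dz) * ny + (y0 + dy)) * nx + x0;
              for (int dx = 0; dx < k; ++dx) {
                sd[base + dx] += w * sig;
                rd[base + dx] += w * rank;
                wd[base + dx] += w;
              }
            }
        }
      }
    }
  }

  // normalize: covered voxels are weight-averaged, uncovered pass through
  for (int j = 0; j < nstrat; ++j) {
    double *dst = REAL(acc[j]);
    double *sd = REAL(sig_acc[j]);
    double *rd = REAL(rank_acc[j]);
    const double *wd = REAL(wsum[j]);
    for (R_xlen_t i = 0; i < nvox; ++i) {
      const double w = wd[i];
      if (w > 0.0) {
        const double iw = 1.0 / w;
        for (int v = 0; v < q; ++v)
          dst[(R_xlen_t)v * nvox + i] *= iw;
        sd[i] *= iw;
        rd[i] *= iw;
      } else {
        for (int v = 0; v < q; ++v)
          dst[(R_xlen_t)v * nvox + i] = src[(R_xlen_t)v * nvox + i];
        sd[i] = NA_REAL;
        rd[i] = NA_REAL;
      }
    }
  }

  // attach shapes here so the R wrapper does not have to copy the arrays
  IntegerVector shape3 = IntegerVector::create(nx, ny, nz);
  for (int j = 0; j < nstrat; ++j) {
    acc[j].attr("dim") = out_dims;
    sig_acc[j].attr("dim") = shape3;
    rank_acc[j].attr("dim") = shape3;
  }
  wsum[0].attr("dim") = shape3;

  return List::create(_["denoised"] = List(acc.begin(), acc.end()),
                      _["sigma"] = List(sig_acc.begin(), sig_acc.end()),
                      _["rank"] = List(rank_acc.begin(), rank_acc.end()),
                      _["coverage"] = wsum[0],
                      _["n_blocks"] = (double)nblocks,
                      _["m"] = m, _["n"] = n);
}
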
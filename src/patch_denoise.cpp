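// Patch-sweep kernels for locally low-rank denoising.
//
// Data layout: a 4D series (x, y, z, t) is addressed as a voxels-by-time
// matrix in column-major order, voxel index v = x + dx*(y + dy*z). Patches
// are axis-aligned boxes; the Casorati matrix of a patch is (patch voxels)
// x T. Overlapping patch reconstructions are averaged with uniform weights
// by accumulating values and counts.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void patch_indices(const arma::uvec& sx, const arma::uvec& sy,
                                 const arma::uvec& sz, arma::uword ix,
                                 arma::uword iy, arma::uword iz,
                                 const arma::uvec& sides,
                                 const arma::uvec& dims, arma::uvec& idx) {
  arma::uword n = 0;
  for (arma::uword z = 0; z < sides[2]; ++z)
    for (arma::uword y = 0; y < sides[1]; ++y)
      for (arma::uword x = 0; x < sides[0]; ++x)
        idx[n++] = (sx[ix] + x) + dims[0] * ((sy[iy] + y) +
                    dims[1] * (sz[iz] + z));
}

// Hard singular-value thresholding of each patch Casorati matrix: zero all
// singular values <= tau, reconstruct, and average overlaps.
// [[Rcpp::export]]
List cpp_llr_svt(const arma::cx_mat& V, IntegerVector dims4,
                 IntegerVector starts_x, IntegerVector starts_y,
                 IntegerVector starts_z, IntegerVector sides3, double tau) {
  arma::uvec dims = {(arma::uword)dims4[0], (arma::uword)dims4[1],
                     (arma::uword)dims4[2]};
  arma::uword T = dims4[3];
  arma::uvec sides = {(arma::uword)sides3[0], (arma::uword)sides3[1],
                      (arma::uword)sides3[2]};
  arma::uvec sx = as<arma::uvec>(starts_x) - 1;
  arma::uvec sy = as<arma::uvec>(starts_y) - 1;
  arma::uvec sz = as<arma::uvec>(starts_z) - 1;
  arma::uword m = sides[0] * sides[1] * sides[2];

  arma::cx_mat acc(V.n_rows, T, arma::fill::zeros);
  arma::vec wt(V.n_rows, arma::fill::zeros);
  arma::uvec idx(m);
  std::vector<int> ranks;
  ranks.reserve(sx.n_elem * sy.n_elem * sz.n_elem);

  arma::cx_mat X(m, T), H(T, T), Vr, rec;
  arma::vec eigval;
  arma::cx_mat eigvec;

  for (arma::uword iz = 0; iz < sz.n_elem; ++iz)
    for (arma::uword iy = 0; iy < sy.n_elem; ++iy)
      for (arma::uword ix = 0; ix < sx.n_elem; ++ix) {
        patch_indices(sx, sy, sz, ix, iy, iz, sides, dims, idx);
        X = V.rows(idx);
        H = X.t() * X;  // Hermitian Gram, T x T
        arma::eig_sym(eigval, eigvec, H);
        // eigval ascending; singular values sqrt(max(ev, 0))
        arma::uword keep_from = T;
        for (arma::uword j = 0; j < T; ++j) {
          double sv = eigval[j] > 0 ? std::sqrt(eigval[j]) : 0.0;
          if (sv > tau) { keep_from = j; break; }
        }
        int r = (keep_from == T) ? 0 : (int)(T - keep_from);
        ranks.push_back(r);
        if (r == (int)T) {
          rec = X;
        } else if (r == 0) {
          rec.zeros(m, T);
        } else {
          Vr = eigvec.cols(keep_from, T - 1);
          rec = (X * Vr) * Vr.t();
        }
        acc.rows(idx) += rec;
        wt.elem(idx) += 1.0;
      }

  return List::create(_["acc"] = acc, _["weight"] = wt,
                      _["ranks"] = wrap(ranks));
}

// Marchenko-Pastur PCA denoising of each patch: classify the trailing
// eigenvalue bulk of the patch covariance as noise when its spread is
// consistent with the MP law, estimate sigma^2 from the bulk mean, and
// reconstruct from the remaining components.
// [[Rcpp::export]]
List cpp_mppca(const arma::mat& V, IntegerVector dims4,
               IntegerVector starts_x, IntegerVector starts_y,
               IntegerVector starts_z, IntegerVector sides3) {
  arma::uvec dims = {(arma::uword)dims4[0], (arma::uword)dims4[1],
                     (arma::uword)dims4[2]};
  arma::uword T = dims4[3];
  arma::uvec sides = {(arma::uword)sides3[0], (arma::uword)sides3[1],
                      (arma::uword)sides3[2]};
  arma::uvec sx = as<arma::uvec>(starts_x) - 1;
  arma::uvec sy = as<arma::uvec>(starts_y) - 1;
  arma::uvec sz = as<arma::uvec>(starts_z) - 1;
  arma::uword m = sides[0] * sides[1] * sides[2];
  arma::uword n_small = std::min(m, T), n_large = std::max(m, T);

  arma::mat acc(V.n_rows, T, arma::fill::zeros);
  arma::vec wt(V.n_rows, arma::fill::zeros);
  arma::uvec idx(m);
  std::vector<int> ranks;
  std::vector<double> sigmas;

  arma::mat X(m, T), G, eigvec, Br, rec;
  arma::vec eigval;

  for (arma::uword iz = 0; iz < sz.n_elem; ++iz)
    for (arma::uword iy = 0; iy < sy.n_elem; ++iy)
      for (arma::uword ix = 0; ix < sx.n_elem; ++ix) {
        patch_indices(sx, sy, sz, ix, iy, iz, sides, dims, idx);
        X = V.rows(idx);
        bool gram_t = (T <= m);  // Gram of the smaller dimension
        G = gram_t ? arma::mat(X.t() * X) : arma::mat(X * X.t());
        arma::eig_sym(eigval, eigvec, G);
        arma::vec lam = eigval / (double)n_large;  // ascending
        // iterate candidate noise-bulk sizes p = 1..n_small; the bulk is
        // accepted while its spread stays below the MP edge width for the
        // sigma^2 implied by its mean
        double clam = 0.0, sigma2 = 0.0;
        arma::uword p_noise = 0;
        for (arma::uword p = 1; p <= n_small; ++p) {
          double l = std::max(lam[p - 1], 0.0);
          clam += l;
          double sig1 = clam / (double)p;
          double gam = (double)p / (double)n_small;
          double sig2 = (l - std::max(lam[0], 0.0)) / (4.0 * std::sqrt(gam));
          if (sig2 <= sig1) { sigma2 = sig1; p_noise = p; }
        }
        int r = (int)(n_small - p_noise);
        ranks.push_back(r);
        sigmas.push_back(std::sqrt(std::max(sigma2, 0.0)));
        if (r == (int)n_small) {
          rec = X;
        } else if (r == 0) {
          rec.zeros(m, T);
        } else {
          Br = eigvec.cols(p_noise, n_small - 1);
          rec = gram_t ? arma::mat((X * Br) * Br.t())
                       : arma::mat(Br * (Br.t() * X));
        }
        acc.rows(idx) += rec;
        wt.elem(idx) += 1.0;
      }

  return List::create(_["acc"] = acc, _["weight"] = wt,
                      _["ranks"] = wrap(ranks), _["sigmas"] = wrap(sigmas));
}
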
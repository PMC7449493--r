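// Dense numeric cores for the network engine: im2col-based convolution
// (forward + backward), max pooling and nearest-neighbour upsampling.
// Feature maps are flat vectors with dims (C, X, Y, Z), column-major
// (channel fastest). Convolution weights are (C_out x K) matrices with
// K = C_in * kx * ky * kz, row index cin + C_in*(tx + kx*(ty + ky*tz)).
// "Same" padding: pad_lo = floor(((k-1)*dil)/2) per axis.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col(const double *x, int C, int X, int Y, int Z,
                        int kx, int ky, int kz, int dil) {
  const int K = C * kx * ky * kz;
  const long N = (long)X * Y * Z;
  const int plx = ((kx - 1) * dil) / 2, ply = ((ky - 1) * dil) / 2, plz = ((kz - 1) * dil) / 2;
  arma::mat cols(K, N, arma::fill::zeros);
  for (int tz = 0; tz < kz; ++tz)
    for (int ty = 0; ty < ky; ++ty)
      for (int tx = 0; tx < kx; ++tx) {
        const int row0 = C * (tx + kx * (ty + ky * tz));
        const int ox = tx * dil - plx, oy = ty * dil - ply, oz = tz * dil - plz;
        for (int z = 0; z < Z; ++z) {
          int zi = z + oz;
          if (zi < 0 || zi >= Z) continue;
          for (int y = 0; y < Y; ++y) {
            int yi = y + oy;
            if (yi < 0 || yi >= Y) continue;
            int x0 = std::max(0, -ox), x1 = std::min(X, X - ox);
            for (int xx = x0; xx < x1; ++xx) {
              int xi = xx + ox;
              long n = xx + (long)X * (y + (long)Y * z);
              long src = (long)C * (xi + (long)X * (yi + (long)Y * zi));
              std::copy(x + src, x + src + C, cols.colptr(n) + row0);
            }
          }
        }
      }
  return cols;
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericMatrix W, NumericVector b,
                           int C, int X, int Y, int Z,
                           int kx, int ky, int kz, int dil) {
  arma::mat cols = im2col(x.begin(), C, X, Y, Z, kx, ky, kz, dil);
  arma::mat Wm(W.begin(), W.nrow(), W.ncol(), false);
  arma::mat out = Wm * cols;
  out.each_col() += arma::vec(b.begin(), b.size(), false);
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(W.nrow(), X, Y, Z);
  return res;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericMatrix W, NumericVector dy,
                  int C, int X, int Y, int Z,
                  int kx, int ky, int kz, int dil) {
  const int Cout = W.nrow(), K = W.ncol();
  const long N = (long)X * Y * Z;
  arma::mat cols = im2col(x.begin(), C, X, Y, Z, kx, ky, kz, dil);
  arma::mat dY(dy.begin(), Cout, N, false);
  arma::mat dW = dY * cols.t();
  arma::vec db = arma::sum(dY, 1);
  arma::mat Wm(W.begin(), Cout, K, false);
  arma::mat dcols = Wm.t() * dY;  // K x N
  // col2im: scatter-add column gradients back to input positions
  NumericVector dx((long)C * X * Y * Z);
  const int plx = ((kx - 1) * dil) / 2, ply = ((ky - 1) * dil) / 2, plz = ((kz - 1) * dil) / 2;
  for (int tz = 0; tz < kz; ++tz)
    for (int ty = 0; ty < ky; ++ty)
      for (int tx = 0; tx < kx; ++tx) {
        const int row0 = C * (tx + kx * (ty + ky * tz));
        const int ox = tx * dil - plx, oy = ty * dil - ply, oz = tz * dil - plz;
        for (int z = 0; z < Z; ++z) {
          int zi = z + oz;
          if (zi < 0 || zi >= Z) continue;
          for (int y = 0; y < Y; ++y) {
            int yi = y + oy;
            if (yi < 0 || yi >= Y) continue;
            int x0 = std::max(0, -ox), x1 = std::min(X, X - ox);
            for (int xx = x0; xx < x1; ++xx) {
              int xi = xx + ox;
              long n = xx + (long)X * (y + (long)Y * z);
              long dst = (long)C * (xi + (long)X * (yi + (long)Y * zi));
              const double *src = dcols.colptr(n) + row0;
              for (int c = 0; c < C; ++c) dx[dst + c] += src[c];
            }
          }
        }
      }
  dx.attr("dim") = IntegerVector::create(C, X, Y, Z);
  NumericMatrix dWr(Cout, K);
  std::copy(dW.begin(), dW.end(), dWr.begin());
  return List::create(_["dW"] = dWr,
                      _["db"] = NumericVector(db.begin(), db.end()),
                      _["dx"] = dx);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int C, int X, int Y, int Z,
                     int fx, int fy, int fz) {
  const int Xo = X / fx, Yo = Y / fy, Zo = Z / fz;
  NumericVector out((long)C * Xo * Yo * Zo);
  IntegerVector arg(out.size());
  for (int zo = 0; zo < Zo; ++zo)
    for (int yo = 0; yo < Yo; ++yo)
      for (int xo = 0; xo < Xo; ++xo)
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf;
          long bidx = -1;
          for (int dz = 0; dz < fz; ++dz)
            for (int dy = 0; dy < fy; ++dy)
              for (int dx = 0; dx < fx; ++dx) {
                long idx = c + (long)C * ((xo * fx + dx) +
                           (long)X * ((yo * fy + dy) + (long)Y * (zo * fz + dz)));
                if (x[idx] > best) { best = x[idx]; bidx = idx; }
              }
          long o = c + (long)C * (xo + (long)Xo * (yo + (long)Yo * zo));
          out[o] = best;
          arg[o] = (int)bidx;
        }
  out.attr("dim") = IntegerVector::create(C, Xo, Yo, Zo);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dy, IntegerVector argmax,
                              int C, int X, int Y, int Z) {
  NumericVector dx((long)C * X * Y * Z);
  for (long i = 0; i < dy.size(); ++i) dx[argmax[i]] += dy[i];
  dx.attr("dim") = IntegerVector::create(C, X, Y, Z);
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_fwd(NumericVector x, int C, int X, int Y, int Z,
                               int fx, int fy, int fz) {
  const int Xo = X * fx, Yo = Y * fy, Zo = Z * fz;
  NumericVector out((long)C * Xo * Yo * Zo);
  for (int zo = 0; zo < Zo; ++zo)
    for (int yo = 0; yo < Yo; ++yo)
      for (int xo = 0; xo < Xo; ++xo) {
        long src = (long)C * ((xo / fx) + (long)X * ((yo / fy) + (long)Y * (zo / fz)));
        long dst = (long)C * (xo + (long)Xo * (yo + (long)Yo * zo));
        std::copy(x.begin() + src, x.begin() + src + C, out.begin() + dst);
      }
  out.attr("dim") = IntegerVector::create(C, Xo, Yo, Zo);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_bwd(NumericVector dy, int C, int X, int Y, int Z,
                               int fx, int fy, int fz) {
  // X, Y, Z are the (smaller) input dims; dy has dims (C, X*fx, Y*fy, Z*fz)
  const int Xo = X * fx, Yo = Y * fy, Zo = Z * fz;
  NumericVector dx((long)C * X * Y * Z);
  for (int zo = 0; zo < Zo; ++zo)
    for (int yo = 0; yo < Yo; ++yo)
      for (int xo = 0; xo < Xo; ++xo) {
        long dst = (long)C * ((xo / fx) + (long)X * ((yo / fy) + (long)Y * (zo / fz)));
        long src = (long)C * (xo + (long)Xo * (yo + (long)Yo * zo));
        for (int c = 0; c < C; ++c) dx[dst + c] += dy[src + c];
      }
  dx.attr("dim") = IntegerVector::create(C, X, Y, Z);
  return dx;
}
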
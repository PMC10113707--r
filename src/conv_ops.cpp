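// Dense 2-D convolution primitives used by the network layers.
//
// Layout conventions (shared with the R side, see R/nn-core.R):
//   feature tensors   arma::cube  H x W x C          (slice = channel)
//   filter banks      arma::mat   Cout x (k*k*Cin)   row-major over output
//                     channels; the k*k*Cin axis is ordered kr (fastest),
//                     kc, then input channel, matching matrix(w, k*k*Cin)
//                     of an R array dim c(k, k, Cin, Cout).
// Cross-correlation (no kernel flip), zero padding, square kernel/stride.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Patch matrix: (k*k*Cin) x (Ho*Wo), output locations column-major (row
// index fastest), consistent with R's matrix(..., Ho, Wo) filling.
static mat im2col(const cube& X, int k, int stride, int pad) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  mat P(k * k * C, Ho * Wo, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& Xc = X.slice(c);
    for (int kc = 0; kc < k; ++kc) {
      for (int kr = 0; kr < k; ++kr) {
        const int prow = c * k * k + kc * k + kr;
        for (int j = 0; j < Wo; ++j) {
          const int cc = j * stride - pad + kc;
          if (cc < 0 || cc >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int rr = i * stride - pad + kr;
            if (rr < 0 || rr >= H) continue;
            P(prow, j * Ho + i) = Xc(rr, cc);
          }
        }
      }
    }
  }
  return P;
}

static cube col2im(const mat& P, int H, int W, int C, int k, int stride, int pad) {
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  cube X(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& Xc = X.slice(c);
    for (int kc = 0; kc < k; ++kc) {
      for (int kr = 0; kr < k; ++kr) {
        const int prow = c * k * k + kc * k + kr;
        for (int j = 0; j < Wo; ++j) {
          const int cc = j * stride - pad + kc;
          if (cc < 0 || cc >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int rr = i * stride - pad + kr;
            if (rr < 0 || rr >= H) continue;
            Xc(rr, cc) += P(prow, j * Ho + i);
          }
        }
      }
    }
  }
  return X;
}

// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube& X, const arma::mat& Wmat,
                      const arma::vec& b, int k, int stride, int pad) {
  const int Ho = out_size(X.n_rows, k, stride, pad);
  const int Wo = out_size(X.n_cols, k, stride, pad);
  const int Cout = Wmat.n_rows;
  mat Y = Wmat * im2col(X, k, stride, pad);   // Cout x (Ho*Wo)
  Y.each_col() += b;
  cube out(Ho, Wo, Cout);
  for (int c = 0; c < Cout; ++c)
    out.slice(c) = reshape(Y.row(c), Ho, Wo);
  return out;
}

// [[Rcpp::export]]
arma::cube conv2d_bwd_input(const arma::cube& dY, const arma::mat& Wmat,
                            int H, int W, int Cin, int k, int stride, int pad) {
  const int Ho = dY.n_rows, Wo = dY.n_cols, Cout = dY.n_slices;
  mat dYmat(Cout, Ho * Wo);
  for (int c = 0; c < Cout; ++c)
    dYmat.row(c) = vectorise(dY.slice(c)).t();
  mat dP = Wmat.t() * dYmat;
  return col2im(dP, H, W, Cin, k, stride, pad);
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd_weight(const arma::cube& X, const arma::cube& dY,
                             int k, int stride, int pad) {
  const int Ho = dY.n_rows, Wo = dY.n_cols, Cout = dY.n_slices;
  mat dYmat(Cout, Ho * Wo);
  for (int c = 0; c < Cout; ++c)
    dYmat.row(c) = vectorise(dY.slice(c)).t();
  mat P = im2col(X, k, stride, pad);
  mat dW = dYmat * P.t();                     // Cout x (k*k*Cin)
  vec db = sum(dYmat, 1);
  return Rcpp::List::create(Rcpp::Named("dW") = dW, Rcpp::Named("db") = db);
}

// Batched variants: loop over samples in C++ to amortise call overhead.

// [[Rcpp::export]]
Rcpp::List conv2d_fwd_batch(Rcpp::List Xs, const arma::mat& Wmat,
                            const arma::vec& b, int k, int stride, int pad) {
  const int B = Xs.size();
  Rcpp::List out(B);
  for (int i = 0; i < B; ++i) {
    cube X = Rcpp::as<cube>(Xs[i]);
    out[i] = conv2d_fwd(X, Wmat, b, k, stride, pad);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd_batch(Rcpp::List Xs, Rcpp::List dYs, const arma::mat& Wmat,
                            int k, int stride, int pad) {
  const int B = Xs.size();
  Rcpp::List dXs(B);
  mat dW(Wmat.n_rows, Wmat.n_cols, fill::zeros);
  vec db(Wmat.n_rows, fill::zeros);
  for (int i = 0; i < B; ++i) {
    cube X = Rcpp::as<cube>(Xs[i]);
    cube dY = Rcpp::as<cube>(dYs[i]);
    const int Ho = dY.n_rows, Wo = dY.n_cols, Cout = dY.n_slices;
    mat dYmat(Cout, Ho * Wo);
    for (int c = 0; c < Cout; ++c)
      dYmat.row(c) = vectorise(dY.slice(c)).t();
    mat P = im2col(X, k, stride, pad);
    dW += dYmat * P.t();
    db += sum(dYmat, 1);
    dXs[i] = col2im(Wmat.t() * dYmat, X.n_rows, X.n_cols, X.n_slices, k, stride, pad);
  }
  return Rcpp::List::create(Rcpp::Named("dXs") = dXs,
                            Rcpp::Named("dW") = dW, Rcpp::Named("db") = db);
}
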
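// Hot computational kernels: strided 1-D convolution and the weighted
// sine-wave decoder, forward and backward.  Layouts match the R code:
// signal batches are C x T x B cubes, weight matrices are c_out x (C*K)
// with column index c + C*(k-1), sine-decoder amplitudes are (C*H) x B.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".conv1d_fwd_cpp")]]
Rcpp::List conv1d_fwd_cpp(const arma::mat& W, const arma::vec& b, const arma::cube& X,
                          const int stride, const int K,
                          const int pad_l, const int pad_r) {
  const int C = X.n_rows, T = X.n_cols, B = X.n_slices;
  const int Tp = T + pad_l + pad_r;
  const int Tout = (Tp - K) / stride + 1;
  const int c_out = W.n_rows;

  mat P(C * K, Tout * B, fill::zeros);
  for (int bi = 0; bi < B; ++bi) {
    const arma::mat& Xs = X.slice(bi);
    for (int j = 0; j < Tout; ++j) {
      const int start = j * stride - pad_l;  // position in unpadded signal
      double* col = P.colptr(bi * Tout + j);
      for (int k = 0; k < K; ++k) {
        const int t = start + k;
        if (t >= 0 && t < T)
          for (int c = 0; c < C; ++c) col[k * C + c] = Xs.at(c, t);
      }
    }
  }
  mat Ym = W * P;
  Ym.each_col() += b;
  cube Y(Ym.memptr(), c_out, Tout, B);
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("P") = P);
}

// [[Rcpp::export(name = ".conv1d_bwd_cpp")]]
Rcpp::List conv1d_bwd_cpp(const arma::mat& W, const arma::mat& P, const arma::cube& dY,
                          const int C, const int T, const int stride,
                          const int K, const int pad_l) {
  const int c_out = dY.n_rows, Tout = dY.n_cols, B = dY.n_slices;
  const mat dYm(const_cast<double*>(dY.memptr()), c_out, Tout * B, false);
  mat dW = dYm * P.t();
  vec db = sum(dYm, 1);
  mat dP = W.t() * dYm;  // (C*K) x (Tout*B)

  cube dX(C, T, B, fill::zeros);
  for (int bi = 0; bi < B; ++bi) {
    mat& dXs = dX.slice(bi);
    for (int j = 0; j < Tout; ++j) {
      const int start = j * stride - pad_l;
      const double* col = dP.colptr(bi * Tout + j);
      for (int k = 0; k < K; ++k) {
        const int t = start + k;
        if (t >= 0 && t < T)
          for (int c = 0; c < C; ++c) dXs.at(c, t) += col[k * C + c];
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW, Rcpp::Named("db") = db,
                            Rcpp::Named("dX") = dX);
}

// [[Rcpp::export(name = ".sine_fwd_cpp")]]
Rcpp::List sine_fwd_cpp(const arma::mat& vA, const arma::mat& Om, const arma::mat& Ph,
                        const arma::vec& tau, const int C) {
  const int H = Om.n_rows, B = Om.n_cols, T = tau.n_elem;
  cube Xhat(C, T, B, fill::zeros);
  mat S(H * B, T);
  for (int bi = 0; bi < B; ++bi) {
    mat Sb(H, T);
    for (int t = 0; t < T; ++t)
      for (int k = 0; k < H; ++k)
        Sb.at(k, t) = std::sin(Om.at(k, bi) * tau[t] + Ph.at(k, bi));
    const mat Ab(const_cast<double*>(vA.colptr(bi)), C, H, false);
    Xhat.slice(bi) = Ab * Sb;
    S.rows(bi * H, bi * H + H - 1) = Sb;
  }
  return Rcpp::List::create(Rcpp::Named("Xhat") = Xhat,
                            Rcpp::Named("S") = S);
}

// [[Rcpp::export(name = ".sine_bwd_cpp")]]
Rcpp::List sine_bwd_cpp(const arma::mat& vA, const arma::mat& Om, const arma::mat& Ph,
                        const arma::vec& tau, const arma::mat& S, const arma::cube& dXhat,
                        const int C) {
  const int H = Om.n_rows, B = Om.n_cols, T = tau.n_elem;
  mat dvA(C * H, B), dOm(H, B), dPh(H, B);
  for (int bi = 0; bi < B; ++bi) {
    const arma::mat& dXb = dXhat.slice(bi);
    const mat Sb = S.rows(bi * H, bi * H + H - 1);
    const mat Ab(const_cast<double*>(vA.colptr(bi)), C, H, false);
    mat dAb = dXb * Sb.t();                    // C x H
    dvA.col(bi) = vectorise(dAb);
    mat dMb = Ab.t() * dXb;                    // H x T, then * cos(M)
    for (int t = 0; t < T; ++t)
      for (int k = 0; k < H; ++k)
        dMb.at(k, t) *= std::cos(Om.at(k, bi) * tau[t] + Ph.at(k, bi));
    dOm.col(bi) = dMb * tau;
    dPh.col(bi) = sum(dMb, 1);
  }
  return Rcpp::List::create(Rcpp::Named("dvA") = dvA,
                            Rcpp::Named("dOm") = dOm,
                            Rcpp::Named("dPh") = dPh);
}
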
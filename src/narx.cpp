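// Closed-loop NARX rollout and backpropagation-through-time gradient.
// The recurrence (three tanh hidden layers, each fed by the delayed model
// outputs and, in layer 1, the constant exogenous features; linear output)
// is the performance-critical inner loop of trend-network training, so it
// is compiled. Teacher-padded truncated rollouts use the same code path:
// EXT carries the lag values that fall outside the simulated window (the
// target history, or zeros at the record start).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// simulate rollouts; lags inside the window read the simulation, lags
// outside read EXT
static mat rollout(const mat& W, const mat& H1, const mat& L2,
                   const mat& H2, const mat& L3, const mat& H3,
                   const vec& L4, const vec& b1, const vec& b2,
                   const vec& b3, double b4, const mat& X,
                   const cube& EXT, const ivec& delays,
                   cube* A1, cube* A2, cube* A3, cube* YH) {
  const uword n = X.n_rows, S = EXT.n_slices, nd = delays.n_elem;
  mat IW = X * W.t();
  IW.each_row() += b1.t();
  mat tH1 = H1.t(), tH2 = H2.t(), tH3 = H3.t(), tL2 = L2.t(), tL3 = L3.t();
  mat Y(n, S, fill::zeros);
  for (uword j = 0; j < S; ++j) {
    mat yh = EXT.slice(j);
    for (uword k = 0; k < nd; ++k) {
      int src = static_cast<int>(j) - delays(k);
      if (src >= 0) yh.col(k) = Y.col(src);
    }
    mat a1 = tanh(yh * tH1 + IW);
    mat a2 = yh * tH2 + a1 * tL2; a2.each_row() += b2.t(); a2 = tanh(a2);
    mat a3 = yh * tH3 + a2 * tL3; a3.each_row() += b3.t(); a3 = tanh(a3);
    Y.col(j) = a3 * L4 + b4;
    if (A1) {
      A1->slice(j) = a1; A2->slice(j) = a2; A3->slice(j) = a3;
      YH->slice(j) = yh;
    }
  }
  return Y;
}

// [[Rcpp::export]]
arma::mat narx_sim_cpp(const arma::mat& W, const arma::mat& H1,
                       const arma::mat& L2, const arma::mat& H2,
                       const arma::mat& L3, const arma::mat& H3,
                       const arma::vec& L4, const arma::vec& b1,
                       const arma::vec& b2, const arma::vec& b3,
                       double b4, const arma::mat& X, int horizon,
                       const arma::ivec& delays) {
  cube EXT(X.n_rows, delays.n_elem, horizon, fill::zeros);
  return rollout(W, H1, L2, H2, L3, H3, L4, b1, b2, b3, b4, X, EXT,
                 delays, nullptr, nullptr, nullptr, nullptr);
}

// mean squared rollout error and its gradient (BPTT)
// [[Rcpp::export]]
Rcpp::List narx_obj_cpp(const arma::mat& W, const arma::mat& H1,
                        const arma::mat& L2, const arma::mat& H2,
                        const arma::mat& L3, const arma::mat& H3,
                        const arma::vec& L4, const arma::vec& b1,
                        const arma::vec& b2, const arma::vec& b3,
                        double b4, const arma::mat& X,
                        const arma::cube& EXT, const arma::mat& TGT,
                        const arma::ivec& delays, bool want_grad) {
  const uword n = X.n_rows, S = TGT.n_cols, nd = delays.n_elem;
  const uword k1 = W.n_rows, k2 = L2.n_rows, k3 = L3.n_rows;
  cube A1(n, k1, S), A2(n, k2, S), A3(n, k3, S), YH(n, nd, S);
  mat Y = rollout(W, H1, L2, H2, L3, H3, L4, b1, b2, b3, b4, X, EXT,
                  delays, &A1, &A2, &A3, &YH);
  mat R = Y - TGT;
  const double N = static_cast<double>(R.n_elem);
  double value = accu(R % R) / N;
  if (!want_grad) {
    return Rcpp::List::create(Rcpp::Named("value") = value,
                              Rcpp::Named("Y") = Y);
  }
  mat dY = 2.0 * R / N;
  mat gW(size(W), fill::zeros), gH1(size(H1), fill::zeros);
  mat gL2(size(L2), fill::zeros), gH2(size(H2), fill::zeros);
  mat gL3(size(L3), fill::zeros), gH3(size(H3), fill::zeros);
  vec gL4(size(L4), fill::zeros), gb1(k1, fill::zeros);
  vec gb2(k2, fill::zeros), gb3(k3, fill::zeros);
  double gb4 = 0.0;
  for (int j = static_cast<int>(S) - 1; j >= 0; --j) {
    vec g = dY.col(j);
    const mat& a1 = A1.slice(j);
    const mat& a2 = A2.slice(j);
    const mat& a3 = A3.slice(j);
    const mat& yh = YH.slice(j);
    gL4 += a3.t() * g;
    gb4 += accu(g);
    mat d3 = (g * L4.t()) % (1.0 - square(a3));
    mat d2 = (d3 * L3) % (1.0 - square(a2));
    mat d1 = (d2 * L2) % (1.0 - square(a1));
    gL3 += d3.t() * a2; gH3 += d3.t() * yh; gb3 += sum(d3, 0).t();
    gL2 += d2.t() * a1; gH2 += d2.t() * yh; gb2 += sum(d2, 0).t();
    gW  += d1.t() * X;  gH1 += d1.t() * yh; gb1 += sum(d1, 0).t();
    mat dyh = d1 * H1 + d2 * H2 + d3 * H3;
    for (uword k = 0; k < nd; ++k) {
      int src = j - delays(k);
      if (src >= 0) dY.col(src) += dyh.col(k);
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("value") = value, Rcpp::Named("Y") = Y,
      Rcpp::Named("gW") = gW, Rcpp::Named("gH1") = gH1,
      Rcpp::Named("gL2") = gL2, Rcpp::Named("gH2") = gH2,
      Rcpp::Named("gL3") = gL3, Rcpp::Named("gH3") = gH3,
      Rcpp::Named("gL4") = gL4, Rcpp::Named("gb1") = gb1,
      Rcpp::Named("gb2") = gb2, Rcpp::Named("gb3") = gb3,
      Rcpp::Named("gb4") = gb4);
}
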
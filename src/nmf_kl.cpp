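#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Multiplicative-update NMF minimizing the generalized Kullback-Leibler
// divergence D(X || WH) = sum x log(x/wh) - x + wh (Brunet-style updates).
// Denominators are floored at `eps`; updates leave exact zeros in W and H
// untouched, as is standard for multiplicative schemes.

static double kl_divergence(const arma::mat& X, const arma::mat& WH,
                            double eps) {
  double d = 0.0;
  for (arma::uword i = 0; i < X.n_elem; ++i) {
    double x = X(i);
    double wh = std::max(WH(i), eps);
    if (x > 0.0)
      d += x * std::log(x / wh) - x + wh;
    else
      d += wh;
  }
  return d;
}

// [[Rcpp::export(name = ".nmf_kl_cpp")]]
Rcpp::List nmf_kl_cpp(const arma::mat& X, arma::mat W, arma::mat H,
                      int max_iter, double tol, double eps) {
  std::vector<double> trace;
  trace.reserve(max_iter);
  arma::mat WH = W * H;
  double prev = kl_divergence(X, WH, eps);
  bool converged = false;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    // H update: H_aj <- H_aj * [ sum_i W_ia X_ij/(WH)_ij ] / sum_i W_ia
    arma::mat R = X / arma::clamp(WH, eps, arma::datum::inf);
    arma::rowvec wsum = arma::sum(W, 0);
    wsum.transform([eps](double v) { return std::max(v, eps); });
    H %= (W.t() * R);
    H.each_col() /= wsum.t();

    // W update with refreshed residual ratio
    WH = W * H;
    R = X / arma::clamp(WH, eps, arma::datum::inf);
    arma::colvec hsum = arma::sum(H, 1);
    hsum.transform([eps](double v) { return std::max(v, eps); });
    W %= (R * H.t());
    W.each_row() /= hsum.t();

    WH = W * H;
    double obj = kl_divergence(X, WH, eps);
    trace.push_back(obj);
    double rel = std::fabs(prev - obj) / (std::fabs(prev) + eps);
    prev = obj;
    if (rel < tol) { converged = true; ++it; break; }
  }
  return Rcpp::List::create(
      Rcpp::Named("W") = W, Rcpp::Named("H") = H,
      Rcpp::Named("objective_trace") = trace,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("iterations") = it);
}
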
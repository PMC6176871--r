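// Kullback-Leibler NMF by multiplicative updates (Lee & Seung / Brunet).
// V (m x n, non-negative) ~ W (m x k) H (k x n).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static double kl_div(const arma::mat& V, const arma::mat& WH) {
    // sum over entries of V*log(V/WH) - V + WH, with 0*log(0) = 0
    double s = 0.0;
    for (arma::uword j = 0; j < V.n_cols; ++j)
        for (arma::uword i = 0; i < V.n_rows; ++i) {
            double v = V(i, j), w = WH(i, j);
            if (v > 0) s += v * std::log(v / w) - v + w;
            else s += w;
        }
    return s;
}

// [[Rcpp::export(name = ".nmf_kl_cpp")]]
Rcpp::List nmf_kl_cpp(const arma::mat& V, arma::mat W, arma::mat H,
                      int max_iter, double tol) {
    const double eps = 1e-12;
    arma::mat WH = W * H + eps;
    double obj = kl_div(V, WH);
    int it = 0;
    for (it = 0; it < max_iter; ++it) {
        // H update
        arma::mat Q = V / WH;                       // m x n
        H %= (W.t() * Q);                           // k x n
        H.each_col() /= (arma::sum(W, 0).t() + eps);
        WH = W * H + eps;
        // W update
        Q = V / WH;
        W %= (Q * H.t());
        W.each_row() /= (arma::sum(H, 1).t() + eps);
        WH = W * H + eps;
        if ((it + 1) % 10 == 0) {
            double obj_new = kl_div(V, WH);
            if (std::abs(obj - obj_new) <= tol * (std::abs(obj) + eps)) {
                obj = obj_new;
                ++it;
                break;
            }
            obj = obj_new;
        }
    }
    return Rcpp::List::create(Rcpp::Named("W") = W, Rcpp::Named("H") = H,
                              Rcpp::Named("kl") = kl_div(V, W * H + eps),
                              Rcpp::Named("iters") = it);
}
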
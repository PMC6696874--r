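// Exact (non-approximate) t-distributed stochastic neighbor embedding,
// following van der Maaten & Hinton (2008): per-point bandwidths found by
// binary search on perplexity, symmetrized affinities, gradient descent with
// momentum, adaptive gains, and early exaggeration. O(n^2) memory/time, which
// is fine for the tens of thousands of cells this package targets per run.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat squared_dist(const mat& X) {
  vec sq = sum(square(X), 1);
  mat D = repmat(sq, 1, X.n_rows) + repmat(sq.t(), X.n_rows, 1) - 2.0 * X * X.t();
  D.elem(find(D < 0)).zeros();
  D.diag().zeros();
  return D;
}

// symmetrized joint probabilities P with entropy = log(perplexity) per row
static mat perplexity_probs(const mat& D, double perplexity, double tol,
                            int max_tries) {
  const uword n = D.n_rows;
  mat P(n, n, fill::zeros);
  const double logU = std::log(perplexity);
  for (uword i = 0; i < n; ++i) {
    double beta = 1.0, betamin = -datum::inf, betamax = datum::inf;
    rowvec Di = D.row(i);
    rowvec Pi(n);
    for (int t = 0; t < max_tries; ++t) {
      Pi = exp(-Di * beta);
      Pi(i) = 0.0;
      double sumP = accu(Pi);
      if (sumP <= 0) sumP = DBL_MIN;
      double H = std::log(sumP) + beta * dot(Di, Pi) / sumP;
      double diff = H - logU;
      if (std::fabs(diff) < tol) break;
      if (diff > 0) {
        betamin = beta;
        beta = std::isinf(betamax) ? beta * 2.0 : (beta + betamax) / 2.0;
      } else {
        betamax = beta;
        beta = std::isinf(betamin) ? beta / 2.0 : (beta + betamin) / 2.0;
      }
    }
    double sumP = accu(Pi);
    if (sumP <= 0) sumP = DBL_MIN;
    P.row(i) = Pi / sumP;
  }
  P = (P + P.t()) / (2.0 * n);
  P.elem(find(P < 1e-12)).fill(1e-12);
  P.diag().zeros();
  return P;
}

// [[Rcpp::export]]
arma::mat tsne_exact_cpp(const arma::mat& X, arma::mat Y, double perplexity,
                         int max_iter, double eta, double exaggeration,
                         int stop_lying_iter, int mom_switch_iter,
                         double momentum_init, double momentum_final) {
  const uword n = X.n_rows;
  mat P = perplexity_probs(squared_dist(X), perplexity, 1e-5, 50);
  P *= exaggeration;

  mat dY(n, 2, fill::zeros), uY(n, 2, fill::zeros), gains(n, 2, fill::ones);
  double momentum = momentum_init;

  for (int iter = 0; iter < max_iter; ++iter) {
    mat DY = squared_dist(Y);
    mat num = 1.0 / (1.0 + DY);
    num.diag().zeros();
    double sum_num = accu(num);
    if (sum_num <= 0) sum_num = DBL_MIN;
    mat Q = num / sum_num;
    Q.elem(find(Q < 1e-12)).fill(1e-12);

    mat L = (P - Q) % num;
    mat grad = 4.0 * (diagmat(sum(L, 1)) - L) * Y;

    mat inc = conv_to<mat>::from(sign(grad) != sign(uY));
    gains = (gains + 0.2) % inc + (gains * 0.8) % (1.0 - inc);
    gains.elem(find(gains < 0.01)).fill(0.01);

    uY = momentum * uY - eta * (gains % grad);
    Y += uY;
    Y.each_row() -= mean(Y, 0);

    if (iter == stop_lying_iter - 1) P /= exaggeration;
    if (iter == mom_switch_iter - 1) momentum = momentum_final;
  }
  return Y;
}

// Jaccard coefficients of k-NN sets for a list of candidate edges.
// nn: n x k matrix of 1-based neighbor indices, each row sorted ascending.
// [[Rcpp::export]]
Rcpp::NumericVector jaccard_pairs_cpp(const Rcpp::IntegerMatrix& nn,
                                      const Rcpp::IntegerVector& u,
                                      const Rcpp::IntegerVector& v) {
  const int k = nn.ncol();
  const int m = u.size();
  Rcpp::NumericVector out(m);
  for (int e = 0; e < m; ++e) {
    const int a = u[e] - 1, b = v[e] - 1;
    int i = 0, j = 0, inter = 0;
    while (i < k && j < k) {
      if (nn(a, i) == nn(b, j)) { ++inter; ++i; ++j; }
      else if (nn(a, i) < nn(b, j)) ++i;
      else ++j;
    }
    out[e] = static_cast<double>(inter) / (2.0 * k - inter);
  }
  return out;
}
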
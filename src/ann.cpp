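// Batch error-backpropagation training of the 6-3-1 sigmoid surrogate.
// All randomness (weight initialization) happens on the R side; this core is
// a deterministic function of its inputs.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigm(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

// Analytic gradient of E = 0.5 * sum_i (y_i - t_i)^2 w.r.t. all weights and
// biases, for a given batch. Exposed to R so tests can compare it against a
// numerical gradient of the same loss.
// [[Rcpp::export]]
Rcpp::List cpp_ann_gradient(const arma::mat& X, const arma::vec& t,
                            const arma::mat& w1, const arma::vec& b1,
                            const arma::vec& w2, double b2) {
  mat H = sigm(X * w1 + repmat(b1.t(), X.n_rows, 1));
  vec y = sigm(H * w2 + b2);
  vec d_out = (y - t) % y % (1.0 - y);
  mat g2 = H.t() * d_out;
  double gb2 = accu(d_out);
  mat dh = (d_out * w2.t()) % H % (1.0 - H);
  mat g1 = X.t() * dh;
  rowvec gb1 = sum(dh, 0);
  return Rcpp::List::create(
    Rcpp::Named("w1") = g1, Rcpp::Named("b1") = gb1.t(),
    Rcpp::Named("w2") = g2, Rcpp::Named("b2") = gb2);
}

// Gradient descent with momentum on the squared error of the learning set;
// tracks testing-set mean squared error every iteration and retains the
// weight snapshot with the minimal testing error. One iteration is one pass
// over the learning set: a single accumulated update in batch mode, or one
// update per record (in fixed record order) in online mode.
// [[Rcpp::export]]
Rcpp::List cpp_ann_train(const arma::mat& Xl, const arma::vec& tl,
                         const arma::mat& Xt, const arma::vec& tt,
                         arma::mat w1, arma::vec b1, arma::vec w2, double b2,
                         double lr, double momentum, int max_iter,
                         bool online) {
  mat v1(size(w1), fill::zeros);
  vec vb1(size(b1), fill::zeros);
  vec v2(size(w2), fill::zeros);
  double vb2 = 0.0;

  vec learn_trace(max_iter, fill::zeros), test_trace(max_iter, fill::zeros);
  double best_test = datum::inf;
  int best_iter = -1;
  mat bw1 = w1; vec bb1 = b1; vec bw2 = w2; double bb2 = b2;
  bool diverged = false;

  for (int it = 0; it < max_iter; ++it) {
    double el;
    if (online) {
      for (uword i = 0; i < Xl.n_rows; ++i) {
        rowvec x = Xl.row(i);
        vec h = sigm(x * w1 + b1.t()).t();
        double y = as_scalar(sigm(h.t() * w2 + b2));
        double d_out = (y - tl(i)) * y * (1.0 - y);
        vec g2 = h * d_out;
        double gb2 = d_out;
        vec dh = d_out * w2 % h % (1.0 - h);
        mat g1 = x.t() * dh.t();
        vec gb1 = dh;
        v1 = momentum * v1 - lr * g1;  w1 += v1;
        vb1 = momentum * vb1 - lr * gb1;  b1 += vb1;
        v2 = momentum * v2 - lr * g2;  w2 += v2;
        vb2 = momentum * vb2 - lr * gb2;  b2 += vb2;
      }
      mat H = sigm(Xl * w1 + repmat(b1.t(), Xl.n_rows, 1));
      vec y = sigm(H * w2 + b2);
      el = mean(square(y - tl));
    } else {
      mat H = sigm(Xl * w1 + repmat(b1.t(), Xl.n_rows, 1));
      vec y = sigm(H * w2 + b2);
      el = mean(square(y - tl));

      vec d_out = (y - tl) % y % (1.0 - y);
      mat g2 = H.t() * d_out;
      double gb2 = accu(d_out);
      mat dh = (d_out * w2.t()) % H % (1.0 - H);
      mat g1 = Xl.t() * dh;
      vec gb1 = sum(dh, 0).t();

      v1 = momentum * v1 - lr * g1;  w1 += v1;
      vb1 = momentum * vb1 - lr * gb1;  b1 += vb1;
      v2 = momentum * v2 - lr * g2;  w2 += v2;
      vb2 = momentum * vb2 - lr * gb2;  b2 += vb2;
    }

    mat Ht = sigm(Xt * w1 + repmat(b1.t(), Xt.n_rows, 1));
    vec yt = sigm(Ht * w2 + b2);
    double et = mean(square(yt - tt));

    learn_trace(it) = el;
    test_trace(it) = et;
    if (!std::isfinite(el) || !std::isfinite(et)) { diverged = true; break; }
    if (et < best_test) {
      best_test = et; best_iter = it;
      bw1 = w1; bb1 = b1; bw2 = w2; bb2 = b2;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("w1") = bw1, Rcpp::Named("b1") = bb1,
    Rcpp::Named("w2") = bw2, Rcpp::Named("b2") = bb2,
    Rcpp::Named("best_test_mse") = best_test,
    Rcpp::Named("best_iter") = best_iter + 1,
    Rcpp::Named("diverged") = diverged,
    Rcpp::Named("learn_trace") = learn_trace,
    Rcpp::Named("test_trace") = test_trace,
    Rcpp::Named("final") = Rcpp::List::create(
      Rcpp::Named("w1") = w1, Rcpp::Named("b1") = b1,
      Rcpp::Named("w2") = w2, Rcpp::Named("b2") = b2));
}
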
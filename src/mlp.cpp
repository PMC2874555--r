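#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// Batch forward pass.  W[l] is an (in x out) matrix, b[l] a length-out
// vector; every layer applies sigmoid(W^T a + b).  Input neurons are
// pass-through, so X enters the first weighted layer directly.
// [[Rcpp::export]]
NumericMatrix cpp_mlp_forward(List W, List b, NumericMatrix X) {
  int L = W.size();
  NumericMatrix A = X;
  for (int l = 0; l < L; ++l) {
    NumericMatrix w = W[l];
    NumericVector bb = b[l];
    int in = w.nrow(), out = w.ncol(), n = A.nrow();
    if (A.ncol() != in)
      stop("layer %d expects %d inputs, got %d", l + 1, in, A.ncol());
    NumericMatrix Z(n, out);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < out; ++j) {
        double s = bb[j];
        for (int k = 0; k < in; ++k) s += A(i, k) * w(k, j);
        Z(i, j) = sigmoid(s);
      }
    A = Z;
  }
  return A;
}

// Activations for one sample, one vector per layer (input included).
static std::vector<std::vector<double> > forward_one(
    const std::vector<NumericMatrix> &W, const std::vector<NumericVector> &b,
    const std::vector<double> &x) {
  std::vector<std::vector<double> > act;
  act.push_back(x);
  for (size_t l = 0; l < W.size(); ++l) {
    int in = W[l].nrow(), out = W[l].ncol();
    std::vector<double> a(out);
    for (int j = 0; j < out; ++j) {
      double s = b[l][j];
      for (int k = 0; k < in; ++k) s += act[l][k] * W[l](k, j);
      a[j] = sigmoid(s);
    }
    act.push_back(a);
  }
  return act;
}

// Error deltas for E = 1/2 * sum_j (a_j - t_j)^2 under sigmoid units.
static std::vector<std::vector<double> > backward_one(
    const std::vector<NumericMatrix> &W,
    const std::vector<std::vector<double> > &act,
    const std::vector<double> &t) {
  int L = W.size();
  std::vector<std::vector<double> > delta(L);
  const std::vector<double> &out = act[L];
  delta[L - 1].resize(out.size());
  for (size_t j = 0; j < out.size(); ++j)
    delta[L - 1][j] = (out[j] - t[j]) * out[j] * (1.0 - out[j]);
  for (int l = L - 2; l >= 0; --l) {
    int in = W[l + 1].nrow(), outn = W[l + 1].ncol();
    delta[l].resize(in);
    for (int k = 0; k < in; ++k) {
      double s = 0.0;
      for (int j = 0; j < outn; ++j) s += W[l + 1](k, j) * delta[l + 1][j];
      delta[l][k] = s * act[l + 1][k] * (1.0 - act[l + 1][k]);
    }
  }
  return delta;
}

// One epoch of per-sample (stochastic) back-propagation with momentum:
//   v <- momentum * v - eta * grad;  w <- w + v
// `order` gives the 1-based sample visiting order.  Inputs are cloned,
// updated copies are returned together with the momentum state and the
// epoch SSE (sum over samples of 1/2 * squared output error, measured
// when each sample is visited).
// [[Rcpp::export]]
List cpp_mlp_epoch(List W, List b, List vW, List vb,
                   NumericMatrix X, NumericMatrix Y,
                   double eta, double momentum, IntegerVector order) {
  int L = W.size();
  std::vector<NumericMatrix> w(L), vw(L);
  std::vector<NumericVector> bb(L), vbb(L);
  for (int l = 0; l < L; ++l) {
    w[l] = clone(as<NumericMatrix>(W[l]));
    bb[l] = clone(as<NumericVector>(b[l]));
    vw[l] = clone(as<NumericMatrix>(vW[l]));
    vbb[l] = clone(as<NumericVector>(vb[l]));
  }
  int d = X.ncol(), nout = Y.ncol();
  double sse = 0.0;
  for (int s = 0; s < order.size(); ++s) {
    int i = order[s] - 1;
    std::vector<double> x(d), t(nout);
    for (int k = 0; k < d; ++k) x[k] = X(i, k);
    for (int j = 0; j < nout; ++j) t[j] = Y(i, j);
    std::vector<std::vector<double> > act = forward_one(w, bb, x);
    for (int j = 0; j < nout; ++j) {
      double e = act[L][j] - t[j];
      sse += 0.5 * e * e;
    }
    std::vector<std::vector<double> > delta = backward_one(w, act, t);
    for (int l = 0; l < L; ++l) {
      int in = w[l].nrow(), out = w[l].ncol();
      for (int j = 0; j < out; ++j) {
        double dj = delta[l][j];
        for (int k = 0; k < in; ++k) {
          double v = momentum * vw[l](k, j) - eta * act[l][k] * dj;
          vw[l](k, j) = v;
          w[l](k, j) += v;
        }
        double v = momentum * vbb[l][j] - eta * dj;
        vbb[l][j] = v;
        bb[l][j] += v;
      }
    }
  }
  List Wo(L), bo(L), vWo(L), vbo(L);
  for (int l = 0; l < L; ++l) {
    Wo[l] = w[l]; bo[l] = bb[l]; vWo[l] = vw[l]; vbo[l] = vbb[l];
  }
  return List::create(_["weights"] = Wo, _["biases"] = bo,
                      _["vel_weights"] = vWo, _["vel_biases"] = vbo,
                      _["sse"] = sse);
}

// Analytic gradient of E = 1/2 * sum_j (R_j - t_j)^2 for a single sample.
// [[Rcpp::export]]
List cpp_mlp_gradient(List W, List b, NumericVector x, NumericVector t) {
  int L = W.size();
  std::vector<NumericMatrix> w(L);
  std::vector<NumericVector> bb(L);
  for (int l = 0; l < L; ++l) {
    w[l] = as<NumericMatrix>(W[l]);
    bb[l] = as<NumericVector>(b[l]);
  }
  std::vector<double> xv(x.begin(), x.end()), tv(t.begin(), t.end());
  std::vector<std::vector<double> > act = forward_one(w, bb, xv);
  std::vector<std::vector<double> > delta = backward_one(w, act, tv);
  List gW(L), gb(L);
  for (int l = 0; l < L; ++l) {
    int in = w[l].nrow(), out = w[l].ncol();
    NumericMatrix gw(in, out);
    NumericVector gbv(out);
    for (int j = 0; j < out; ++j) {
      for (int k = 0; k < in; ++k) gw(k, j) = act[l][k] * delta[l][j];
      gbv[j] = delta[l][j];
    }
    gW[l] = gw; gb[l] = gbv;
  }
  return List::create(_["weights"] = gW, _["biases"] = gb);
}
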
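#include <Rcpp.h>
using namespace Rcpp;

// Trial-by-trial filters for the associative-learning models. Each filter
// receives the binary stimulus matrix X (trials x elemental cues) and the
// outcome vector r, and returns the pre-outcome (prediction-time) latent
// state of every trial together with the model's mean response. The R-level
// step functions (rw_step etc.) are the single-trial reference
// implementations; these loops must agree with them exactly.

// [[Rcpp::export]]
List rw_filter_cpp(NumericMatrix X, NumericVector r, double alpha,
                   double w0, double lambda) {
  int n = X.nrow(), k = X.ncol();
  NumericVector w(k, w0);
  NumericVector m(n), delta(n);
  NumericMatrix V(n, k);
  for (int t = 0; t < n; ++t) {
    double pred = 0.0;
    for (int j = 0; j < k; ++j) {
      V(t, j) = w[j];
      pred += X(t, j) * w[j];
    }
    m[t] = pred;
    double d = lambda * r[t] - pred;
    delta[t] = d;
    for (int j = 0; j < k; ++j) w[j] += alpha * d * X(t, j);
  }
  return List::create(_["m"] = m, _["V"] = V, _["delta"] = delta,
                      _["w_final"] = w);
}

// Kalman filter over associative weights: diffusion Sigma += q*I, then a
// standard conjugate update with scalar measurement x'w + noise. Sigma is
// re-symmetrized after every update to keep it numerically PSD.
// [[Rcpp::export]]
List krw_filter_cpp(NumericMatrix X, NumericVector r, double w0_mean,
                    double w0_var, double q, double r_noise) {
  int n = X.nrow(), k = X.ncol();
  NumericVector w(k, w0_mean);
  NumericMatrix S(k, k);
  for (int j = 0; j < k; ++j) S(j, j) = w0_var;
  NumericVector m(n), delta(n);
  NumericMatrix V(n, k), gain(n, k);
  NumericVector Sig(n * k * k);
  NumericVector Sx(k);
  for (int t = 0; t < n; ++t) {
    // diffusion of the weight prior
    for (int j = 0; j < k; ++j) S(j, j) += q;
    double pred = 0.0;
    for (int j = 0; j < k; ++j) {
      V(t, j) = w[j];
      pred += X(t, j) * w[j];
    }
    m[t] = pred;
    for (int a = 0; a < k; ++a)
      for (int b = 0; b < k; ++b)
        Sig[t + n * (a + k * b)] = S(a, b);   // prediction-time covariance
    // gain = S x / (x' S x + r_noise)
    double xSx = 0.0;
    for (int a = 0; a < k; ++a) {
      double acc = 0.0;
      for (int b = 0; b < k; ++b) acc += S(a, b) * X(t, b);
      Sx[a] = acc;
      xSx += X(t, a) * acc;
    }
    double denom = xSx + r_noise;
    double d = r[t] - pred;
    delta[t] = d;
    for (int a = 0; a < k; ++a) {
      double g = Sx[a] / denom;
      gain(t, a) = g;
      w[a] += g * d;
    }
    // S <- S - gain x' S, then symmetrize
    for (int a = 0; a < k; ++a)
      for (int b = 0; b < k; ++b)
        S(a, b) -= gain(t, a) * Sx[b];
    for (int a = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b) {
        double s = 0.5 * (S(a, b) + S(b, a));
        S(a, b) = s;
        S(b, a) = s;
      }
  }
  Sig.attr("dim") = IntegerVector::create(n, k, k);
  return List::create(_["m"] = m, _["V"] = V, _["Sigma"] = Sig,
                      _["gain"] = gain, _["delta"] = delta,
                      _["w_final"] = w, _["S_final"] = S);
}

// Hybrid Rescorla-Wagner / Pearce-Hall: weights updated with a dynamic
// per-cue learning rate (associability) that tracks |prediction error|.
// Only presented cues update.
// [[Rcpp::export]]
List rwph_filter_cpp(NumericMatrix X, NumericVector r, double kappa,
                     double eta, double alpha0, double w0) {
  int n = X.nrow(), k = X.ncol();
  NumericVector w(k, w0), a(k, alpha0);
  NumericVector mV(n), mA(n), delta(n);
  NumericMatrix V(n, k), assoc(n, k);
  for (int t = 0; t < n; ++t) {
    double predV = 0.0, predA = 0.0;
    for (int j = 0; j < k; ++j) {
      V(t, j) = w[j];
      assoc(t, j) = a[j];
      predV += X(t, j) * w[j];
      predA += X(t, j) * a[j];
    }
    mV[t] = predV;
    mA[t] = predA;
    double d = r[t] - predV;
    delta[t] = d;
    for (int j = 0; j < k; ++j) {
      if (X(t, j) > 0) {
        w[j] += kappa * a[j] * d;
        a[j] = eta * std::fabs(d) + (1.0 - eta) * a[j];
      }
    }
  }
  return List::create(_["mV"] = mV, _["mA"] = mA, _["V"] = V,
                      _["assoc"] = assoc, _["delta"] = delta,
                      _["w_final"] = w, _["a_final"] = a);
}
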
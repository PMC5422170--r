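#include <Rcpp.h>
using namespace Rcpp;

// One-hidden-layer feedforward network trained by online (per-sample)
// backpropagation on squared error. Weights are updated in the fixed
// sample order supplied by the caller; the epoch MSE is the mean over
// samples and output nodes of the pre-update squared error. Training
// stops when the epoch MSE drops below `tolerance` or after `max_epochs`.
//
// activation: 0 = logistic sigmoid on hidden and output layers,
//             1 = tanh on the hidden layer, logistic on the output layer.
// [[Rcpp::export]]
List bpnn_train_cpp(NumericMatrix X, NumericMatrix T,
                    NumericMatrix W1, NumericVector b1,
                    NumericMatrix W2, NumericVector b2,
                    IntegerVector order, double lr,
                    double tolerance, int max_epochs, int activation) {
  int n = X.nrow(), ni = X.ncol();
  int nh = W1.nrow(), no = W2.nrow();
  std::vector<double> h(nh), o(no), delta_o(no), delta_h(nh);
  std::vector<double> mse_log;
  mse_log.reserve(256);
  bool converged = false;
  int epochs = 0;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    double sse = 0.0;
    for (int s = 0; s < n; ++s) {
      int i = order[s] - 1;
      // forward
      for (int j = 0; j < nh; ++j) {
        double z = b1[j];
        for (int k = 0; k < ni; ++k) z += W1(j, k) * X(i, k);
        h[j] = activation == 1 ? std::tanh(z) : 1.0 / (1.0 + std::exp(-z));
      }
      for (int m = 0; m < no; ++m) {
        double z = b2[m];
        for (int j = 0; j < nh; ++j) z += W2(m, j) * h[j];
        o[m] = 1.0 / (1.0 + std::exp(-z));
      }
      // error and output deltas
      for (int m = 0; m < no; ++m) {
        double e = T(i, m) - o[m];
        sse += e * e;
        delta_o[m] = e * o[m] * (1.0 - o[m]);
      }
      // hidden deltas
      for (int j = 0; j < nh; ++j) {
        double acc = 0.0;
        for (int m = 0; m < no; ++m) acc += delta_o[m] * W2(m, j);
        double dact = activation == 1 ? (1.0 - h[j] * h[j]) : h[j] * (1.0 - h[j]);
        delta_h[j] = acc * dact;
      }
      // updates
      for (int m = 0; m < no; ++m) {
        for (int j = 0; j < nh; ++j) W2(m, j) += lr * delta_o[m] * h[j];
        b2[m] += lr * delta_o[m];
      }
      for (int j = 0; j < nh; ++j) {
        for (int k = 0; k < ni; ++k) W1(j, k) += lr * delta_h[j] * X(i, k);
        b1[j] += lr * delta_h[j];
      }
    }
    double mse = sse / (double)(n * no);
    mse_log.push_back(mse);
    epochs = epoch + 1;
    if (mse < tolerance) { converged = true; break; }
  }

  return List::create(_["W1"] = W1, _["b1"] = b1,
                      _["W2"] = W2, _["b2"] = b2,
                      _["mse"] = NumericVector(mse_log.begin(), mse_log.end()),
                      _["epochs"] = epochs,
                      _["converged"] = converged);
}
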
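// Fully connected multilayer perceptron sharing the training machinery of the
// convolutional network: per-sample SGD on half squared error with early
// stopping. Used by the ANN comparison classifiers (first hidden layer scaled
// tanh, remaining layers logistic).
//
// sizes: neurons per layer including input and 2-neuron output.
// acts: activation code per non-input layer: 1 = a*tanh(b*u), 2 = logistic.
// Flat layout: per layer l >= 1, per neuron: sizes[l-1] weights + bias.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

inline double sigmoid(double u) { return 1.0 / (1.0 + std::exp(-u)); }

struct MlpCfg {
  std::vector<int> sizes, acts, off;
  double a, b;
  int L, nParams;
};

MlpCfg parseMlp(IntegerVector sizes, IntegerVector acts, double a, double b) {
  MlpCfg c;
  c.sizes = std::vector<int>(sizes.begin(), sizes.end());
  c.acts = std::vector<int>(acts.begin(), acts.end());
  c.a = a; c.b = b;
  c.L = (int)c.sizes.size() - 1;
  if ((int)c.acts.size() != c.L) stop("need one activation per non-input layer");
  int off = 0;
  for (int l = 1; l <= c.L; ++l) {
    c.off.push_back(off);
    off += c.sizes[l] * (c.sizes[l - 1] + 1);
  }
  c.nParams = off;
  return c;
}

void mlpForward(const MlpCfg& c, const double* w, const double* x,
                std::vector<std::vector<double>>& act) {
  act.assign(c.L + 1, {});
  act[0].assign(x, x + c.sizes[0]);
  for (int l = 1; l <= c.L; ++l) {
    int nIn = c.sizes[l - 1], nOut = c.sizes[l];
    act[l].assign(nOut, 0.0);
    for (int j = 0; j < nOut; ++j) {
      const double* wj = w + c.off[l - 1] + j * (nIn + 1);
      double u = wj[nIn];
      for (int i = 0; i < nIn; ++i) u += wj[i] * act[l - 1][i];
      act[l][j] = c.acts[l - 1] == 1 ? c.a * std::tanh(c.b * u) : sigmoid(u);
    }
  }
}

double mlpGrad(const MlpCfg& c, const double* w, const double* x,
               const double* target, std::vector<std::vector<double>>& act,
               double* g) {
  mlpForward(c, w, x, act);
  std::fill(g, g + c.nParams, 0.0);
  int nOut = c.sizes[c.L];
  std::vector<double> delta(nOut);
  double loss = 0.0;
  for (int j = 0; j < nOut; ++j) {
    double e = act[c.L][j] - target[j];
    loss += 0.5 * e * e;
    double z = act[c.L][j];
    double fp = c.acts[c.L - 1] == 1 ? c.b * (c.a - z * z / c.a)
                                     : z * (1.0 - z);
    delta[j] = e * fp;
  }
  for (int l = c.L; l >= 1; --l) {
    int nIn = c.sizes[l - 1], nO = c.sizes[l];
    for (int j = 0; j < nO; ++j) {
      double* gj = g + c.off[l - 1] + j * (nIn + 1);
      for (int i = 0; i < nIn; ++i) gj[i] = delta[j] * act[l - 1][i];
      gj[nIn] = delta[j];
    }
    if (l > 1) {
      std::vector<double> prev(nIn, 0.0);
      for (int i = 0; i < nIn; ++i) {
        double s = 0.0;
        for (int j = 0; j < nO; ++j)
          s += delta[j] * w[c.off[l - 1] + j * (nIn + 1) + i];
        double z = act[l - 1][i];
        double fp = c.acts[l - 2] == 1 ? c.b * (c.a - z * z / c.a)
                                       : z * (1.0 - z);
        prev[i] = s * fp;
      }
      delta.swap(prev);
    }
  }
  return loss;
}

void targetFor(int y, double* t) {
  t[0] = y == 1 ? 0.0 : 1.0;
  t[1] = y == 1 ? 1.0 : 0.0;
}

}  // namespace

// [[Rcpp::export(name = ".mlpCountParamsCpp")]]
int mlpCountParamsCpp(IntegerVector sizes, IntegerVector acts) {
  return parseMlp(sizes, acts, 1.7159, 2.0 / 3.0).nParams;
}

// [[Rcpp::export(name = ".mlpGradCpp")]]
List mlpGradCpp(IntegerVector sizes, IntegerVector acts, double a, double b,
                NumericVector params, NumericVector x, NumericVector target) {
  MlpCfg c = parseMlp(sizes, acts, a, b);
  if ((int)params.size() != c.nParams) stop("parameter vector has wrong length");
  std::vector<std::vector<double>> act;
  NumericVector g(c.nParams);
  double loss = mlpGrad(c, params.begin(), x.begin(), target.begin(), act,
                        g.begin());
  NumericVector z(act[c.L].begin(), act[c.L].end());
  return List::create(_["grad"] = g, _["loss"] = loss, _["z"] = z);
}

// [[Rcpp::export(name = ".mlpPredictCpp")]]
NumericMatrix mlpPredictCpp(IntegerVector sizes, IntegerVector acts, double a,
                            double b, NumericVector params, NumericMatrix X) {
  MlpCfg c = parseMlp(sizes, acts, a, b);
  std::vector<std::vector<double>> act;
  NumericMatrix out(X.nrow(), 2);
  std::vector<double> x(c.sizes[0]);
  for (int i = 0; i < X.nrow(); ++i) {
    for (int j = 0; j < c.sizes[0]; ++j) x[j] = X(i, j);
    mlpForward(c, params.begin(), x.data(), act);
    out(i, 0) = act[c.L][0];
    out(i, 1) = act[c.L][1];
  }
  return out;
}

// [[Rcpp::export(name = ".mlpTrainCpp")]]
List mlpTrainCpp(IntegerVector sizes, IntegerVector acts, double a, double b,
                 NumericVector params0, NumericMatrix Xtr, IntegerVector ytr,
                 NumericMatrix Xval, IntegerVector yval, double lr,
                 int maxEpochs, int patience) {
  MlpCfg c = parseMlp(sizes, acts, a, b);
  if ((int)params0.size() != c.nParams) stop("parameter vector has wrong length");
  int n = Xtr.nrow(), D = c.sizes[0];
  if (Xtr.ncol() != D) stop("Xtr must have sizes[1] columns");
  std::vector<double> w(params0.begin(), params0.end());
  std::vector<double> best(w), g(c.nParams), x(D);
  std::vector<std::vector<double>> act;
  std::vector<double> histTrain, histVal;
  double bestVal = R_PosInf;
  int bestEpoch = 0, wait = 0, epoch = 0;
  bool useVal = Xval.nrow() > 0;
  for (epoch = 1; epoch <= maxEpochs; ++epoch) {
    IntegerVector ord = sample(n, n, false);
    double trainLoss = 0.0;
    for (int k = 0; k < n; ++k) {
      int i = ord[k] - 1;
      for (int j = 0; j < D; ++j) x[j] = Xtr(i, j);
      double tgt[2];
      targetFor(ytr[i], tgt);
      trainLoss += mlpGrad(c, w.data(), x.data(), tgt, act, g.data());
      if (lr != 0.0)
        for (int j = 0; j < c.nParams; ++j) w[j] -= lr * g[j];
    }
    trainLoss /= n;
    double v = trainLoss;
    if (useVal) {
      v = 0.0;
      for (int i = 0; i < Xval.nrow(); ++i) {
        for (int j = 0; j < D; ++j) x[j] = Xval(i, j);
        mlpForward(c, w.data(), x.data(), act);
        double tgt[2];
        targetFor(yval[i], tgt);
        for (int kk = 0; kk < 2; ++kk) {
          double e = act[c.L][kk] - tgt[kk];
          v += 0.5 * e * e;
        }
      }
      v /= Xval.nrow();
    }
    histTrain.push_back(trainLoss);
    histVal.push_back(v);
    if (v < bestVal) {
      bestVal = v;
      best = w;
      bestEpoch = epoch;
      wait = 0;
    } else if (++wait >= patience) break;
  }
  int stopped = std::min(epoch, maxEpochs);
  return List::create(
      _["params"] = NumericVector(best.begin(), best.end()),
      _["trainMSE"] = NumericVector(histTrain.begin(), histTrain.end()),
      _["valMSE"] = NumericVector(histVal.begin(), histVal.end()),
      _["stoppedEpoch"] = stopped, _["bestEpoch"] = bestEpoch);
}
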
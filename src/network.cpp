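// Five-layer network: input (M x T) -> spatial convolution (Nc maps, kernels
// spanning all M channels at one time index, stride 1, length T) -> temporal
// convolution + subsampling (map m: kernel length K_m = T/P_m, stride K_m,
// P_m outputs) -> dense hidden (Q, logistic) -> dense output (2, logistic).
// Scaled tanh f(u) = a * tanh(b * u) on the two convolutional layers.
//
// Parameters live in one flat vector:
//   [spatial: for m: M weights + bias] [temporal: for m: K_m weights + bias]
//   [hidden: for q: SP weights + bias] [output: for i in {Z0,Z1}: Q weights + bias]
// Labels: 1 = remembered (target (0,1)), 0 = forgotten (target (1,0)).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct NetCfg {
  int M, T, Nc, Q, SP, nParams;
  double a, b;
  std::vector<int> P, K, offTempMap;
  int offSpatial, offTemporal, offHidden, offOut;
};

NetCfg parseCfg(const List& cfg) {
  NetCfg c;
  c.M = as<int>(cfg["nCh"]);
  c.T = as<int>(cfg["tLen"]);
  c.Nc = as<int>(cfg["nC"]);
  c.Q = as<int>(cfg["q"]);
  c.a = as<double>(cfg["a"]);
  c.b = as<double>(cfg["b"]);
  IntegerVector p = cfg["p"];
  if ((int)p.size() != c.Nc) stop("length(p) must equal nC");
  c.SP = 0;
  for (int m = 0; m < c.Nc; ++m) {
    if (c.T % p[m] != 0) stop("P_m must divide T");
    c.P.push_back(p[m]);
    c.K.push_back(c.T / p[m]);
    c.SP += p[m];
  }
  c.offSpatial = 0;
  c.offTemporal = c.Nc * (c.M + 1);
  int off = c.offTemporal;
  for (int m = 0; m < c.Nc; ++m) { c.offTempMap.push_back(off); off += c.K[m] + 1; }
  c.offHidden = off;
  c.offOut = c.offHidden + c.Q * (c.SP + 1);
  c.nParams = c.offOut + 2 * (c.Q + 1);
  return c;
}

inline double sigmoid(double u) { return 1.0 / (1.0 + std::exp(-u)); }

struct Trace {
  std::vector<double> xc;   // Nc * T (map-major)
  std::vector<double> xcs;  // SP concatenated over maps
  std::vector<double> xh;   // Q
  double z[2];
};

// I is column-major M x T
void forwardOne(const NetCfg& c, const double* w, const double* I, Trace& tr) {
  tr.xc.assign((size_t)c.Nc * c.T, 0.0);
  tr.xcs.assign(c.SP, 0.0);
  tr.xh.assign(c.Q, 0.0);
  for (int m = 0; m < c.Nc; ++m) {
    const double* km = w + c.offSpatial + m * (c.M + 1);
    double bm = km[c.M];
    for (int t = 0; t < c.T; ++t) {
      double u = bm;
      const double* col = I + (size_t)t * c.M;
      for (int d = 0; d < c.M; ++d) u += km[d] * col[d];
      tr.xc[(size_t)m * c.T + t] = c.a * std::tanh(c.b * u);
    }
  }
  int pos = 0;
  for (int m = 0; m < c.Nc; ++m) {
    const double* kk = w + c.offTempMap[m];
    double bb = kk[c.K[m]];
    const double* xm = &tr.xc[(size_t)m * c.T];
    for (int p = 0; p < c.P[m]; ++p) {
      double u = bb;
      for (int j = 0; j < c.K[m]; ++j) u += kk[j] * xm[p * c.K[m] + j];
      tr.xcs[pos++] = c.a * std::tanh(c.b * u);
    }
  }
  for (int q = 0; q < c.Q; ++q) {
    const double* wq = w + c.offHidden + q * (c.SP + 1);
    double u = wq[c.SP];
    for (int j = 0; j < c.SP; ++j) u += wq[j] * tr.xcs[j];
    tr.xh[q] = sigmoid(u);
  }
  for (int i = 0; i < 2; ++i) {
    const double* wi = w + c.offOut + i * (c.Q + 1);
    double u = wi[c.Q];
    for (int q = 0; q < c.Q; ++q) u += wi[q] * tr.xh[q];
    tr.z[i] = sigmoid(u);
  }
}

// gradient of E = 0.5 * sum_i (z_i - t_i)^2; returns loss
double gradOne(const NetCfg& c, const double* w, const double* I,
               const double* target, Trace& tr, double* g) {
  forwardOne(c, w, I, tr);
  std::fill(g, g + c.nParams, 0.0);
  double dOut[2], loss = 0.0;
  for (int i = 0; i < 2; ++i) {
    double e = tr.z[i] - target[i];
    loss += 0.5 * e * e;
    dOut[i] = e * tr.z[i] * (1.0 - tr.z[i]);
  }
  for (int i = 0; i < 2; ++i) {
    double* gi = g + c.offOut + i * (c.Q + 1);
    for (int q = 0; q < c.Q; ++q) gi[q] = dOut[i] * tr.xh[q];
    gi[c.Q] = dOut[i];
  }
  std::vector<double> dH(c.Q);
  for (int q = 0; q < c.Q; ++q) {
    double s = 0.0;
    for (int i = 0; i < 2; ++i) s += dOut[i] * w[c.offOut + i * (c.Q + 1) + q];
    dH[q] = s * tr.xh[q] * (1.0 - tr.xh[q]);
    double* gq = g + c.offHidden + q * (c.SP + 1);
    for (int j = 0; j < c.SP; ++j) gq[j] = dH[q] * tr.xcs[j];
    gq[c.SP] = dH[q];
  }
  std::vector<double> dCS(c.SP);
  for (int j = 0; j < c.SP; ++j) {
    double s = 0.0;
    for (int q = 0; q < c.Q; ++q) s += dH[q] * w[c.offHidden + q * (c.SP + 1) + j];
    double x = tr.xcs[j];
    dCS[j] = s * c.b * (c.a - x * x / c.a);   // f'(u) for f = a tanh(b u)
  }
  int pos = 0;
  std::vector<double> dC((size_t)c.Nc * c.T, 0.0);
  for (int m = 0; m < c.Nc; ++m) {
    const double* kk = w + c.offTempMap[m];
    double* gk = g + c.offTempMap[m];
    const double* xm = &tr.xc[(size_t)m * c.T];
    for (int p = 0; p < c.P[m]; ++p) {
      double d = dCS[pos + p];
      for (int j = 0; j < c.K[m]; ++j) {
        gk[j] += d * xm[p * c.K[m] + j];
        dC[(size_t)m * c.T + p * c.K[m] + j] += d * kk[j];
      }
      gk[c.K[m]] += d;
    }
    pos += c.P[m];
  }
  for (int m = 0; m < c.Nc; ++m) {
    double* gm = g + c.offSpatial + m * (c.M + 1);
    for (int t = 0; t < c.T; ++t) {
      double x = tr.xc[(size_t)m * c.T + t];
      double d = dC[(size_t)m * c.T + t] * c.b * (c.a - x * x / c.a);
      const double* col = I + (size_t)t * c.M;
      for (int dch = 0; dch < c.M; ++dch) gm[dch] += d * col[dch];
      gm[c.M] += d;
    }
  }
  return loss;
}

void targetFor(int y, double* t) {  // y: 1 remembered -> (0,1); 0 forgotten -> (1,0)
  t[0] = y == 1 ? 0.0 : 1.0;
  t[1] = y == 1 ? 1.0 : 0.0;
}

double valLoss(const NetCfg& c, const double* w, const List& X,
               const IntegerVector& y, Trace& tr) {
  double s = 0.0;
  for (int i = 0; i < X.size(); ++i) {
    NumericMatrix Ii = X[i];
    double tgt[2];
    targetFor(y[i], tgt);
    forwardOne(c, w, REAL(Ii), tr);
    for (int k = 0; k < 2; ++k) {
      double e = tr.z[k] - tgt[k];
      s += 0.5 * e * e;
    }
  }
  return s / X.size();
}

}  // namespace

// [[Rcpp::export(name = ".nnForwardCpp")]]
List nnForwardCpp(List cfg, NumericVector params, NumericMatrix I) {
  NetCfg c = parseCfg(cfg);
  if ((int)params.size() != c.nParams) stop("parameter vector has wrong length");
  if (I.nrow() != c.M || I.ncol() != c.T) stop("input must be nCh x tLen");
  Trace tr;
  forwardOne(c, params.begin(), REAL(I), tr);
  NumericMatrix xc(c.T, c.Nc);
  for (int m = 0; m < c.Nc; ++m)
    for (int t = 0; t < c.T; ++t) xc(t, m) = tr.xc[(size_t)m * c.T + t];
  List xcs(c.Nc);
  int pos = 0;
  for (int m = 0; m < c.Nc; ++m) {
    NumericVector v(c.P[m]);
    for (int p = 0; p < c.P[m]; ++p) v[p] = tr.xcs[pos++];
    xcs[m] = v;
  }
  return List::create(_["z"] = NumericVector::create(tr.z[0], tr.z[1]),
                      _["xc"] = xc, _["xcs"] = xcs,
                      _["xh"] = NumericVector(tr.xh.begin(), tr.xh.end()));
}

// [[Rcpp::export(name = ".nnGradCpp")]]
List nnGradCpp(List cfg, NumericVector params, NumericMatrix I,
               NumericVector target) {
  NetCfg c = parseCfg(cfg);
  if ((int)params.size() != c.nParams) stop("parameter vector has wrong length");
  Trace tr;
  NumericVector g(c.nParams);
  double loss = gradOne(c, params.begin(), REAL(I), target.begin(), tr,
                        g.begin());
  return List::create(_["grad"] = g, _["loss"] = loss,
                      _["z"] = NumericVector::create(tr.z[0], tr.z[1]));
}

// [[Rcpp::export(name = ".nnPredictCpp")]]
NumericMatrix nnPredictCpp(List cfg, NumericVector params, List X) {
  NetCfg c = parseCfg(cfg);
  Trace tr;
  NumericMatrix out(X.size(), 2);
  for (int i = 0; i < X.size(); ++i) {
    NumericMatrix Ii = X[i];
    forwardOne(c, params.begin(), REAL(Ii), tr);
    out(i, 0) = tr.z[0];
    out(i, 1) = tr.z[1];
  }
  return out;
}

// Per-sample SGD with epoch-wise reshuffling (R's RNG) and early stopping on
// validation MSE. Returns the best-on-validation parameters.
// [[Rcpp::export(name = ".nnTrainCpp")]]
List nnTrainCpp(List cfg, NumericVector params0, List Xtr, IntegerVector ytr,
                List Xval, IntegerVector yval, double lr, int maxEpochs,
                int patience) {
  NetCfg c = parseCfg(cfg);
  if ((int)params0.size() != c.nParams) stop("parameter vector has wrong length");
  int n = Xtr.size();
  if (n < 1) stop("no training samples");
  std::vector<double> w(params0.begin(), params0.end());
  std::vector<double> best(w), g(c.nParams);
  Trace tr;
  std::vector<double> histTrain, histVal;
  double bestVal = R_PosInf;
  int bestEpoch = 0, wait = 0, epoch = 0;
  bool useVal = Xval.size() > 0;
  for (epoch = 1; epoch <= maxEpochs; ++epoch) {
    IntegerVector ord = sample(n, n, false);  // 1-based
    double trainLoss = 0.0;
    for (int k = 0; k < n; ++k) {
      int i = ord[k] - 1;
      NumericMatrix Ii = Xtr[i];
      double tgt[2];
      targetFor(ytr[i], tgt);
      trainLoss += gradOne(c, w.data(), REAL(Ii), tgt, tr, g.data());
      if (lr != 0.0)
        for (int j = 0; j < c.nParams; ++j) w[j] -= lr * g[j];
    }
    trainLoss /= n;
    double v = useVal ? valLoss(c, w.data(), Xval, yval, tr) : trainLoss;
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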
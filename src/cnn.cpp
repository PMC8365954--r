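// Convolutional sequence feature extractor.
//
// Architecture: one-hot DNA (A,C,G,T; N = all-zero) -> conv layer 1
// (k1 kernels, width w1) -> non-overlapping max pooling (width `pool`)
// -> ReLU -> conv layer 2 (k2 kernels, width w2) -> ReLU -> global max
// pooling (one feature per last-layer kernel). Pretraining couples the
// extractor to a dense head (hidden ReLU layer -> sigmoid) under a
// weighted binary cross-entropy on pair labels; the four orientation
// passes (left-F, left-RC, right-F, right-RC) share extractor weights.
//
// Because the input is one-hot, the first convolution is computed as a
// gather over kernel weight columns instead of an im2col GEMM; max
// pooling and ReLU commute, so pooling is applied to pre-activations and
// ReLU afterwards. Backpropagation routes gradients through the stored
// pooling/global argmax positions only. All computation is
// single-threaded and free of internal RNG: parameter initialization and
// epoch shuffling orders are supplied by the caller, so training is
// byte-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Config {
  int L, k1, w1, pool, k2, w2, h;
};

static Config get_config(const List& c) {
  Config cfg;
  cfg.L = as<int>(c["input_length"]);
  cfg.k1 = as<int>(c["n_kernels1"]);
  cfg.w1 = as<int>(c["width1"]);
  cfg.pool = as<int>(c["pool"]);
  cfg.k2 = as<int>(c["n_kernels2"]);
  cfg.w2 = as<int>(c["width2"]);
  cfg.h = as<int>(c["hidden"]);
  int P1 = cfg.L - cfg.w1 + 1;
  int Q = P1 / cfg.pool;
  int P2 = Q - cfg.w2 + 1;
  if (cfg.L < 1 || cfg.k1 < 1 || cfg.w1 < 1 || cfg.pool < 1 ||
      cfg.k2 < 1 || cfg.w2 < 1 || cfg.h < 1 || P1 < 1 || Q < 1 || P2 < 1) {
    stop("extractor config yields a non-positive spatial size");
  }
  return cfg;
}

// Canonical parameter order.
enum { P_W1 = 0, P_B1, P_W2, P_B2, P_WD1, P_BD1, P_WD2, P_BD2, N_PAR };
static const char* PAR_NAMES[N_PAR] = {"W1", "b1", "W2", "b2",
                                       "Wd1", "bd1", "wd2", "bd2"};

static std::vector<arma::mat> get_params(const List& p) {
  std::vector<arma::mat> out(N_PAR);
  for (int i = 0; i < N_PAR; ++i) {
    out[i] = as<arma::mat>(p[PAR_NAMES[i]]);
  }
  return out;
}

static List put_params(const std::vector<arma::mat>& p) {
  List out;
  for (int i = 0; i < N_PAR; ++i) out[PAR_NAMES[i]] = p[i];
  return out;
}

struct SeqCache {
  arma::mat M1;     // k1 x Q, ReLU'd pooled layer-1 activations
  arma::umat pArg;  // k1 x Q, argmax position in Z1 per pool window
  arma::uvec gArg;  // k2, global argmax position in Z2
  arma::vec feat;   // k2, ReLU'd global max
};

// Reverse complement of integer codes (0=A,1=C,2=G,3=T,4=N).
static void rc_codes(const int* in, int* out, int L) {
  for (int i = 0; i < L; ++i) {
    int c = in[L - 1 - i];
    out[i] = c < 4 ? 3 - c : 4;
  }
}

static void forward_seq(const int* codes, const Config& cfg,
                        const std::vector<arma::mat>& P, SeqCache& C,
                        arma::mat& Z1ws) {
  const int P1 = cfg.L - cfg.w1 + 1;
  const arma::mat& W1 = P[P_W1];  // k1 x (4*w1)
  const double* b1 = P[P_B1].memptr();
  Z1ws.set_size(cfg.k1, P1);
  for (int p = 0; p < P1; ++p) {
    double* zc = Z1ws.colptr(p);
    std::memcpy(zc, b1, cfg.k1 * sizeof(double));
    for (int j = 0; j < cfg.w1; ++j) {
      int idx = codes[p + j];
      if (idx < 4) {
        const double* wc = W1.colptr(4 * j + idx);
        for (int r = 0; r < cfg.k1; ++r) zc[r] += wc[r];
      }
    }
  }
  const int Q = P1 / cfg.pool;
  C.M1.set_size(cfg.k1, Q);
  C.pArg.set_size(cfg.k1, Q);
  for (int q = 0; q < Q; ++q) {
    int p0 = q * cfg.pool;
    for (int r = 0; r < cfg.k1; ++r) {
      double best = Z1ws(r, p0);
      int bi = p0;
      for (int p = p0 + 1; p < p0 + cfg.pool; ++p) {
        if (Z1ws(r, p) > best) { best = Z1ws(r, p); bi = p; }
      }
      C.pArg(r, q) = bi;
      C.M1(r, q) = best > 0 ? best : 0.0;
    }
  }
  const int P2 = Q - cfg.w2 + 1;
  // columns p..p+w2-1 of M1 are contiguous, so the layer-2 input column
  // is a direct view into M1 memory
  arma::mat Z2(cfg.k2, P2);
  const arma::mat& W2 = P[P_W2];  // k2 x (k1*w2)
  for (int p = 0; p < P2; ++p) {
    arma::vec c2(const_cast<double*>(C.M1.colptr(p)), cfg.k1 * cfg.w2,
                 false, true);
    Z2.col(p) = W2 * c2;
  }
  Z2.each_col() += P[P_B2].col(0);
  C.gArg.set_size(cfg.k2);
  C.feat.set_size(cfg.k2);
  for (int r = 0; r < cfg.k2; ++r) {
    double best = Z2(r, 0);
    int bi = 0;
    for (int p = 1; p < P2; ++p) {
      if (Z2(r, p) > best) { best = Z2(r, p); bi = p; }
    }
    C.gArg(r) = bi;
    C.feat(r) = best > 0 ? best : 0.0;
  }
}

static void backward_seq(const int* codes, const Config& cfg,
                         const std::vector<arma::mat>& P,
                         const arma::mat& W2T,  // (k1*w2) x k2
                         const SeqCache& C, const arma::vec& dfeat,
                         std::vector<arma::mat>& G,
                         arma::mat& dM1, arma::mat& dZ1,
                         std::vector<int>& touchedP) {
  const int Q = C.M1.n_cols;
  const int cw = cfg.k1 * cfg.w2;
  dM1.zeros(cfg.k1, Q);
  bool any = false;
  for (int r = 0; r < cfg.k2; ++r) {
    double g = dfeat(r);
    if (g == 0.0 || C.feat(r) <= 0.0) continue;
    any = true;
    int p = C.gArg(r);
    const double* c2 = C.M1.colptr(p);
    for (int c = 0; c < cw; ++c) G[P_W2](r, c) += g * c2[c];
    G[P_B2](r, 0) += g;
    double* dm = dM1.colptr(p);
    const double* wt = W2T.colptr(r);
    for (int c = 0; c < cw; ++c) dm[c] += g * wt[c];
  }
  if (!any) return;
  const int P1 = cfg.L - cfg.w1 + 1;
  dZ1.zeros(cfg.k1, P1);
  touchedP.clear();
  for (int q = 0; q < Q; ++q) {
    const double* m1 = C.M1.colptr(q);
    const double* dm = dM1.colptr(q);
    for (int r = 0; r < cfg.k1; ++r) {
      if (dm[r] != 0.0 && m1[r] > 0.0) {
        int p = C.pArg(r, q);
        dZ1(r, p) += dm[r];
        touchedP.push_back(p);
      }
    }
  }
  std::sort(touchedP.begin(), touchedP.end());
  touchedP.erase(std::unique(touchedP.begin(), touchedP.end()),
                 touchedP.end());
  for (int p : touchedP) {
    const double* dz = dZ1.colptr(p);
    for (int r = 0; r < cfg.k1; ++r) G[P_B1](r, 0) += dz[r];
    for (int j = 0; j < cfg.w1; ++j) {
      int idx = codes[p + j];
      if (idx < 4) {
        double* gw = G[P_W1].colptr(4 * j + idx);
        for (int r = 0; r < cfg.k1; ++r) gw[r] += dz[r];
      }
    }
  }
}

// Average precision with tied scores grouped into one threshold; must
// stay consistent with the R-level auprc() convention.
static double average_precision(const arma::vec& s, const arma::vec& y) {
  arma::uvec ord = arma::sort_index(s, "descend");
  double npos = arma::accu(y);
  double tp = 0, fp = 0, ap = 0, prev_rec = 0;
  int n = s.n_elem;
  for (int i = 0; i < n; ++i) {
    int k = ord(i);
    if (y(k) > 0.5) tp += 1; else fp += 1;
    bool boundary = (i == n - 1) || (s(ord(i + 1)) != s(k));
    if (boundary) {
      double rec = tp / npos;
      double prec = tp / (tp + fp);
      ap += (rec - prev_rec) * prec;
      prev_rec = rec;
    }
  }
  return ap;
}

struct HeadOut {
  double prob;
  arma::vec z, hpre, hh;
};

static void head_forward(const Config& cfg, const std::vector<arma::mat>& P,
                         const SeqCache* C4, HeadOut& H) {
  H.z.set_size(4 * cfg.k2);
  for (int b = 0; b < 4; ++b) {
    H.z.subvec(b * cfg.k2, (b + 1) * cfg.k2 - 1) = C4[b].feat;
  }
  H.hpre = P[P_WD1] * H.z + P[P_BD1].col(0);
  H.hh = arma::max(H.hpre, arma::zeros(cfg.h));
  double logit = arma::dot(P[P_WD2].col(0), H.hh) + P[P_BD2](0, 0);
  H.prob = 1.0 / (1.0 + std::exp(-logit));
}

// Forward pass: per-pair probabilities of the extractor + dense head.
static arma::vec predict_pairs_head(const IntegerMatrix& seqL,
                                    const IntegerMatrix& seqR,
                                    const Config& cfg,
                                    const std::vector<arma::mat>& P) {
  int n = seqL.ncol();
  arma::vec out(n);
  SeqCache C4[4];
  arma::mat Z1ws;
  std::vector<int> buf(cfg.L);
  HeadOut H;
  for (int i = 0; i < n; ++i) {
    const int* lF = &seqL(0, i);
    const int* rF = &seqR(0, i);
    forward_seq(lF, cfg, P, C4[0], Z1ws);
    rc_codes(lF, buf.data(), cfg.L);
    forward_seq(buf.data(), cfg, P, C4[1], Z1ws);
    forward_seq(rF, cfg, P, C4[2], Z1ws);
    rc_codes(rF, buf.data(), cfg.L);
    forward_seq(buf.data(), cfg, P, C4[3], Z1ws);
    head_forward(cfg, P, C4, H);
    out(i) = H.prob;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_train_stage1(IntegerMatrix seqL, IntegerMatrix seqR,
                      NumericVector y, NumericVector w,
                      IntegerMatrix vseqL, IntegerMatrix vseqR,
                      NumericVector vy, List params0, List config,
                      List hyper, IntegerMatrix perms) {
  Config cfg = get_config(config);
  std::vector<arma::mat> P = get_params(params0);
  const int n = seqL.ncol();
  const double lr = as<double>(hyper["learning_rate"]);
  const int batch = as<int>(hyper["batch_size"]);
  const int max_epochs = as<int>(hyper["max_epochs"]);
  const int patience = as<int>(hyper["patience"]);

  std::vector<arma::mat> G(N_PAR), M(N_PAR), V(N_PAR);
  for (int i = 0; i < N_PAR; ++i) {
    G[i] = arma::zeros(arma::size(P[i]));
    M[i] = arma::zeros(arma::size(P[i]));
    V[i] = arma::zeros(arma::size(P[i]));
  }
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  long t = 0;

  SeqCache C4[4];
  arma::mat Z1ws, dM1, dZ1;
  std::vector<int> rcbufL(cfg.L), rcbufR(cfg.L), touchedP;
  HeadOut H;
  arma::vec dfeat(cfg.k2);

  std::vector<arma::mat> bestP = P;
  double best_val = -1.0;
  int best_epoch = 0, since_best = 0, epochs_run = 0;
  std::vector<double> log_loss, log_val;

  arma::vec vyv(vy.begin(), vy.size());

  for (int e = 0; e < max_epochs; ++e) {
    double loss_sum = 0, wsum_total = 0;
    arma::mat W2T = P[P_W2].t();
    for (int b0 = 0; b0 < n; b0 += batch) {
      int b1 = std::min(b0 + batch, n);
      double wsum = 0;
      for (int k = b0; k < b1; ++k) wsum += w[perms(e, k) - 1];
      for (int i = 0; i < N_PAR; ++i) G[i].zeros();
      for (int k = b0; k < b1; ++k) {
        int i = perms(e, k) - 1;
        const int* lF = &seqL(0, i);
        const int* rF = &seqR(0, i);
        rc_codes(lF, rcbufL.data(), cfg.L);
        rc_codes(rF, rcbufR.data(), cfg.L);
        forward_seq(lF, cfg, P, C4[0], Z1ws);
        forward_seq(rcbufL.data(), cfg, P, C4[1], Z1ws);
        forward_seq(rF, cfg, P, C4[2], Z1ws);
        forward_seq(rcbufR.data(), cfg, P, C4[3], Z1ws);
        head_forward(cfg, P, C4, H);
        double p = std::min(std::max(H.prob, 1e-12), 1.0 - 1e-12);
        double yi = y[i], wi = w[i];
        loss_sum += -wi * (yi * std::log(p) + (1 - yi) * std::log(1 - p));
        wsum_total += wi;
        double dlogit = wi * (H.prob - yi) / wsum;
        // head gradients
        for (int r = 0; r < cfg.h; ++r) {
          G[P_WD2](r, 0) += H.hh(r) * dlogit;
        }
        G[P_BD2](0, 0) += dlogit;
        arma::vec dh = P[P_WD2].col(0) * dlogit;
        for (int r = 0; r < cfg.h; ++r) {
          if (H.hpre(r) <= 0) dh(r) = 0;
        }
        G[P_WD1] += dh * H.z.t();
        G[P_BD1].col(0) += dh;
        arma::vec dzv = P[P_WD1].t() * dh;
        const int* codes4[4] = {lF, rcbufL.data(), rF, rcbufR.data()};
        for (int blk = 0; blk < 4; ++blk) {
          dfeat = dzv.subvec(blk * cfg.k2, (blk + 1) * cfg.k2 - 1);
          backward_seq(codes4[blk], cfg, P, W2T, C4[blk], dfeat, G,
                       dM1, dZ1, touchedP);
        }
      }
      // Adam step
      ++t;
      double bc1 = 1.0 - std::pow(beta1, (double)t);
      double bc2 = 1.0 - std::pow(beta2, (double)t);
      for (int i = 0; i < N_PAR; ++i) {
        M[i] = beta1 * M[i] + (1 - beta1) * G[i];
        V[i] = beta2 * V[i] + (1 - beta2) * arma::square(G[i]);
        P[i] -= lr * (M[i] / bc1) / (arma::sqrt(V[i] / bc2) + eps);
      }
      W2T = P[P_W2].t();
    }
    double train_loss = loss_sum / wsum_total;
    arma::vec vscores = predict_pairs_head(vseqL, vseqR, cfg, P);
    double val_ap = average_precision(vscores, vyv);
    log_loss.push_back(train_loss);
    log_val.push_back(val_ap);
    epochs_run = e + 1;
    if (val_ap > best_val + 1e-9) {
      best_val = val_ap;
      best_epoch = e + 1;
      bestP = P;
      since_best = 0;
    } else {
      ++since_best;
      if (since_best >= patience) break;
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix log(epochs_run, 3);
  for (int e = 0; e < epochs_run; ++e) {
    log(e, 0) = e + 1;
    log(e, 1) = log_loss[e];
    log(e, 2) = log_val[e];
  }
  colnames(log) = CharacterVector::create("epoch", "train_loss", "val_auprc");
  return List::create(_["params"] = put_params(bestP),
                      _["log"] = log,
                      _["best_epoch"] = best_epoch,
                      _["best_val_auprc"] = best_val);
}

// [[Rcpp::export]]
NumericMatrix cpp_extract_features(IntegerMatrix seqs, List params,
                                   List config, bool rc) {
  Config cfg = get_config(config);
  std::vector<arma::mat> P = get_params(params);
  int n = seqs.ncol();
  if (seqs.nrow() != cfg.L) stop("sequence length does not match config");
  NumericMatrix out(n, cfg.k2);
  SeqCache C;
  arma::mat Z1ws;
  std::vector<int> buf(cfg.L);
  for (int i = 0; i < n; ++i) {
    const int* codes = &seqs(0, i);
    if (rc) {
      rc_codes(codes, buf.data(), cfg.L);
      forward_seq(buf.data(), cfg, P, C, Z1ws);
    } else {
      forward_seq(codes, cfg, P, C, Z1ws);
    }
    for (int r = 0; r < cfg.k2; ++r) out(i, r) = C.feat(r);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_predict_head(IntegerMatrix seqL, IntegerMatrix seqR,
                               List params, List config) {
  Config cfg = get_config(config);
  std::vector<arma::mat> P = get_params(params);
  arma::vec out = predict_pairs_head(seqL, seqR, cfg, P);
  return NumericVector(out.begin(), out.end());
}

// First-convolutional-layer responses (conv + bias, no ReLU) for
// kernel-width windows; one row per window, one column per kernel.
// [[Rcpp::export]]
NumericMatrix cpp_conv1_scores(IntegerMatrix windows, List params,
                               List config) {
  Config cfg = get_config(config);
  std::vector<arma::mat> P = get_params(params);
  if (windows.nrow() != cfg.w1) stop("window width does not match config");
  int m = windows.ncol();
  NumericMatrix out(m, cfg.k1);
  const arma::mat& W1 = P[P_W1];
  for (int i = 0; i < m; ++i) {
    arma::vec z = P[P_B1].col(0);
    for (int j = 0; j < cfg.w1; ++j) {
      int idx = windows(j, i);
      if (idx < 4) z += W1.col(4 * j + idx);
    }
    for (int r = 0; r < cfg.k1; ++r) out(i, r) = z(r);
  }
  return out;
}
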
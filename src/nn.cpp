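// Sequence-labeling network for multi-task per-residue prediction:
// dense input projection -> transformer encoder layers (single-head
// self-attention + feed-forward, layer norm, residual) -> 1-D CNN layers
// (kernel 3, same padding) -> bidirectional LSTM layers -> one linear head
// per active task. Forward pass and analytic backpropagation are
// implemented here; the masked multi-task loss couples the heads.
//
// Proteins are processed at their own length (ragged batches); batch
// gradients are accumulated over proteins with per-task scaling
// weight / (number of unmasked residues in the batch), matching the
// mean-over-unmasked-residues reduction of the R-level loss.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;

static const double LN_EPS = 1e-5;

struct Cfg {
  int d, ff, ntr, ncnn, nrnn, h;
  double dropout;
  std::vector<std::string> tasks;
  int out_dim() const { return nrnn > 0 ? 2 * h : d; }
};

static Cfg parse_cfg(const List& cfg) {
  Cfg c;
  c.d = as<int>(cfg["d_model"]);
  c.ff = as<int>(cfg["ff_dim"]);
  c.ntr = as<int>(cfg["n_transformer"]);
  c.ncnn = as<int>(cfg["n_cnn"]);
  c.nrnn = as<int>(cfg["n_birnn"]);
  c.h = as<int>(cfg["rnn_hidden"]);
  c.dropout = as<double>(cfg["dropout"]);
  c.tasks = as<std::vector<std::string>>(cfg["tasks"]);
  return c;
}

static int task_nclass(const std::string& t) {
  if (t == "IF" || t == "BU") return 2;
  if (t == "S3") return 3;
  if (t == "S8") return 8;
  return 1;  // SA
}

struct Params {
  std::map<std::string, mat> P;
  mat& operator[](const std::string& k) {
    auto it = P.find(k);
    if (it == P.end()) stop("missing parameter: " + k);
    return it->second;
  }
};

static Params load_params(const List& params) {
  Params p;
  CharacterVector nm = params.names();
  for (int i = 0; i < params.size(); ++i)
    p.P[as<std::string>(nm[i])] = as<mat>(params[i]);
  return p;
}

struct Grads {
  std::map<std::string, mat> G;
  void add(const std::string& k, const mat& g) {
    auto it = G.find(k);
    if (it == G.end()) G[k] = g; else it->second += g;
  }
};

// ---- primitive layers ---------------------------------------------------

static mat relu(const mat& x) { return arma::clamp(x, 0.0, arma::datum::inf); }

static mat relu_mask(const mat& pre) {
  return arma::conv_to<mat>::from(pre > 0);
}

static mat softmax_rows(const mat& s) {
  mat t = s;
  t.each_col() -= arma::max(s, 1);
  mat e = arma::exp(t);
  e.each_col() /= arma::sum(e, 1);
  return e;
}

struct LnCache { mat xhat; vec invstd; };

static mat layernorm_fwd(const mat& x, const mat& g, const mat& b, LnCache& c) {
  vec mu = arma::mean(x, 1);
  vec var = arma::var(x, 1, 1);  // population variance per row
  c.invstd = 1.0 / arma::sqrt(var + LN_EPS);
  c.xhat = x;
  c.xhat.each_col() -= mu;
  c.xhat.each_col() %= c.invstd;
  mat y = c.xhat;
  y.each_row() %= g.row(0);
  y.each_row() += b.row(0);
  return y;
}

static mat layernorm_bwd(const mat& dy, const mat& g, const LnCache& c,
                         mat& dg, mat& db) {
  dg = arma::sum(dy % c.xhat, 0);
  db = arma::sum(dy, 0);
  mat dxhat = dy;
  dxhat.each_row() %= g.row(0);
  vec m1 = arma::mean(dxhat, 1);
  vec m2 = arma::mean(dxhat % c.xhat, 1);
  mat dx = dxhat;
  dx.each_col() -= m1;
  mat t2 = c.xhat;
  t2.each_col() %= m2;
  dx -= t2;
  dx.each_col() %= c.invstd;
  return dx;
}

// dropout: inverted scaling; mask entries are 0 or 1/(1-p)
static mat dropout_mask(int n, int m, double p, std::mt19937_64& rng) {
  mat msk(n, m);
  std::uniform_real_distribution<double> u(0.0, 1.0);
  double keep = 1.0 - p;
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i)
      msk(i, j) = (u(rng) < keep) ? 1.0 / keep : 0.0;
  return msk;
}

// concat of shifted rows for kernel-3 convolution with zero padding
static mat shift_concat(const mat& h) {
  int L = h.n_rows, d = h.n_cols;
  mat z(L, 3 * d, arma::fill::zeros);
  z.cols(d, 2 * d - 1) = h;
  if (L > 1) {
    z.submat(1, 0, L - 1, d - 1) = h.rows(0, L - 2);          // previous
    z.submat(0, 2 * d, L - 2, 3 * d - 1) = h.rows(1, L - 1);  // next
  }
  return z;
}

static void shift_concat_bwd(const mat& dz, mat& dh) {
  int L = dh.n_rows, d = dh.n_cols;
  dh += dz.cols(d, 2 * d - 1);
  if (L > 1) {
    dh.rows(0, L - 2) += dz.submat(1, 0, L - 1, d - 1);
    dh.rows(1, L - 1) += dz.submat(0, 2 * d, L - 2, 3 * d - 1);
  }
}

// ---- LSTM ----------------------------------------------------------------

struct LstmCache {
  mat x;                      // input sequence (L x in)
  mat ig, fg, og, gg, cs, hs, tc;  // gates, cell, hidden, tanh(cell): L x h
};

// gate order in the 4h weight block: input, forget, cell(g), output
static mat lstm_fwd(const mat& x, const mat& Wx, const mat& Wh, const mat& b,
                    LstmCache& cc) {
  int L = x.n_rows, h = Wh.n_rows;
  cc.x = x;
  cc.ig.set_size(L, h); cc.fg.set_size(L, h); cc.og.set_size(L, h);
  cc.gg.set_size(L, h); cc.cs.set_size(L, h); cc.hs.set_size(L, h);
  cc.tc.set_size(L, h);
  rowvec hprev(h, arma::fill::zeros), cprev(h, arma::fill::zeros);
  for (int t = 0; t < L; ++t) {
    rowvec z = x.row(t) * Wx + hprev * Wh + b.row(0);
    rowvec i = 1.0 / (1.0 + arma::exp(-z.subvec(0, h - 1)));
    rowvec f = 1.0 / (1.0 + arma::exp(-z.subvec(h, 2 * h - 1)));
    rowvec g = arma::tanh(z.subvec(2 * h, 3 * h - 1));
    rowvec o = 1.0 / (1.0 + arma::exp(-z.subvec(3 * h, 4 * h - 1)));
    rowvec c = f % cprev + i % g;
    rowvec tc = arma::tanh(c);
    rowvec hh = o % tc;
    cc.ig.row(t) = i; cc.fg.row(t) = f; cc.gg.row(t) = g; cc.og.row(t) = o;
    cc.cs.row(t) = c; cc.tc.row(t) = tc; cc.hs.row(t) = hh;
    hprev = hh; cprev = c;
  }
  return cc.hs;
}

static mat lstm_bwd(const mat& dh_out, const mat& Wx, const mat& Wh,
                    const LstmCache& cc, mat& dWx, mat& dWh, mat& db) {
  int L = cc.x.n_rows, h = Wh.n_rows;
  dWx.zeros(Wx.n_rows, Wx.n_cols);
  dWh.zeros(Wh.n_rows, Wh.n_cols);
  db.zeros(1, 4 * h);
  mat dx(L, cc.x.n_cols, arma::fill::zeros);
  rowvec dh_next(h, arma::fill::zeros), dc_next(h, arma::fill::zeros);
  for (int t = L - 1; t >= 0; --t) {
    rowvec dh = dh_out.row(t) + dh_next;
    rowvec i = cc.ig.row(t), f = cc.fg.row(t), g = cc.gg.row(t),
           o = cc.og.row(t), tc = cc.tc.row(t);
    rowvec dc = dh % o % (1.0 - tc % tc) + dc_next;
    rowvec cprev = (t > 0) ? rowvec(cc.cs.row(t - 1))
                           : rowvec(h, arma::fill::zeros);
    rowvec di = dc % g % i % (1.0 - i);
    rowvec df = dc % cprev % f % (1.0 - f);
    rowvec dg = dc % i % (1.0 - g % g);
    rowvec do_ = dh % tc % o % (1.0 - o);
    rowvec dz(4 * h);
    dz.subvec(0, h - 1) = di;
    dz.subvec(h, 2 * h - 1) = df;
    dz.subvec(2 * h, 3 * h - 1) = dg;
    dz.subvec(3 * h, 4 * h - 1) = do_;
    dWx += cc.x.row(t).t() * dz;
    if (t > 0) dWh += cc.hs.row(t - 1).t() * dz;
    db += dz;
    dx.row(t) = dz * Wx.t();
    dh_next = dz * Wh.t();
    dc_next = dc % f;
  }
  return dx;
}

// ---- full trunk forward with caches -------------------------------------

struct TrCache {
  mat Hin, Q, K, V, A, AV, O, Dmask1, R1, H1;
  LnCache ln1;
  mat Fpre, Frelu, F2, Dmask2, R2;
  LnCache ln2;
};

struct CnnCache { mat Hin, Z, pre, Dmask; };

struct ForwardCache {
  mat X, pre_in, H0, Dmask0;
  std::vector<TrCache> tr;
  std::vector<CnnCache> cnn;
  std::vector<LstmCache> fw, bw;   // per biLSTM layer
  std::vector<mat> rnn_in, rnn_out, rnn_dmask;
  mat trunk_out;
};

static mat trunk_forward(Params& P, const Cfg& cfg, const mat& X,
                         bool training, std::mt19937_64& rng,
                         ForwardCache& fc) {
  int L = X.n_rows;
  double p = training ? cfg.dropout : 0.0;
  fc.X = X;
  fc.pre_in = X * P["in_W"];
  fc.pre_in.each_row() += P["in_b"].row(0);
  mat H = relu(fc.pre_in);
  fc.Dmask0 = (p > 0) ? dropout_mask(L, cfg.d, p, rng)
                      : mat(L, cfg.d, arma::fill::ones);
  H %= fc.Dmask0;
  fc.H0 = H;
  double scale = 1.0 / std::sqrt((double)cfg.d);
  fc.tr.resize(cfg.ntr);
  for (int l = 0; l < cfg.ntr; ++l) {
    TrCache& c = fc.tr[l];
    std::string pf = "t" + std::to_string(l) + "_";
    c.Hin = H;
    c.Q = H * P[pf + "Wq"];
    c.K = H * P[pf + "Wk"];
    c.V = H * P[pf + "Wv"];
    c.A = softmax_rows(c.Q * c.K.t() * scale);
    c.AV = c.A * c.V;
    c.O = c.AV * P[pf + "Wo"];
    c.O.each_row() += P[pf + "bo"].row(0);
    c.Dmask1 = (p > 0) ? dropout_mask(L, cfg.d, p, rng)
                       : mat(L, cfg.d, arma::fill::ones);
    c.O %= c.Dmask1;
    c.R1 = c.Hin + c.O;
    c.H1 = layernorm_fwd(c.R1, P[pf + "ln1_g"], P[pf + "ln1_b"], c.ln1);
    c.Fpre = c.H1 * P[pf + "W1"];
    c.Fpre.each_row() += P[pf + "b1"].row(0);
    c.Frelu = relu(c.Fpre);
    c.F2 = c.Frelu * P[pf + "W2"];
    c.F2.each_row() += P[pf + "b2"].row(0);
    c.Dmask2 = (p > 0) ? dropout_mask(L, cfg.d, p, rng)
                       : mat(L, cfg.d, arma::fill::ones);
    c.F2 %= c.Dmask2;
    c.R2 = c.H1 + c.F2;
    H = layernorm_fwd(c.R2, P[pf + "ln2_g"], P[pf + "ln2_b"], c.ln2);
  }
  fc.cnn.resize(cfg.ncnn);
  for (int l = 0; l < cfg.ncnn; ++l) {
    CnnCache& c = fc.cnn[l];
    std::string pf = "c" + std::to_string(l) + "_";
    c.Hin = H;
    c.Z = shift_concat(H);
    c.pre = c.Z * P[pf + "W"];
    c.pre.each_row() += P[pf + "b"].row(0);
    mat Hn = relu(c.pre);
    c.Dmask = (p > 0) ? dropout_mask(L, cfg.d, p, rng)
                      : mat(L, cfg.d, arma::fill::ones);
    Hn %= c.Dmask;
    H = c.Hin + Hn;  // residual keeps depth trainable
  }
  fc.fw.resize(cfg.nrnn);
  fc.bw.resize(cfg.nrnn);
  fc.rnn_in.resize(cfg.nrnn);
  fc.rnn_out.resize(cfg.nrnn);
  fc.rnn_dmask.resize(cfg.nrnn);
  for (int l = 0; l < cfg.nrnn; ++l) {
    std::string pf = "l" + std::to_string(l);
    fc.rnn_in[l] = H;
    mat hf = lstm_fwd(H, P[pf + "f_Wx"], P[pf + "f_Wh"], P[pf + "f_b"], fc.fw[l]);
    mat Hrev = arma::flipud(H);
    mat hb = lstm_fwd(Hrev, P[pf + "b_Wx"], P[pf + "b_Wh"], P[pf + "b_b"], fc.bw[l]);
    mat out = arma::join_rows(hf, arma::flipud(hb));
    fc.rnn_dmask[l] = (p > 0) ? dropout_mask(L, 2 * cfg.h, p, rng)
                              : mat(L, 2 * cfg.h, arma::fill::ones);
    out %= fc.rnn_dmask[l];
    fc.rnn_out[l] = out;
    H = out;
  }
  fc.trunk_out = H;
  return H;
}

static mat trunk_backward(Params& P, const Cfg& cfg, const ForwardCache& fc,
                          mat dH, Grads& G) {
  for (int l = cfg.nrnn - 1; l >= 0; --l) {
    std::string pf = "l" + std::to_string(l);
    dH %= fc.rnn_dmask[l];
    mat dhf = dH.cols(0, cfg.h - 1);
    mat dhb = arma::flipud(mat(dH.cols(cfg.h, 2 * cfg.h - 1)));
    mat dWx, dWh, db;
    mat dx_f = lstm_bwd(dhf, P[pf + "f_Wx"], P[pf + "f_Wh"], fc.fw[l],
                        dWx, dWh, db);
    G.add(pf + "f_Wx", dWx); G.add(pf + "f_Wh", dWh); G.add(pf + "f_b", db);
    mat dx_b = lstm_bwd(dhb, P[pf + "b_Wx"], P[pf + "b_Wh"], fc.bw[l],
                        dWx, dWh, db);
    G.add(pf + "b_Wx", dWx); G.add(pf + "b_Wh", dWh); G.add(pf + "b_b", db);
    dH = dx_f + arma::flipud(dx_b);
  }
  for (int l = cfg.ncnn - 1; l >= 0; --l) {
    const CnnCache& c = fc.cnn[l];
    std::string pf = "c" + std::to_string(l) + "_";
    mat dHn = dH % c.Dmask;
    mat dpre = dHn % relu_mask(c.pre);
    G.add(pf + "W", c.Z.t() * dpre);
    G.add(pf + "b", arma::sum(dpre, 0));
    mat dZ = dpre * P[pf + "W"].t();
    mat dHin(c.Hin.n_rows, c.Hin.n_cols, arma::fill::zeros);
    shift_concat_bwd(dZ, dHin);
    dH = dH + dHin;  // residual
  }
  double scale = 1.0 / std::sqrt((double)cfg.d);
  for (int l = cfg.ntr - 1; l >= 0; --l) {
    const TrCache& c = fc.tr[l];
    std::string pf = "t" + std::to_string(l) + "_";
    mat dg, db;
    mat dR2 = layernorm_bwd(dH, P[pf + "ln2_g"], c.ln2, dg, db);
    G.add(pf + "ln2_g", dg); G.add(pf + "ln2_b", db);
    mat dF2 = dR2 % c.Dmask2;
    mat dH1 = dR2;  // residual branch
    G.add(pf + "W2", c.Frelu.t() * dF2);
    G.add(pf + "b2", arma::sum(dF2, 0));
    mat dFrelu = dF2 * P[pf + "W2"].t();
    mat dFpre = dFrelu % relu_mask(c.Fpre);
    G.add(pf + "W1", c.H1.t() * dFpre);
    G.add(pf + "b1", arma::sum(dFpre, 0));
    dH1 += dFpre * P[pf + "W1"].t();
    mat dR1 = layernorm_bwd(dH1, P[pf + "ln1_g"], c.ln1, dg, db);
    G.add(pf + "ln1_g", dg); G.add(pf + "ln1_b", db);
    mat dO = dR1 % c.Dmask1;
    mat dHin = dR1;  // residual branch
    G.add(pf + "Wo", c.AV.t() * dO);
    G.add(pf + "bo", arma::sum(dO, 0));
    mat dAV = dO * P[pf + "Wo"].t();
    mat dA = dAV * c.V.t();
    mat dV = c.A.t() * dAV;
    // softmax backward per row
    vec rowdot = arma::sum(dA % c.A, 1);
    mat dS = dA;
    dS.each_col() -= rowdot;
    dS %= c.A;
    dS *= scale;
    mat dQ = dS * c.K;
    mat dK = dS.t() * c.Q;
    G.add(pf + "Wq", c.Hin.t() * dQ);
    G.add(pf + "Wk", c.Hin.t() * dK);
    G.add(pf + "Wv", c.Hin.t() * dV);
    dHin += dQ * P[pf + "Wq"].t() + dK * P[pf + "Wk"].t() + dV * P[pf + "Wv"].t();
    dH = dHin;
  }
  dH %= fc.Dmask0;
  mat dpre = dH % relu_mask(fc.pre_in);
  G.add("in_W", fc.X.t() * dpre);
  G.add("in_b", arma::sum(dpre, 0));
  return dpre * P["in_W"].t();
}

// ---- heads + loss --------------------------------------------------------

static List heads_forward(Params& P, const Cfg& cfg, const mat& H) {
  List out;
  for (const std::string& t : cfg.tasks) {
    int K = task_nclass(t);
    mat logits = H * P["head_" + t + "_W"];
    logits.each_row() += P["head_" + t + "_b"].row(0);
    out[t] = (K == 1) ? logits : softmax_rows(logits);
  }
  return out;
}

// [[Rcpp::export(name = ".nn_predict_cpp")]]
List nn_predict_cpp(List params, List cfg_in, List X_list) {
  Cfg cfg = parse_cfg(cfg_in);
  Params P = load_params(params);
  std::mt19937_64 rng(0);
  List out;
  for (const std::string& t : cfg.tasks) out[t] = List(X_list.size());
  for (int i = 0; i < X_list.size(); ++i) {
    ForwardCache fc;
    mat H = trunk_forward(P, cfg, as<mat>(X_list[i]), false, rng, fc);
    List heads = heads_forward(P, cfg, H);
    for (const std::string& t : cfg.tasks) {
      List slot = out[t];
      slot[i] = heads[t];
    }
  }
  return out;
}

// Batch loss + gradient. Per task: loss = sum over unmasked residues of the
// per-residue loss / (number of unmasked residues in the batch); interface
// positives scaled by class_weight. Total = sum over active tasks of
// weight * task mean loss.
// [[Rcpp::export(name = ".nn_batch_grad_cpp")]]
List nn_batch_grad_cpp(List params, List cfg_in, List batch,
                       NumericVector weights, double class_weight,
                       bool training, int dropout_seed) {
  Cfg cfg = parse_cfg(cfg_in);
  Params P = load_params(params);
  std::mt19937_64 rng((uint64_t)dropout_seed);
  int B = batch.size();
  CharacterVector wnames = weights.names();
  std::map<std::string, double> w;
  for (int i = 0; i < weights.size(); ++i)
    w[as<std::string>(wnames[i])] = weights[i];

  // first pass: per-task unmasked counts over the batch
  std::map<std::string, double> cnt;
  for (const std::string& t : cfg.tasks) cnt[t] = 0.0;
  for (int b = 0; b < B; ++b) {
    List masks = as<List>(as<List>(batch[b])["masks"]);
    for (const std::string& t : cfg.tasks) {
      LogicalVector m = masks[t];
      for (int i = 0; i < m.size(); ++i) if (m[i]) cnt[t] += 1.0;
    }
  }

  Grads G;
  std::map<std::string, double> loss_sum;
  for (const std::string& t : cfg.tasks) loss_sum[t] = 0.0;

  for (int b = 0; b < B; ++b) {
    List rec = batch[b];
    mat X = as<mat>(rec["X"]);
    List labels = as<List>(rec["labels"]);
    List masks = as<List>(rec["masks"]);
    ForwardCache fc;
    mat H = trunk_forward(P, cfg, X, training, rng, fc);
    int L = H.n_rows;
    mat dH(L, cfg.out_dim(), arma::fill::zeros);
    for (const std::string& t : cfg.tasks) {
      if (cnt[t] == 0.0) continue;
      LogicalVector m = masks[t];
      NumericVector y = labels[t];
      int K = task_nclass(t);
      mat logits = H * P["head_" + t + "_W"];
      logits.each_row() += P["head_" + t + "_b"].row(0);
      mat dlogits(L, K, arma::fill::zeros);
      double inv = 1.0 / cnt[t];
      if (K == 1) {
        for (int i = 0; i < L; ++i) {
          if (!m[i]) continue;
          double diff = logits(i, 0) - y[i];
          loss_sum[t] += diff * diff * inv;
          dlogits(i, 0) = 2.0 * diff * inv;
        }
      } else {
        mat prob = softmax_rows(logits);
        for (int i = 0; i < L; ++i) {
          if (!m[i]) continue;
          int cls = (t == "S3" || t == "S8") ? (int)y[i] - 1 : (int)y[i];
          double sc = inv;
          if (t == "IF" && cls == 1) sc *= class_weight;
          loss_sum[t] += -std::log(std::max(prob(i, cls), 1e-12)) * sc;
          for (int k = 0; k < K; ++k)
            dlogits(i, k) = sc * (prob(i, k) - (k == cls ? 1.0 : 0.0));
        }
      }
      double tw = w.count(t) ? w[t] : 0.0;
      if (tw == 0.0) continue;
      mat dlog_w = dlogits * tw;
      G.add("head_" + t + "_W", H.t() * dlog_w);
      G.add("head_" + t + "_b", arma::sum(dlog_w, 0));
      dH += dlog_w * P["head_" + t + "_W"].t();
    }
    trunk_backward(P, cfg, fc, dH, G);
  }

  double total = 0.0;
  List task_losses, counts;
  for (const std::string& t : cfg.tasks) {
    task_losses[t] = loss_sum[t];
    counts[t] = cnt[t];
    total += (w.count(t) ? w[t] : 0.0) * loss_sum[t];
  }
  List grads;
  for (auto& kv : G.G) grads[kv.first] = kv.second;
  return List::create(_["total"] = total, _["task_losses"] = task_losses,
                      _["counts"] = counts, _["grads"] = grads);
}
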
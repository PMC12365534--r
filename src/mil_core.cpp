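// Single-precision training and inference core for the gated attention-MIL
// network.  The R-level functions mil_embed()/attention_scores()/
// attention_pool()/mil_classify() are the reference implementation; this
// file mirrors them exactly (see test-mil-core.R for the equivalence check)
// and exists so that cohort-scale training stays on BLAS sgemm.  Bags of an
// accumulation group are stacked row-wise so every large GEMM runs once per
// optimizer step, not once per bag.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// parameter tensor order; biases are stored 1 x n so Adam treats every
// parameter uniformly
enum { W1, B1, WV, BV, WU, BU, AW, AC, WC1, BC1, WC2, BC2, NPAR };

typedef std::vector<arma::fmat> Tensors;

Tensors tensors_from_list(const List& p) {
  Tensors t(NPAR);
  t[W1]  = arma::conv_to<arma::fmat>::from(as<arma::mat>(p["W1"]));
  t[B1]  = arma::conv_to<arma::fmat>::from(as<arma::rowvec>(p["b1"]));
  t[WV]  = arma::conv_to<arma::fmat>::from(as<arma::mat>(p["Wv"]));
  t[BV]  = arma::conv_to<arma::fmat>::from(as<arma::rowvec>(p["bv"]));
  t[WU]  = arma::conv_to<arma::fmat>::from(as<arma::mat>(p["Wu"]));
  t[BU]  = arma::conv_to<arma::fmat>::from(as<arma::rowvec>(p["bu"]));
  t[AW]  = arma::conv_to<arma::fmat>::from(as<arma::vec>(p["w"]));
  t[AC]  = arma::fmat(1, 1);
  t[AC](0, 0) = (float)as<double>(p["c"]);
  t[WC1] = arma::conv_to<arma::fmat>::from(as<arma::mat>(p["Wc1"]));
  t[BC1] = arma::conv_to<arma::fmat>::from(as<arma::rowvec>(p["bc1"]));
  t[WC2] = arma::conv_to<arma::fmat>::from(as<arma::mat>(p["Wc2"]));
  t[BC2] = arma::conv_to<arma::fmat>::from(as<arma::rowvec>(p["bc2"]));
  return t;
}

List tensors_to_list(const Tensors& t) {
  return List::create(
    _["W1"]  = arma::conv_to<arma::mat>::from(t[W1]),
    _["b1"]  = arma::conv_to<arma::rowvec>::from(t[B1].row(0)),
    _["Wv"]  = arma::conv_to<arma::mat>::from(t[WV]),
    _["bv"]  = arma::conv_to<arma::rowvec>::from(t[BV].row(0)),
    _["Wu"]  = arma::conv_to<arma::mat>::from(t[WU]),
    _["bu"]  = arma::conv_to<arma::rowvec>::from(t[BU].row(0)),
    _["w"]   = arma::conv_to<arma::vec>::from(t[AW].col(0)),
    _["c"]   = (double)t[AC](0, 0),
    _["Wc1"] = arma::conv_to<arma::mat>::from(t[WC1]),
    _["bc1"] = arma::conv_to<arma::rowvec>::from(t[BC1].row(0)),
    _["Wc2"] = arma::conv_to<arma::mat>::from(t[WC2]),
    _["bc2"] = arma::conv_to<arma::rowvec>::from(t[BC2].row(0)));
}

// xorshift128+ for dropout masks (cheap relative to mt19937 at ~3e5 draws
// per optimizer step)
struct XorShift {
  uint64_t s0, s1;
  explicit XorShift(uint64_t seed) {
    s0 = seed * 2685821657736338717ULL + 1ULL;
    s1 = (seed ^ 0x9E3779B97F4A7C15ULL) * 6364136223846793005ULL + 1ULL;
    next(); next();
  }
  uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  float unif() { return (next() >> 40) * (1.0f / 16777216.0f); }
};

arma::fvec softmax_seg(const arma::fvec& s) {
  arma::fvec e = arma::exp(s - s.max());
  return e / arma::accu(e);
}

struct Adam {
  Tensors m, v;
  long t = 0;
  void init(const Tensors& p) {
    m.resize(p.size()); v.resize(p.size());
    for (size_t i = 0; i < p.size(); ++i) {
      m[i].zeros(p[i].n_rows, p[i].n_cols);
      v[i].zeros(p[i].n_rows, p[i].n_cols);
    }
  }
  void step(Tensors& p, const Tensors& g, float lr, float wd) {
    t += 1;
    const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
    float c1 = 1.0f - std::pow(b1, (float)t);
    float c2 = 1.0f - std::pow(b2, (float)t);
    // fused in-place update: no temporaries, one pass per tensor
    for (size_t i = 0; i < p.size(); ++i) {
      float* pp = p[i].memptr();
      const float* gp = g[i].memptr();
      float* mp = m[i].memptr();
      float* vp = v[i].memptr();
      const arma::uword n = p[i].n_elem;
      for (arma::uword j = 0; j < n; ++j) {
        float gi = gp[j] + wd * pp[j];
        mp[j] = b1 * mp[j] + (1.0f - b1) * gi;
        vp[j] = b2 * vp[j] + (1.0f - b2) * gi * gi;
        pp[j] -= lr * (mp[j] / c1) /
                 (std::sqrt(vp[j] / c2) + eps);
      }
    }
  }
};

std::vector<arma::fmat> bags_to_fmat(const List& X) {
  std::vector<arma::fmat> out;
  out.reserve(X.size());
  for (R_xlen_t i = 0; i < X.size(); ++i)
    out.push_back(arma::conv_to<arma::fmat>::from(as<arma::mat>(X[i])));
  return out;
}

// forward pass for one bag at inference
void forward_infer(const Tensors& t, bool gated, const arma::fmat& X,
                   arma::fvec& prob, arma::fvec& attn, arma::fvec& raw) {
  arma::fmat H = X * t[W1];
  H.each_row() += t[B1].row(0);
  H = arma::clamp(H, 0.0f, arma::datum::inf);
  arma::fmat Av = arma::tanh(H * t[WV] +
                             arma::repmat(t[BV], H.n_rows, 1));
  arma::fmat G;
  if (gated) {
    arma::fmat Au = 1.0f / (1.0f + arma::exp(-(H * t[WU] +
                      arma::repmat(t[BU], H.n_rows, 1))));
    G = Av % Au;
  } else G = Av;
  arma::fvec s = G * t[AW].col(0) + t[AC](0, 0);
  raw = s;
  attn = softmax_seg(s);
  arma::frowvec z = attn.t() * H;
  arma::frowvec q1 = z * t[WC1] + t[BC1].row(0);
  q1 = arma::clamp(q1, 0.0f, arma::datum::inf);
  arma::frowvec logits = q1 * t[WC2] + t[BC2].row(0);
  prob = softmax_seg(logits.t());
}

} // namespace

// [[Rcpp::export(name = ".mil_train_cpp")]]
List mil_train_cpp(List X, IntegerVector y, List params0, bool gated,
                   double dropout, int n_classes, std::string loss_mode,
                   double ema_decay, double eps_stat,
                   NumericVector stat0, NumericVector count0,
                   int epochs, double lr, double weight_decay, int accum,
                   int seed) {
  const int n = X.size();
  if (n == 0) stop("empty training set");
  std::vector<arma::fmat> bags = bags_to_fmat(X);
  const arma::uword D = bags[0].n_cols;
  Tensors net = tensors_from_list(params0);
  const arma::uword E = net[W1].n_cols, A = net[WV].n_cols;
  const arma::uword P = net[WC1].n_cols, K = net[WC2].n_cols;
  if ((int)K != n_classes) stop("parameter/classes mismatch");

  std::mt19937 order_rng((unsigned)seed);
  XorShift drop_rng((uint64_t)seed * 7919ULL + 13ULL);
  const float keep = 1.0f - (float)dropout;

  arma::fvec stat = arma::conv_to<arma::fvec>::from(as<arma::vec>(stat0));
  arma::fvec cls_count =
      arma::conv_to<arma::fvec>::from(as<arma::vec>(count0));
  arma::fvec train_count(n_classes, arma::fill::zeros);
  for (int i = 0; i < n; ++i) train_count((arma::uword)y[i]) += 1.0f;

  Adam adam; adam.init(net);
  Tensors g(NPAR);

  NumericVector epoch_loss(epochs);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), order_rng);
    double loss_sum = 0.0;
    for (int start = 0; start < n; start += accum) {
      const int B = std::min(accum, n - start);
      // stack the group's bags row-wise
      arma::uword Mtot = 0;
      std::vector<arma::uword> off(B + 1, 0);
      for (int b = 0; b < B; ++b) {
        Mtot += bags[order[start + b]].n_rows;
        off[b + 1] = Mtot;
      }
      arma::fmat Xc(Mtot, D);
      for (int b = 0; b < B; ++b)
        Xc.rows(off[b], off[b + 1] - 1) = bags[order[start + b]];

      // sample weights from incoming class statistics, mean 1 over batch
      arma::fvec wts(B, arma::fill::ones);
      if (loss_mode == "rebalanced") {
        for (int b = 0; b < B; ++b)
          wts(b) = 1.0f / (stat((arma::uword)y[order[start + b]]) +
                           (float)eps_stat);
      } else if (loss_mode == "cbce") {
        for (int b = 0; b < B; ++b) {
          float cnt = train_count((arma::uword)y[order[start + b]]);
          wts(b) = cnt > 0.0f ? 1.0f / cnt : 1.0f;
        }
      }
      wts *= (float)B / arma::accu(wts);

      // ---- forward (stacked) ----
      arma::fmat Z1 = Xc * net[W1];
      Z1.each_row() += net[B1].row(0);
      arma::fmat Hd = arma::clamp(Z1, 0.0f, arma::datum::inf);
      if (dropout > 0.0) {
        for (arma::uword j = 0; j < Hd.n_elem; ++j)
          if (drop_rng.unif() < (float)dropout) Hd[j] = 0.0f;
          else Hd[j] /= keep;
      }
      arma::fmat Av = arma::tanh(Hd * net[WV] + arma::repmat(net[BV], Mtot, 1));
      arma::fmat Au, G;
      if (gated) {
        Au = 1.0f / (1.0f + arma::exp(-(Hd * net[WU] +
               arma::repmat(net[BU], Mtot, 1))));
        G = Av % Au;
      } else G = Av;
      arma::fvec svec = G * net[AW].col(0) + net[AC](0, 0);

      arma::fvec a(Mtot);
      arma::fmat Zp(B, E);           // pooled slide vectors
      for (int b = 0; b < B; ++b) {
        arma::fvec ab = softmax_seg(svec.subvec(off[b], off[b + 1] - 1));
        a.subvec(off[b], off[b + 1] - 1) = ab;
        Zp.row(b) = ab.t() * Hd.rows(off[b], off[b + 1] - 1);
      }
      arma::fmat Q1 = Zp * net[WC1] + arma::repmat(net[BC1], B, 1);
      arma::fmat H1 = arma::clamp(Q1, 0.0f, arma::datum::inf);
      arma::fmat L = H1 * net[WC2] + arma::repmat(net[BC2], B, 1);
      arma::fmat Pm(B, K);
      for (int b = 0; b < B; ++b)
        Pm.row(b) = softmax_seg(L.row(b).t()).t();

      // loss, gradient magnitudes, dlogits
      arma::fmat dL(B, K);
      arma::fvec gmag(B);
      for (int b = 0; b < B; ++b) {
        int yb = y[order[start + b]];
        float py = std::max(Pm(b, (arma::uword)yb), 1e-12f);
        loss_sum += wts(b) * (-std::log(py));
        gmag(b) = 2.0f * (1.0f - Pm(b, (arma::uword)yb));
        for (arma::uword k = 0; k < K; ++k)
          dL(b, k) = (wts(b) / B) *
                     (Pm(b, k) - (k == (arma::uword)yb ? 1.0f : 0.0f));
      }

      // ---- backward ----
      g[WC2] = H1.t() * dL;
      g[BC2] = arma::sum(dL, 0);
      arma::fmat dH1 = dL * net[WC2].t();
      arma::fmat dQ1 = dH1 % arma::conv_to<arma::fmat>::from(Q1 > 0.0f);
      g[WC1] = Zp.t() * dQ1;
      g[BC1] = arma::sum(dQ1, 0);
      arma::fmat dZp = dQ1 * net[WC1].t();   // B x E

      arma::fvec ds(Mtot);
      arma::fmat dHd(Mtot, E);
      for (int b = 0; b < B; ++b) {
        arma::fvec ab = a.subvec(off[b], off[b + 1] - 1);
        arma::fvec da = Hd.rows(off[b], off[b + 1] - 1) * dZp.row(b).t();
        ds.subvec(off[b], off[b + 1] - 1) =
            ab % (da - arma::dot(ab, da));
        dHd.rows(off[b], off[b + 1] - 1) = ab * dZp.row(b);
      }
      g[AW] = G.t() * ds;
      g[AC].set_size(1, 1);
      g[AC](0, 0) = arma::accu(ds);
      arma::fmat dG = ds * net[AW].col(0).t();
      arma::fmat dZv = (gated ? arma::fmat(dG % Au) : dG) %
                       (1.0f - arma::square(Av));
      g[WV] = Hd.t() * dZv;
      g[BV] = arma::sum(dZv, 0);
      dHd += dZv * net[WV].t();
      if (gated) {
        arma::fmat dZu = (dG % Av) % (Au % (1.0f - Au));
        g[WU] = Hd.t() * dZu;
        g[BU] = arma::sum(dZu, 0);
        dHd += dZu * net[WU].t();
      } else {
        g[WU].zeros(net[WU].n_rows, net[WU].n_cols);
        g[BU].zeros(1, net[BU].n_cols);
      }
      // ReLU+dropout factor recovered from Hd/Z1 (Hd>0 => kept and active)
      arma::fmat dZ1(Mtot, E, arma::fill::zeros);
      arma::uvec idx = arma::find(Hd > 0.0f);
      dZ1.elem(idx) = dHd.elem(idx) % (Hd.elem(idx) / Z1.elem(idx));
      g[W1] = Xc.t() * dZ1;
      g[B1] = arma::sum(dZ1, 0);

      adam.step(net, g, (float)lr, (float)weight_decay);

      // EMA of per-class gradient magnitude, updated after the batch
      for (int b = 0; b < B; ++b) {
        arma::uword yb = (arma::uword)y[order[start + b]];
        stat(yb) = (float)ema_decay * stat(yb) +
                   (1.0f - (float)ema_decay) * gmag(b);
        cls_count(yb) += 1.0f;
      }
    }
    epoch_loss[ep] = loss_sum / n;
    Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["params"] = tensors_to_list(net),
    _["epoch_loss"] = epoch_loss,
    _["stat"] = arma::conv_to<arma::vec>::from(stat),
    _["count"] = arma::conv_to<arma::vec>::from(cls_count));
}

// [[Rcpp::export(name = ".mil_predict_cpp")]]
List mil_predict_cpp(List X, List params, bool gated) {
  std::vector<arma::fmat> bags = bags_to_fmat(X);
  Tensors net = tensors_from_list(params);
  const int n = bags.size();
  const int K = net[WC2].n_cols;
  NumericMatrix prob(n, K);
  List attn(n), attn_raw(n);
  for (int i = 0; i < n; ++i) {
    arma::fvec p, a, r;
    forward_infer(net, gated, bags[i], p, a, r);
    for (int k = 0; k < K; ++k) prob(i, k) = p((arma::uword)k);
    attn[i] = arma::conv_to<arma::vec>::from(a);
    attn_raw[i] = arma::conv_to<arma::vec>::from(r);
  }
  return List::create(_["prob"] = prob, _["attention"] = attn,
                      _["attention_raw"] = attn_raw);
}

// FNV-1a over a raw byte stream; returns a double exactly representing the
// 32-bit hash (content-hash seeds for the test backbone).
// [[Rcpp::export(name = ".fnv1a_cpp")]]
double fnv1a_cpp(RawVector bytes) {
  uint32_t h = 2166136261u;
  for (R_xlen_t i = 0; i < bytes.size(); ++i) {
    h ^= (uint32_t)bytes[i];
    h *= 16777619u;
  }
  return (double)h;
}

// Gradient of the weighted-CE objective for one batch (dropout disabled);
// exposed for the finite-difference check in the test suite.
// [[Rcpp::export(name = ".mil_grad_cpp")]]
List mil_grad_cpp(List X, IntegerVector y, List params, bool gated,
                  NumericVector wts) {
  std::vector<arma::fmat> bags = bags_to_fmat(X);
  Tensors net = tensors_from_list(params);
  const int B = bags.size();
  const arma::uword D = bags[0].n_cols, E = net[W1].n_cols;
  const arma::uword K = net[WC2].n_cols;
  arma::uword Mtot = 0;
  std::vector<arma::uword> off(B + 1, 0);
  for (int b = 0; b < B; ++b) {
    Mtot += bags[b].n_rows;
    off[b + 1] = Mtot;
  }
  arma::fmat Xc(Mtot, D);
  for (int b = 0; b < B; ++b) Xc.rows(off[b], off[b + 1] - 1) = bags[b];
  Tensors g(NPAR);
  double loss = 0.0;

  arma::fmat Z1 = Xc * net[W1];
  Z1.each_row() += net[B1].row(0);
  arma::fmat Hd = arma::clamp(Z1, 0.0f, arma::datum::inf);
  arma::fmat Av = arma::tanh(Hd * net[WV] + arma::repmat(net[BV], Mtot, 1));
  arma::fmat Au, G;
  if (gated) {
    Au = 1.0f / (1.0f + arma::exp(-(Hd * net[WU] +
           arma::repmat(net[BU], Mtot, 1))));
    G = Av % Au;
  } else G = Av;
  arma::fvec svec = G * net[AW].col(0) + net[AC](0, 0);
  arma::fvec a(Mtot);
  arma::fmat Zp(B, E);
  for (int b = 0; b < B; ++b) {
    arma::fvec ab = softmax_seg(svec.subvec(off[b], off[b + 1] - 1));
    a.subvec(off[b], off[b + 1] - 1) = ab;
    Zp.row(b) = ab.t() * Hd.rows(off[b], off[b + 1] - 1);
  }
  arma::fmat Q1 = Zp * net[WC1] + arma::repmat(net[BC1], B, 1);
  arma::fmat H1 = arma::clamp(Q1, 0.0f, arma::datum::inf);
  arma::fmat L = H1 * net[WC2] + arma::repmat(net[BC2], B, 1);
  arma::fmat Pm(B, K);
  for (int b = 0; b < B; ++b) Pm.row(b) = softmax_seg(L.row(b).t()).t();
  arma::fmat dL(B, K);
  for (int b = 0; b < B; ++b) {
    int yb = y[b];
    float py = std::max(Pm(b, (arma::uword)yb), 1e-12f);
    loss += wts[b] / B * (-std::log(py));
    for (arma::uword k = 0; k < K; ++k)
      dL(b, k) = ((float)wts[b] / B) *
                 (Pm(b, k) - (k == (arma::uword)yb ? 1.0f : 0.0f));
  }
  g[WC2] = H1.t() * dL;
  g[BC2] = arma::sum(dL, 0);
  arma::fmat dH1 = dL * net[WC2].t();
  arma::fmat dQ1 = dH1 % arma::conv_to<arma::fmat>::from(Q1 > 0.0f);
  g[WC1] = Zp.t() * dQ1;
  g[BC1] = arma::sum(dQ1, 0);
  arma::fmat dZp = dQ1 * net[WC1].t();
  arma::fvec ds(Mtot);
  arma::fmat dHd(Mtot, E);
  for (int b = 0; b < B; ++b) {
    arma::fvec ab = a.subvec(off[b], off[b + 1] - 1);
    arma::fvec da = Hd.rows(off[b], off[b + 1] - 1) * dZp.row(b).t();
    ds.subvec(off[b], off[b + 1] - 1) = ab % (da - arma::dot(ab, da));
    dHd.rows(off[b], off[b + 1] - 1) = ab * dZp.row(b);
  }
  g[AW] = G.t() * ds;
  g[AC].set_size(1, 1);
  g[AC](0, 0) = arma::accu(ds);
  arma::fmat dG = ds * net[AW].col(0).t();
  arma::fmat dZv = (gated ? arma::fmat(dG % Au) : dG) %
                   (1.0f - arma::square(Av));
  g[WV] = Hd.t() * dZv;
  g[BV] = arma::sum(dZv, 0);
  dHd += dZv * net[WV].t();
  if (gated) {
    arma::fmat dZu = (dG % Av) % (Au % (1.0f - Au));
    g[WU] = Hd.t() * dZu;
    g[BU] = arma::sum(dZu, 0);
    dHd += dZu * net[WU].t();
  } else {
    g[WU].zeros(net[WU].n_rows, net[WU].n_cols);
    g[BU].zeros(1, net[BU].n_cols);
  }
  arma::fmat dZ1 = dHd % arma::conv_to<arma::fmat>::from(Z1 > 0.0f);
  g[W1] = Xc.t() * dZ1;
  g[B1] = arma::sum(dZ1, 0);
  List gl = tensors_to_list(g);
  gl["loss"] = loss;
  return gl;
}

// Accumulate the instance cross-product matrix sum_i x_i x_i^T over a bag
// list without materializing the pooled matrix; rows are subsampled by a
// deterministic stride so at most max_rows instances contribute.
// [[Rcpp::export(name = ".instance_crossprod_cpp")]]
List instance_crossprod_cpp(List X, int max_rows) {
  const int n = X.size();
  long total = 0;
  for (int i = 0; i < n; ++i)
    total += as<NumericMatrix>(X[i]).nrow();
  double keep = std::min(1.0, (double)max_rows / (double)total);
  arma::fmat S;
  long used = 0;
  double acc = 0.0;   // fractional row accumulator for the stride
  for (int i = 0; i < n; ++i) {
    arma::fmat B = arma::conv_to<arma::fmat>::from(as<arma::mat>(X[i]));
    if (S.n_rows == 0) S.zeros(B.n_cols, B.n_cols);
    if (keep >= 1.0) {
      S += B.t() * B;
      used += B.n_rows;
    } else {
      std::vector<arma::uword> rows;
      for (arma::uword r = 0; r < B.n_rows; ++r) {
        acc += keep;
        if (acc >= 1.0) { rows.push_back(r); acc -= 1.0; }
      }
      if (!rows.empty()) {
        arma::uvec idx(rows.size());
        for (size_t k = 0; k < rows.size(); ++k) idx[k] = rows[k];
        arma::fmat Bs = B.rows(idx);
        S += Bs.t() * Bs;
        used += Bs.n_rows;
      }
    }
  }
  return List::create(_["S"] = arma::conv_to<arma::mat>::from(S),
                      _["n"] = (double)used);
}
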
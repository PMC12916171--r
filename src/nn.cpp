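// Hybrid recurrent + convolutional pair classifier: forward pass,
// backpropagation and SGD update, operating on a flat parameter vector.
//
// The network reads a p x q matrix as a length-p sequence of q-dimensional
// steps, passes it through an (optionally bidirectional) recurrent layer
// (simple RNN / GRU / LSTM), treats the sequence output as a single-channel
// 2-D map, applies a stack of valid convolutions with ReLU, one max-pool,
// dropout, and three dense layers ending in a sigmoid unit.  Binary
// cross-entropy gradients are accumulated over a mini-batch.
//
// All parameters live in one numeric vector; nn_layout() publishes the
// (name, nrow, ncol, offset) map used by the R side for initialization.

#include <RcppArmadillo.h>
#include <map>
#include <memory>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace { inline arma::mat relu(const arma::mat& x) {
  arma::mat y(x); y.elem(arma::find(y < 0)).zeros(); return y;
} }

namespace {

struct NetCfg {
  int p, q;                // input rows (time steps) and columns (features)
  int rnn_type;            // 0 none, 1 simple RNN, 2 GRU, 3 LSTM
  bool bidir;
  int h;                   // recurrent units per direction
  std::vector<int> conv;   // filters per convolutional layer
  int k;                   // square kernel size
  int pool;                // max-pool size (applied once after conv stack)
  int d1, d2;              // hidden dense sizes
  double drop1, drop2;     // dropout after feature extractor / before output
};

NetCfg parse_cfg(const Rcpp::List& L) {
  NetCfg c;
  c.p = Rcpp::as<int>(L["p"]);
  c.q = Rcpp::as<int>(L["q"]);
  c.rnn_type = Rcpp::as<int>(L["rnn_type"]);
  c.bidir = Rcpp::as<bool>(L["bidir"]);
  c.h = Rcpp::as<int>(L["h"]);
  c.conv = Rcpp::as<std::vector<int>>(L["conv"]);
  c.k = Rcpp::as<int>(L["kernel"]);
  c.pool = Rcpp::as<int>(L["pool"]);
  c.d1 = Rcpp::as<int>(L["d1"]);
  c.d2 = Rcpp::as<int>(L["d2"]);
  c.drop1 = Rcpp::as<double>(L["drop1"]);
  c.drop2 = Rcpp::as<double>(L["drop2"]);
  return c;
}

int n_gates(int rnn_type) {
  switch (rnn_type) {
    case 1: return 1;
    case 2: return 3;  // update, reset, candidate
    case 3: return 4;  // input, forget, output, cell candidate
    default: return 0;
  }
}

struct ParamSpec {
  std::string name;
  int nrow, ncol;
  arma::uword offset;  // 0-based into the flat vector
};

// Feature-map geometry after the recurrent stage and each conv layer.
// Throws with the offending layer name when a map degenerates.
void map_dims(const NetCfg& c, int& rows, int& cols, int& chans, int& flat) {
  rows = c.p;
  cols = (c.rnn_type > 0) ? (c.bidir ? 2 * c.h : c.h) : c.q;
  chans = 1;
  for (size_t i = 0; i < c.conv.size(); ++i) {
    rows -= (c.k - 1);
    cols -= (c.k - 1);
    if (rows < 1 || cols < 1)
      Rcpp::stop("feature map collapses at conv layer %d (kernel %d too large)",
                 (int)i + 1, c.k);
    chans = c.conv[i];
  }
  if (!c.conv.empty()) {
    rows /= c.pool;
    cols /= c.pool;
    if (rows < 1 || cols < 1)
      Rcpp::stop("feature map collapses at the max-pool layer (pool %d)", c.pool);
  }
  flat = rows * cols * chans;
}

std::vector<ParamSpec> layout(const NetCfg& c) {
  std::vector<ParamSpec> specs;
  arma::uword off = 0;
  auto add = [&](const std::string& nm, int nr, int nc) {
    specs.push_back({nm, nr, nc, off});
    off += (arma::uword)nr * nc;
  };
  const int g = n_gates(c.rnn_type);
  const int ndir = (c.rnn_type > 0) ? (c.bidir ? 2 : 1) : 0;
  for (int d = 0; d < ndir; ++d) {
    std::string tag = "rnn" + std::to_string(d + 1);
    add(tag + "_W", c.q, g * c.h);
    add(tag + "_U", c.h, g * c.h);
    add(tag + "_b", 1, g * c.h);
  }
  int ch = 1;
  for (size_t i = 0; i < c.conv.size(); ++i) {
    std::string tag = "conv" + std::to_string(i + 1);
    add(tag + "_W", c.k * c.k * ch, c.conv[i]);
    add(tag + "_b", 1, c.conv[i]);
    ch = c.conv[i];
  }
  int rows, cols, chans, flat;
  map_dims(c, rows, cols, chans, flat);
  add("dense1_W", flat, c.d1);
  add("dense1_b", 1, c.d1);
  add("dense2_W", c.d1, c.d2);
  add("dense2_b", 1, c.d2);
  add("out_W", c.d2, 1);
  add("out_b", 1, 1);
  return specs;
}

// Non-owning matrix views over a flat buffer.
struct Params {
  std::vector<mat> M;
  std::map<std::string, int> idx;
  Params(double* base, const std::vector<ParamSpec>& specs) {
    M.reserve(specs.size());  // views must never be copied by reallocation
    for (size_t i = 0; i < specs.size(); ++i) {
      M.emplace_back(base + specs[i].offset, specs[i].nrow, specs[i].ncol,
                     false, true);
      idx[specs[i].name] = (int)i;
    }
  }
  mat& operator[](const std::string& nm) { return M[idx.at(nm)]; }
};

inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// ---------------------------------------------------------------------------
// Recurrent layers (one direction).  X is p x q, output H is p x h.
// Caches hold per-step gate activations for backprop through time.

struct RnnCache {
  mat Z, R, C, I, F, O, G, Ct, Hprev, H;  // each p x h (subset used per type)
};

void rnn_forward(const NetCfg& c, const mat& X, mat& W, mat& U, mat& b,
                 mat& H, RnnCache& cc) {
  const int p = X.n_rows, h = c.h;
  mat A = X * W;  // p x g*h, bias added per step below
  A.each_row() += b;
  H.set_size(p, h);
  cc.Hprev.set_size(p, h);
  rowvec hp(h, fill::zeros);
  if (c.rnn_type == 1) {
    for (int t = 0; t < p; ++t) {
      cc.Hprev.row(t) = hp;
      hp = tanh(A.row(t) + hp * U);
      H.row(t) = hp;
    }
  } else if (c.rnn_type == 2) {
    cc.Z.set_size(p, h); cc.R.set_size(p, h); cc.C.set_size(p, h);
    mat Uz = U.cols(0, h - 1), Ur = U.cols(h, 2 * h - 1),
        Uc = U.cols(2 * h, 3 * h - 1);
    for (int t = 0; t < p; ++t) {
      cc.Hprev.row(t) = hp;
      rowvec z = sigmoid(A(t, span(0, h - 1)) + hp * Uz);
      rowvec r = sigmoid(A(t, span(h, 2 * h - 1)) + hp * Ur);
      rowvec cand = tanh(A(t, span(2 * h, 3 * h - 1)) + (r % hp) * Uc);
      hp = (1.0 - z) % hp + z % cand;
      cc.Z.row(t) = z; cc.R.row(t) = r; cc.C.row(t) = cand;
      H.row(t) = hp;
    }
  } else {  // LSTM
    cc.I.set_size(p, h); cc.F.set_size(p, h); cc.O.set_size(p, h);
    cc.G.set_size(p, h); cc.Ct.set_size(p, h);
    rowvec cp(h, fill::zeros);
    for (int t = 0; t < p; ++t) {
      cc.Hprev.row(t) = hp;
      rowvec a = A.row(t) + hp * U;
      rowvec i = sigmoid(a.cols(0, h - 1));
      rowvec f = sigmoid(a.cols(h, 2 * h - 1));
      rowvec o = sigmoid(a.cols(2 * h, 3 * h - 1));
      rowvec g = tanh(a.cols(3 * h, 4 * h - 1));
      cp = f % cp + i % g;
      hp = o % tanh(cp);
      cc.I.row(t) = i; cc.F.row(t) = f; cc.O.row(t) = o; cc.G.row(t) = g;
      cc.Ct.row(t) = cp;  // c_{t-1} is Ct.row(t-1); t = 0 uses zeros
      H.row(t) = hp;
    }
  }
  cc.H = H;
}

void rnn_backward(const NetCfg& c, const mat& X, mat& W, mat& U,
                  const RnnCache& cc, const mat& dH,
                  mat& dW, mat& dU, mat& db) {
  const int p = X.n_rows, h = c.h;
  mat dA(p, n_gates(c.rnn_type) * h, fill::zeros);
  rowvec dh(h, fill::zeros);
  if (c.rnn_type == 1) {
    for (int t = p - 1; t >= 0; --t) {
      dh += dH.row(t);
      rowvec ht = cc.H.row(t);
      rowvec da = dh % (1.0 - ht % ht);
      dA.row(t) = da;
      dU += cc.Hprev.row(t).t() * da;
      dh = da * U.t();
    }
  } else if (c.rnn_type == 2) {
    mat Uz = U.cols(0, h - 1), Ur = U.cols(h, 2 * h - 1),
        Uc = U.cols(2 * h, 3 * h - 1);
    mat dUz(size(Uz), fill::zeros), dUr(size(Ur), fill::zeros),
        dUc(size(Uc), fill::zeros);
    for (int t = p - 1; t >= 0; --t) {
      dh += dH.row(t);
      rowvec z = cc.Z.row(t), r = cc.R.row(t), cand = cc.C.row(t),
             hp = cc.Hprev.row(t);
      rowvec dz = dh % (cand - hp);
      rowvec dcand = dh % z;
      rowvec dhp = dh % (1.0 - z);
      rowvec dac = dcand % (1.0 - cand % cand);
      rowvec drhp = dac * Uc.t();
      rowvec dr = drhp % hp;
      dhp += drhp % r;
      rowvec dar = dr % r % (1.0 - r);
      rowvec daz = dz % z % (1.0 - z);
      dhp += daz * Uz.t() + dar * Ur.t();
      dUz += hp.t() * daz;
      dUr += hp.t() * dar;
      dUc += (r % hp).t() * dac;
      dA(t, span(0, h - 1)) = daz;
      dA(t, span(h, 2 * h - 1)) = dar;
      dA(t, span(2 * h, 3 * h - 1)) = dac;
      dh = dhp;
    }
    dU.cols(0, h - 1) += dUz;
    dU.cols(h, 2 * h - 1) += dUr;
    dU.cols(2 * h, 3 * h - 1) += dUc;
  } else {  // LSTM
    rowvec dc(h, fill::zeros);
    for (int t = p - 1; t >= 0; --t) {
      dh += dH.row(t);
      rowvec i = cc.I.row(t), f = cc.F.row(t), o = cc.O.row(t),
             g = cc.G.row(t), ct = cc.Ct.row(t), hp = cc.Hprev.row(t);
      rowvec cprev = (t > 0) ? rowvec(cc.Ct.row(t - 1))
                             : rowvec(h, fill::zeros);
      rowvec tc = tanh(ct);
      rowvec do_ = dh % tc;
      dc += dh % o % (1.0 - tc % tc);
      rowvec di = dc % g, df = dc % cprev, dg = dc % i;
      rowvec dcprev = dc % f;
      rowvec dai = di % i % (1.0 - i);
      rowvec daf = df % f % (1.0 - f);
      rowvec dao = do_ % o % (1.0 - o);
      rowvec dag = dg % (1.0 - g % g);
      rowvec da = join_rows(join_rows(dai, daf), join_rows(dao, dag));
      dA.row(t) = da;
      dU += hp.t() * da;
      dh = da * U.t();
      dc = dcprev;
    }
  }
  dW += X.t() * dA;
  db += sum(dA, 0);
}

// ---------------------------------------------------------------------------
// Convolution via im2col.  Patch index = i + j * out_rows (column-major).

void im2col(const cube& in, int k, mat& P) {
  const int orow = in.n_rows - k + 1, ocol = in.n_cols - k + 1,
            ch = in.n_slices;
  P.set_size((arma::uword)orow * ocol, (arma::uword)k * k * ch);
  for (int c0 = 0; c0 < ch; ++c0)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const int col = c0 * k * k + kj * k + ki;
        double* dst = P.colptr(col);
        for (int j = 0; j < ocol; ++j) {
          const double* src = in.slice_colptr(c0, j + kj) + ki;
          std::memcpy(dst + (arma::uword)j * orow, src,
                      sizeof(double) * orow);
        }
      }
}

void col2im_add(const mat& dP, int k, cube& dIn) {
  const int orow = dIn.n_rows - k + 1, ocol = dIn.n_cols - k + 1,
            ch = dIn.n_slices;
  for (int c0 = 0; c0 < ch; ++c0)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const int col = c0 * k * k + kj * k + ki;
        const double* src = dP.colptr(col);
        for (int j = 0; j < ocol; ++j) {
          double* dst = dIn.slice_colptr(c0, j + kj) + ki;
          const double* s = src + (arma::uword)j * orow;
          for (int i = 0; i < orow; ++i) dst[i] += s[i];
        }
      }
}

struct ConvCache {
  mat P;        // im2col patches
  mat Zpre;     // pre-activation (npatch x filters)
  cube out;     // relu output as cube
};

struct PoolCache {
  cube out;
  ucube argmax;  // linear index into input slice
};

void maxpool_forward(const cube& in, int s, PoolCache& pc) {
  const int ro = in.n_rows / s, co = in.n_cols / s, ch = in.n_slices;
  pc.out.set_size(ro, co, ch);
  pc.argmax.set_size(ro, co, ch);
  for (int c0 = 0; c0 < ch; ++c0)
    for (int j = 0; j < co; ++j)
      for (int i = 0; i < ro; ++i) {
        double best = -datum::inf;
        arma::uword bidx = 0;
        for (int dj = 0; dj < s; ++dj)
          for (int di = 0; di < s; ++di) {
            const int ii = i * s + di, jj = j * s + dj;
            const double v = in(ii, jj, c0);
            if (v > best) { best = v; bidx = ii + (arma::uword)jj * in.n_rows; }
          }
        pc.out(i, j, c0) = best;
        pc.argmax(i, j, c0) = bidx;
      }
}

void maxpool_backward(const PoolCache& pc, const cube& dOut, cube& dIn) {
  for (arma::uword c0 = 0; c0 < dOut.n_slices; ++c0)
    for (arma::uword j = 0; j < dOut.n_cols; ++j)
      for (arma::uword i = 0; i < dOut.n_rows; ++i)
        dIn.slice(c0)(pc.argmax(i, j, c0)) += dOut(i, j, c0);
}

// Inverted dropout mask using the R RNG (deterministic under set.seed).
rowvec dropout_mask(int n, double rate) {
  rowvec m(n);
  const double keep = 1.0 - rate;
  for (int i = 0; i < n; ++i)
    m(i) = (unif_rand() < keep) ? 1.0 / keep : 0.0;
  return m;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List nn_layout(Rcpp::List cfg) {
  NetCfg c = parse_cfg(cfg);
  std::vector<ParamSpec> specs = layout(c);
  const int n = specs.size();
  Rcpp::CharacterVector name(n);
  Rcpp::IntegerVector nrow(n), ncol(n), offset(n);
  arma::uword total = 0;
  for (int i = 0; i < n; ++i) {
    name[i] = specs[i].name;
    nrow[i] = specs[i].nrow;
    ncol[i] = specs[i].ncol;
    offset[i] = specs[i].offset + 1;  // 1-based for R
    total = specs[i].offset + (arma::uword)specs[i].nrow * specs[i].ncol;
  }
  int rows, cols, chans, flat;
  map_dims(c, rows, cols, chans, flat);
  return Rcpp::List::create(
      Rcpp::Named("name") = name, Rcpp::Named("nrow") = nrow,
      Rcpp::Named("ncol") = ncol, Rcpp::Named("offset") = offset,
      Rcpp::Named("total") = (double)total,
      Rcpp::Named("flat") = flat);
}

// Forward (and optionally backward) pass over a mini-batch.
// X: p x q x B cube; y: labels (ignored unless gradients requested).
// Returns scores, mean BCE loss, and the mean gradient when training.
// [[Rcpp::export]]
Rcpp::List nn_batch(Rcpp::NumericVector theta, Rcpp::List cfg, arma::cube X,
                    Rcpp::NumericVector y, bool training) {
  NetCfg c = parse_cfg(cfg);
  std::vector<ParamSpec> specs = layout(c);
  const arma::uword total =
      specs.back().offset +
      (arma::uword)specs.back().nrow * specs.back().ncol;
  if ((arma::uword)theta.size() != total)
    Rcpp::stop("parameter vector has length %d, expected %d",
               (int)theta.size(), (int)total);
  if ((int)X.n_rows != c.p || (int)X.n_cols != c.q)
    Rcpp::stop("input slices are %dx%d, expected %dx%d", (int)X.n_rows,
               (int)X.n_cols, c.p, c.q);
  Params par(theta.begin(), specs);

  const int B = X.n_slices;
  const int nconv = (int)c.conv.size();
  const int ndir = (c.rnn_type > 0) ? (c.bidir ? 2 : 1) : 0;
  int mrow, mcol, mch, flat;
  map_dims(c, mrow, mcol, mch, flat);

  Rcpp::NumericVector grad;
  std::unique_ptr<Params> gpar;
  if (training) {
    grad = Rcpp::NumericVector(total);  // zero-initialized
    gpar.reset(new Params(grad.begin(), specs));
  }

  Rcpp::NumericVector scores(B);
  double loss = 0.0;
  Rcpp::RNGScope rng;  // dropout masks draw from the R RNG

  for (int s = 0; s < B; ++s) {
    mat Xi(X.slice(s));

    // --- recurrent stage ---
    mat H;  // p x D map fed to the conv stack
    std::vector<RnnCache> rcache(ndir);
    mat Xrev;
    if (c.rnn_type > 0) {
      mat H1;
      rnn_forward(c, Xi, par["rnn1_W"], par["rnn1_U"], par["rnn1_b"], H1,
                  rcache[0]);
      if (c.bidir) {
        Xrev = flipud(Xi);
        mat H2;
        rnn_forward(c, Xrev, par["rnn2_W"], par["rnn2_U"], par["rnn2_b"], H2,
                    rcache[1]);
        H = join_rows(H1, flipud(H2));
      } else {
        H = H1;
      }
    } else {
      H = Xi;
    }

    // --- conv stack ---
    cube cur(H.n_rows, H.n_cols, 1);
    cur.slice(0) = H;
    std::vector<ConvCache> ccache(nconv);
    std::vector<cube> cin(nconv);
    for (int li = 0; li < nconv; ++li) {
      cin[li] = cur;
      im2col(cur, c.k, ccache[li].P);
      mat& W = par["conv" + std::to_string(li + 1) + "_W"];
      mat& b = par["conv" + std::to_string(li + 1) + "_b"];
      ccache[li].Zpre = ccache[li].P * W;
      ccache[li].Zpre.each_row() += b;
      mat A = relu(ccache[li].Zpre);
      const int orow = cur.n_rows - c.k + 1, ocol = cur.n_cols - c.k + 1;
      cube nxt(orow, ocol, c.conv[li]);
      for (int f = 0; f < c.conv[li]; ++f)
        nxt.slice(f) = reshape(A.col(f), orow, ocol);
      ccache[li].out = nxt;
      cur = nxt;
    }

    PoolCache pc;
    if (nconv > 0) {
      maxpool_forward(cur, c.pool, pc);
      cur = pc.out;
    }

    // Flatten in cube memory order (row, column, slice); the backward pass
    // below unpacks dfeat in the same order.
    rowvec feat = vectorise(cur).t();
    rowvec mask1;
    if (training && c.drop1 > 0) {
      mask1 = dropout_mask(flat, c.drop1);
      feat %= mask1;
    }

    // --- dense head ---
    rowvec a1 = feat * par["dense1_W"] + par["dense1_b"];
    rowvec h1 = relu(a1);
    rowvec a2 = h1 * par["dense2_W"] + par["dense2_b"];
    rowvec h2 = relu(a2);
    rowvec mask2;
    rowvec h2d = h2;
    if (training && c.drop2 > 0) {
      mask2 = dropout_mask(c.d2, c.drop2);
      h2d = h2 % mask2;
    }
    double logit = as_scalar(h2d * par["out_W"]) + par["out_b"](0, 0);
    double sc = 1.0 / (1.0 + std::exp(-logit));
    scores[s] = sc;

    const double yi = (s < y.size()) ? y[s] : NA_REAL;
    if (!ISNA(yi)) {
      const double eps = 1e-12;
      loss += -(yi * std::log(sc + eps) + (1.0 - yi) * std::log(1.0 - sc + eps));
    }

    if (!training) continue;

    // --- backward ---
    Params& g = *gpar;
    const double dlogit = (sc - yi) / B;
    g["out_W"] += h2d.t() * dlogit;
    g["out_b"](0, 0) += dlogit;
    rowvec dh2d = dlogit * par["out_W"].t();
    rowvec dh2 = (c.drop2 > 0) ? rowvec(dh2d % mask2) : dh2d;
    rowvec da2 = dh2;
    da2.elem(find(a2 <= 0)).zeros();
    g["dense2_W"] += h1.t() * da2;
    g["dense2_b"] += da2;
    rowvec dh1 = da2 * par["dense2_W"].t();
    rowvec da1 = dh1;
    da1.elem(find(a1 <= 0)).zeros();
    g["dense1_W"] += feat.t() * da1;
    g["dense1_b"] += da1;
    rowvec dfeat = da1 * par["dense1_W"].t();
    if (c.drop1 > 0) dfeat %= mask1;

    cube dcur(mrow, mcol, mch);
    std::memcpy(dcur.memptr(), dfeat.memptr(), sizeof(double) * flat);

    mat dH;
    if (nconv > 0) {
      cube dpool(ccache[nconv - 1].out.n_rows, ccache[nconv - 1].out.n_cols,
                 ccache[nconv - 1].out.n_slices, fill::zeros);
      maxpool_backward(pc, dcur, dpool);
      cube dnext = dpool;
      for (int li = nconv - 1; li >= 0; --li) {
        const int orow = dnext.n_rows, ocol = dnext.n_cols,
                  nf = dnext.n_slices;
        mat dA((arma::uword)orow * ocol, nf);
        for (int f = 0; f < nf; ++f)
          dA.col(f) = vectorise(dnext.slice(f));
        dA.elem(find(ccache[li].Zpre <= 0)).zeros();
        mat& W = par["conv" + std::to_string(li + 1) + "_W"];
        g["conv" + std::to_string(li + 1) + "_W"] += ccache[li].P.t() * dA;
        g["conv" + std::to_string(li + 1) + "_b"] += sum(dA, 0);
        if (li > 0 || c.rnn_type > 0) {
          mat dP = dA * W.t();
          cube dIn(cin[li].n_rows, cin[li].n_cols, cin[li].n_slices,
                   fill::zeros);
          col2im_add(dP, c.k, dIn);
          if (li > 0) {
            dnext = dIn;
          } else {
            dH = dIn.slice(0);
          }
        }
      }
    } else {
      dH = dcur.slice(0);
    }

    if (c.rnn_type > 0 && dH.n_elem > 0) {
      if (c.bidir) {
        mat dH1 = dH.cols(0, c.h - 1);
        mat dH2 = flipud(dH.cols(c.h, 2 * c.h - 1));
        rnn_backward(c, Xi, par["rnn1_W"], par["rnn1_U"], rcache[0], dH1,
                     g["rnn1_W"], g["rnn1_U"], g["rnn1_b"]);
        rnn_backward(c, Xrev, par["rnn2_W"], par["rnn2_U"], rcache[1], dH2,
                     g["rnn2_W"], g["rnn2_U"], g["rnn2_b"]);
      } else {
        rnn_backward(c, Xi, par["rnn1_W"], par["rnn1_U"], rcache[0], dH,
                     g["rnn1_W"], g["rnn1_U"], g["rnn1_b"]);
      }
    }
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("scores") = scores,
      Rcpp::Named("loss") = loss / std::max(B, 1));
  if (training) out["grad"] = grad;
  return out;
}

// In-place SGD with classical momentum: v <- mom*v - lr*g; theta <- theta + v.
// [[Rcpp::export]]
void nn_sgd_step(Rcpp::NumericVector theta, Rcpp::NumericVector velocity,
                 Rcpp::NumericVector grad, double lr, double momentum) {
  const R_xlen_t n = theta.size();
  if (velocity.size() != n || grad.size() != n)
    Rcpp::stop("theta, velocity and grad must have equal length");
  double* t = theta.begin();
  double* v = velocity.begin();
  const double* g = grad.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    v[i] = momentum * v[i] - lr * g[i];
    t[i] += v[i];
  }
}
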
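// Minibatch trainer for small fully convolutional / convolutional
// classifiers on single-channel images. Layers: conv 3x3 ('same' padding,
// bias, ReLU), max-pool 2x2 (floor on odd dims), dropout (inverted),
// global average pooling, flatten, dense. Loss: softmax cross-entropy.
// Optimiser: Adam. All randomness (init, shuffling, dropout) comes from one
// std::mt19937 seeded from R, so runs are reproducible bit-for-bit on a
// fixed BLAS.
//
// Layout: "spatial" activations are (C x HW*B) matrices where sample b
// occupies the HW-column block starting at b*HW and pixel p = r*W+c;
// "vector" activations are (dim x B). Flatten is then a pure reshape
// because Armadillo stores column-major. A 3x3 convolution is computed as
// nine shifted gemms: Out = sum_k W_k * shift_k(A), where shift_k copies
// contiguous row spans, which keeps the inner loops memcpy-bound.

#include <RcppArmadillo.h>
#include <random>
#include <vector>

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::cube;

enum LType { L_CONV, L_POOL, L_DROPOUT, L_GAP, L_FLATTEN, L_DENSE };

struct Layer {
  LType type = L_CONV;
  int filters = 0;      // conv
  int units = 0;        // dense
  double rate = 0.0;    // dropout
  bool relu = true;     // dense only; conv is always ReLU
  int inH = 0, inW = 0, inC = 0, outH = 0, outW = 0, outC = 0;
  int in_dim = 0, out_dim = 0;
  mat W; vec b;
  mat mW, vW; vec mb, vb;    // Adam state
};

static std::vector<Layer> parse_layers(const List& layer_list, int H, int W) {
  std::vector<Layer> layers;
  int curH = H, curW = W, curC = 1;
  bool spatial = true;
  for (int i = 0; i < layer_list.size(); ++i) {
    List ld = layer_list[i];
    std::string type = as<std::string>(ld["type"]);
    Layer L;
    if (type == "conv") {
      if (!spatial) stop("conv layer after a non-spatial layer");
      L.type = L_CONV;
      L.filters = as<int>(ld["filters"]);
      L.inH = curH; L.inW = curW; L.inC = curC;
      L.outH = curH; L.outW = curW; L.outC = L.filters;
      curC = L.filters;
    } else if (type == "maxpool") {
      if (!spatial) stop("maxpool layer after a non-spatial layer");
      L.type = L_POOL;
      L.inH = curH; L.inW = curW; L.inC = curC;
      L.outH = curH / 2; L.outW = curW / 2; L.outC = curC;
      if (L.outH < 1 || L.outW < 1) stop("maxpool would empty the feature map");
      curH = L.outH; curW = L.outW;
    } else if (type == "dropout") {
      L.type = L_DROPOUT;
      L.rate = as<double>(ld["rate"]);
      L.inH = curH; L.inW = curW; L.inC = curC;
      L.outH = curH; L.outW = curW; L.outC = curC;
      L.in_dim = L.out_dim = spatial ? 0 : curC;
    } else if (type == "gap") {
      if (!spatial) stop("gap layer after a non-spatial layer");
      L.type = L_GAP;
      L.inH = curH; L.inW = curW; L.inC = curC;
      L.out_dim = curC;
      spatial = false;
    } else if (type == "flatten") {
      if (!spatial) stop("flatten layer after a non-spatial layer");
      L.type = L_FLATTEN;
      L.inH = curH; L.inW = curW; L.inC = curC;
      L.out_dim = curC * curH * curW;
      spatial = false;
    } else if (type == "dense") {
      if (spatial) stop("dense layer requires gap or flatten first");
      L.type = L_DENSE;
      L.units = as<int>(ld["units"]);
      L.relu = as<std::string>(ld["activation"]) == "relu";
      L.in_dim = curC;
      L.out_dim = L.units;
    } else {
      stop("unknown layer type: " + type);
    }
    layers.push_back(L);
    if (L.type == L_GAP || L.type == L_FLATTEN || L.type == L_DENSE)
      curC = L.out_dim;
  }
  return layers;
}

static void init_weights(std::vector<Layer>& layers, std::mt19937& rng) {
  std::normal_distribution<double> norm(0.0, 1.0);
  for (Layer& L : layers) {
    if (L.type == L_CONV) {
      int fan_in = 9 * L.inC;
      double sd = std::sqrt(2.0 / fan_in);
      L.W.set_size(L.filters, fan_in);
      for (arma::uword j = 0; j < L.W.n_cols; ++j)
        for (arma::uword i = 0; i < L.W.n_rows; ++i)
          L.W(i, j) = sd * norm(rng);
      L.b.zeros(L.filters);
    } else if (L.type == L_DENSE) {
      double sd = std::sqrt(2.0 / L.in_dim);
      L.W.set_size(L.out_dim, L.in_dim);
      for (arma::uword j = 0; j < L.W.n_cols; ++j)
        for (arma::uword i = 0; i < L.W.n_rows; ++i)
          L.W(i, j) = sd * norm(rng);
      L.b.zeros(L.out_dim);
    }
    if (L.type == L_CONV || L.type == L_DENSE) {
      L.mW.zeros(arma::size(L.W)); L.vW.zeros(arma::size(L.W));
      L.mb.zeros(L.b.n_elem);      L.vb.zeros(L.b.n_elem);
    }
  }
}

struct Cache {
  std::vector<mat> A;                         // A[i] = output of layer i
  std::vector<std::vector<mat>> shifts;       // conv: 9 shifted inputs
  std::vector<std::vector<arma::uword>> pidx; // pool argmax (input column)
  std::vector<mat> mask;                      // dropout masks
};

// Copy A shifted by kernel offset (dr, dc) with zero padding; spans of
// consecutive pixel columns are contiguous, so this is memcpy-bound.
static void make_shift(const mat& A, mat& S, int H, int W, int B,
                       int dr, int dc) {
  int C = A.n_rows, HW = H * W;
  S.set_size(C, A.n_cols);  // no-op when already sized; reused across batches
  int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);   // dest col range
  int span = std::max(0, c1 - c0);
  for (int b = 0; b < B; ++b) {
    size_t off = (size_t)b * HW;
    for (int r = 0; r < H; ++r) {
      int rr = r + dr;
      double* row0 = S.colptr(off + (size_t)r * W);
      if (rr < 0 || rr >= H || span == 0) {
        std::fill(row0, row0 + (size_t)C * W, 0.0);
        continue;
      }
      // zero only the padded prefix/suffix, copy the valid span
      if (c0 > 0) std::fill(row0, row0 + (size_t)C * c0, 0.0);
      std::memcpy(row0 + (size_t)C * c0,
                  A.colptr(off + (size_t)rr * W + c0 + dc),
                  sizeof(double) * (size_t)C * span);
      if (c1 < W)
        std::fill(row0 + (size_t)C * c1, row0 + (size_t)C * W, 0.0);
    }
  }
}

// Scatter-add of the shifted gradient back onto the input (adjoint of
// make_shift).
static void add_shift_back(mat& dA, const mat& dS, int H, int W, int B,
                           int dr, int dc) {
  int C = dA.n_rows, HW = H * W;
  int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
  if (c1 <= c0) return;
  int span = c1 - c0;
  for (int b = 0; b < B; ++b) {
    size_t off = (size_t)b * HW;
    for (int r = 0; r < H; ++r) {
      int rr = r + dr;
      if (rr < 0 || rr >= H) continue;
      double* dst = dA.colptr(off + (size_t)rr * W + c0 + dc);
      const double* src = dS.colptr(off + (size_t)r * W + c0);
      for (size_t t = 0; t < (size_t)C * span; ++t) dst[t] += src[t];
    }
  }
}

static mat forward(std::vector<Layer>& layers, const mat& A0, int B,
                   bool training, std::mt19937& rng, Cache& cache) {
  size_t nl = layers.size();
  if (cache.A.size() != nl) {
    cache.A.assign(nl, mat());
    cache.shifts.assign(nl, std::vector<mat>());
    cache.pidx.assign(nl, std::vector<arma::uword>());
    cache.mask.assign(nl, mat());
    for (size_t i = 0; i < nl; ++i)
      if (layers[i].type == L_CONV) cache.shifts[i].assign(9, mat());
  }
  const mat* cur = &A0;
  for (size_t i = 0; i < nl; ++i) {
    Layer& L = layers[i];
    if (L.type == L_CONV) {
      int C = L.inC;
      std::vector<mat>& S = cache.shifts[i];
      mat& Z = cache.A[i];
      Z.set_size(L.filters, cur->n_cols);
      Z.each_col() = L.b;
      for (int k = 0; k < 9; ++k) {
        make_shift(*cur, S[k], L.inH, L.inW, B, k / 3 - 1, k % 3 - 1);
        Z += L.W.cols((size_t)k * C, (size_t)(k + 1) * C - 1) * S[k];
      }
      Z.transform([](double v) { return v > 0.0 ? v : 0.0; });
    } else if (L.type == L_POOL) {
      int iW = L.inW, oH = L.outH, oW = L.outW, C = L.inC;
      int iHW = L.inH * L.inW, oHW = oH * oW;
      mat out(C, (size_t)oHW * B);
      std::vector<arma::uword> pidx((size_t)C * oHW * B);
      const mat& A = *cur;
      for (int b = 0; b < B; ++b) {
        size_t ioff = (size_t)b * iHW, ooff = (size_t)b * oHW;
        for (int r = 0; r < oH; ++r)
          for (int c = 0; c < oW; ++c) {
            size_t q[4] = {ioff + (size_t)(2 * r) * iW + 2 * c,
                           ioff + (size_t)(2 * r) * iW + 2 * c + 1,
                           ioff + (size_t)(2 * r + 1) * iW + 2 * c,
                           ioff + (size_t)(2 * r + 1) * iW + 2 * c + 1};
            size_t ocol = ooff + (size_t)(r * oW + c);
            const double* s0 = A.colptr(q[0]);
            const double* s1 = A.colptr(q[1]);
            const double* s2 = A.colptr(q[2]);
            const double* s3 = A.colptr(q[3]);
            double* dst = out.colptr(ocol);
            arma::uword* pix = &pidx[(size_t)C * ocol];
            for (int ch = 0; ch < C; ++ch) {
              double best = s0[ch]; size_t bq = q[0];
              if (s1[ch] > best) { best = s1[ch]; bq = q[1]; }
              if (s2[ch] > best) { best = s2[ch]; bq = q[2]; }
              if (s3[ch] > best) { best = s3[ch]; bq = q[3]; }
              dst[ch] = best; pix[ch] = bq;
            }
          }
      }
      cache.pidx[i] = std::move(pidx);
      cache.A[i] = std::move(out);
    } else if (L.type == L_DROPOUT) {
      mat out = *cur;
      if (training && L.rate > 0.0) {
        std::bernoulli_distribution keep(1.0 - L.rate);
        mat msk(arma::size(out));
        double scale = 1.0 / (1.0 - L.rate);
        for (arma::uword j = 0; j < msk.n_cols; ++j)
          for (arma::uword r = 0; r < msk.n_rows; ++r)
            msk(r, j) = keep(rng) ? scale : 0.0;
        out %= msk;
        cache.mask[i] = std::move(msk);
      }
      cache.A[i] = std::move(out);
    } else if (L.type == L_GAP) {
      int HW = L.inH * L.inW, C = L.inC;
      mat out(C, B);
      for (int b = 0; b < B; ++b)
        out.col(b) = arma::mean(
          cur->cols((size_t)b * HW, (size_t)(b + 1) * HW - 1), 1);
      cache.A[i] = std::move(out);
    } else if (L.type == L_FLATTEN) {
      mat out = *cur;
      out.reshape(L.out_dim, B);
      cache.A[i] = std::move(out);
    } else { // dense
      mat Z = L.W * (*cur);
      Z.each_col() += L.b;
      if (L.relu) Z.transform([](double v) { return v > 0.0 ? v : 0.0; });
      cache.A[i] = std::move(Z);
    }
    cur = &cache.A[i];
  }
  return cache.A[nl - 1];
}

// dLogits: (K x B) gradient of mean loss wrt final layer output.
static void backward(std::vector<Layer>& layers, const mat& A0, int B,
                     Cache& cache, const mat& dLogits,
                     std::vector<mat>& gW, std::vector<vec>& gb) {
  mat dA = dLogits;
  for (int i = (int)layers.size() - 1; i >= 0; --i) {
    Layer& L = layers[i];
    const mat& Ain = (i == 0) ? A0 : cache.A[i - 1];
    const mat& Aout = cache.A[i];
    if (L.type == L_CONV) {
      int C = L.inC;
      mat dZ = dA % (Aout > 0.0);
      gW[i].set_size(arma::size(L.W));
      gb[i] = arma::sum(dZ, 1);
      bool need_dAin = i > 0;  // no gradient wrt the input image itself
      mat dAin;
      if (need_dAin) dAin.zeros(C, Ain.n_cols);
      mat dS;
      for (int k = 0; k < 9; ++k) {
        gW[i].cols((size_t)k * C, (size_t)(k + 1) * C - 1) =
          dZ * cache.shifts[i][k].t();
        if (need_dAin) {
          dS = L.W.cols((size_t)k * C, (size_t)(k + 1) * C - 1).t() * dZ;
          add_shift_back(dAin, dS, L.inH, L.inW, B, k / 3 - 1, k % 3 - 1);
        }
      }
      dA = std::move(dAin);
    } else if (L.type == L_POOL) {
      int iHW = L.inH * L.inW, oHW = L.outH * L.outW;
      int C = L.inC;
      mat dAin(C, (size_t)iHW * B, arma::fill::zeros);
      const std::vector<arma::uword>& pidx = cache.pidx[i];
      for (size_t ocol = 0; ocol < (size_t)oHW * B; ++ocol) {
        const double* src = dA.colptr(ocol);
        const arma::uword* pix = &pidx[(size_t)C * ocol];
        for (int ch = 0; ch < C; ++ch)
          dAin(ch, pix[ch]) += src[ch];
      }
      dA = std::move(dAin);
    } else if (L.type == L_DROPOUT) {
      if (cache.mask[i].n_elem > 0) dA %= cache.mask[i];
    } else if (L.type == L_GAP) {
      int HW = L.inH * L.inW, C = L.inC;
      mat dAin(C, (size_t)HW * B);
      for (int b = 0; b < B; ++b) {
        vec g = dA.col(b) / (double)HW;
        dAin.cols((size_t)b * HW, (size_t)(b + 1) * HW - 1).each_col() = g;
      }
      dA = std::move(dAin);
    } else if (L.type == L_FLATTEN) {
      dA.reshape(L.inC, (size_t)(L.inH * L.inW) * B);
    } else { // dense
      mat dZ = L.relu ? mat(dA % (Aout > 0.0)) : dA;
      gW[i] = dZ * Ain.t();
      gb[i] = arma::sum(dZ, 1);
      dA = L.W.t() * dZ;
    }
  }
}

// Gather input slab into the spatial layout (1 x HW*B).
static mat input_slab(const cube& X, const std::vector<int>& idx,
                      int from, int to) {
  int H = X.n_rows, W = X.n_cols, HW = H * W, B = to - from;
  mat A0(1, (size_t)HW * B);
  for (int b = 0; b < B; ++b) {
    const mat& sl = X.slice(idx[from + b]);
    double* dst = A0.memptr() + (size_t)b * HW;
    for (int r = 0; r < H; ++r)
      for (int c = 0; c < W; ++c)
        dst[r * W + c] = sl(r, c);
  }
  return A0;
}

static double softmax_xent(const mat& logits, const arma::ivec& y,
                           mat& dLogits, int& correct) {
  int K = logits.n_rows, B = logits.n_cols;
  dLogits.set_size(K, B);
  double loss = 0.0;
  correct = 0;
  for (int b = 0; b < B; ++b) {
    vec z = logits.col(b);
    double m = z.max();
    vec e = arma::exp(z - m);
    vec p = e / arma::accu(e);
    int yb = (int)y[b];
    loss += -std::log(std::max(p[yb], 1e-300));
    int am = 0; double best = p[0];
    for (int k = 1; k < K; ++k) if (p[k] > best) { best = p[k]; am = k; }
    if (am == yb) ++correct;
    p[yb] -= 1.0;
    dLogits.col(b) = p / (double)B;
  }
  return loss / B;
}

static void adam_step(std::vector<Layer>& layers, std::vector<mat>& gW,
                      std::vector<vec>& gb, double lr, double b1, double b2,
                      double eps, long t) {
  double c1 = 1.0 - std::pow(b1, (double)t);
  double c2 = 1.0 - std::pow(b2, (double)t);
  for (size_t i = 0; i < layers.size(); ++i) {
    Layer& L = layers[i];
    if (L.type != L_CONV && L.type != L_DENSE) continue;
    L.mW = b1 * L.mW + (1 - b1) * gW[i];
    L.vW = b2 * L.vW + (1 - b2) * arma::square(gW[i]);
    L.W -= lr * (L.mW / c1) / (arma::sqrt(L.vW / c2) + eps);
    L.mb = b1 * L.mb + (1 - b1) * gb[i];
    L.vb = b2 * L.vb + (1 - b2) * arma::square(gb[i]);
    L.b -= lr * (L.mb / c1) / (arma::sqrt(L.vb / c2) + eps);
  }
}

static List get_weights(const std::vector<Layer>& layers) {
  List out;
  for (const Layer& L : layers) {
    if (L.type == L_CONV || L.type == L_DENSE)
      out.push_back(List::create(_["W"] = L.W, _["b"] = L.b));
  }
  return out;
}

static void set_weights(std::vector<Layer>& layers, const List& weights) {
  int j = 0;
  for (Layer& L : layers) {
    if (L.type == L_CONV || L.type == L_DENSE) {
      if (j >= weights.size())
        stop("weight list too short for this architecture");
      List wl = weights[j++];
      mat W = as<mat>(wl["W"]);
      vec b = as<vec>(wl["b"]);
      if (W.n_rows != L.W.n_rows || W.n_cols != L.W.n_cols ||
          b.n_elem != L.b.n_elem)
        stop("weight shape mismatch between model and architecture");
      L.W = W; L.b = b;
    }
  }
  if (j != weights.size()) stop("weight list longer than this architecture");
}

// Mean loss and accuracy on an index set (no dropout).
static void evaluate_set(std::vector<Layer>& layers, const cube& X,
                         const arma::ivec& y, const std::vector<int>& idx,
                         std::mt19937& rng, double& loss, double& acc) {
  int n = idx.size();
  double tot = 0.0; int corr = 0;
  Cache cache;
  for (int from = 0; from < n; from += 128) {
    int to = std::min(n, from + 128);
    int B = to - from;
    mat A0 = input_slab(X, idx, from, to);
    mat logits = forward(layers, A0, B, false, rng, cache);
    arma::ivec yb(B);
    for (int b = 0; b < B; ++b) yb[b] = y[idx[from + b]];
    mat dL; int c;
    tot += softmax_xent(logits, yb, dL, c) * B;
    corr += c;
  }
  loss = tot / n;
  acc = (double)corr / n;
}

// [[Rcpp::export]]
List fcn_train_cpp(const arma::cube& X, const arma::ivec& y,
                   const List& layer_list, const List& cfg) {
  int n = X.n_slices;
  if ((int)y.n_elem != n) stop("length(labels) must equal number of images");
  double lr = as<double>(cfg["learning_rate"]);
  int batch = as<int>(cfg["batch_size"]);
  int epochs = as<int>(cfg["max_epochs"]);
  int patience = as<int>(cfg["patience"]);
  double val_frac = as<double>(cfg["validation_fraction"]);
  unsigned seed = (unsigned)as<int>(cfg["seed"]);
  bool verbose = as<bool>(cfg["verbose"]);

  std::mt19937 rng(seed);
  std::vector<Layer> layers = parse_layers(layer_list, X.n_rows, X.n_cols);
  init_weights(layers, rng);

  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;
  std::shuffle(perm.begin(), perm.end(), rng);
  int n_val = (int)std::floor(val_frac * n);
  bool use_val = n_val >= 1 && patience >= 0;
  std::vector<int> val_idx(perm.end() - (use_val ? n_val : 0), perm.end());
  std::vector<int> tr_idx(perm.begin(), perm.end() - (use_val ? n_val : 0));
  int n_tr = tr_idx.size();
  if (n_tr < 1) stop("no training samples left after validation split");

  std::vector<mat> gW(layers.size());
  std::vector<vec> gb(layers.size());
  Cache cache;
  long t = 0;
  double best_val = R_PosInf;
  int wait = 0;
  List best_weights = get_weights(layers);
  bool have_best = false;

  std::vector<double> h_tl, h_ta, h_vl, h_va;
  int epochs_run = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(tr_idx.begin(), tr_idx.end(), rng);
    double ep_loss = 0.0; int ep_corr = 0;
    for (int from = 0; from < n_tr; from += batch) {
      int to = std::min(n_tr, from + batch);
      int B = to - from;
      mat A0 = input_slab(X, tr_idx, from, to);
      mat logits = forward(layers, A0, B, true, rng, cache);
      arma::ivec yb(B);
      for (int b = 0; b < B; ++b) yb[b] = y[tr_idx[from + b]];
      mat dLogits; int corr;
      double l = softmax_xent(logits, yb, dLogits, corr);
      ep_loss += l * B; ep_corr += corr;
      backward(layers, A0, B, cache, dLogits, gW, gb);
      adam_step(layers, gW, gb, lr, 0.9, 0.999, 1e-8, ++t);
    }
    ++epochs_run;
    h_tl.push_back(ep_loss / n_tr);
    h_ta.push_back((double)ep_corr / n_tr);
    double vl = NA_REAL, va = NA_REAL;
    if (use_val) {
      evaluate_set(layers, X, y, val_idx, rng, vl, va);
      if (vl < best_val - 1e-9) {
        best_val = vl; wait = 0;
        best_weights = get_weights(layers);
        have_best = true;
      } else if (++wait > patience) {
        h_vl.push_back(vl); h_va.push_back(va);
        break;
      }
    }
    h_vl.push_back(vl); h_va.push_back(va);
    if (verbose)
      Rcout << "epoch " << (ep + 1) << " loss " << h_tl.back()
            << " acc " << h_ta.back() << " val_loss " << vl << "\n";
    Rcpp::checkUserInterrupt();
  }
  if (have_best) set_weights(layers, best_weights);

  return List::create(
    _["weights"] = get_weights(layers),
    _["epochs_run"] = epochs_run,
    _["history"] = DataFrame::create(
      _["epoch"] = seq_len(epochs_run),
      _["train_loss"] = h_tl, _["train_acc"] = h_ta,
      _["val_loss"] = h_vl, _["val_acc"] = h_va));
}

// [[Rcpp::export]]
arma::mat fcn_predict_cpp(const arma::cube& X, const List& layer_list,
                          const List& weights) {
  int n = X.n_slices;
  std::mt19937 rng(0); // unused: no dropout at inference
  std::vector<Layer> layers = parse_layers(layer_list, X.n_rows, X.n_cols);
  init_weights(layers, rng);
  set_weights(layers, weights);
  const Layer& last = layers.back();
  int K = last.out_dim > 0 ? last.out_dim : last.outC;
  mat out(n, K);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  Cache cache;
  for (int from = 0; from < n; from += 128) {
    int to = std::min(n, from + 128);
    int B = to - from;
    mat A0 = input_slab(X, idx, from, to);
    mat logits = forward(layers, A0, B, false, rng, cache);
    for (int b = 0; b < B; ++b) {
      vec z = logits.col(b);
      double m = z.max();
      vec e = arma::exp(z - m);
      out.row(from + b) = (e / arma::accu(e)).t();
    }
  }
  return out;
}

// [[Rcpp::export]]
int fcn_weight_count_cpp(const List& layer_list, int H, int W) {
  std::vector<Layer> layers = parse_layers(layer_list, H, W);
  std::mt19937 rng(0);
  init_weights(layers, rng);
  long total = 0;
  for (const Layer& L : layers)
    if (L.type == L_CONV || L.type == L_DENSE)
      total += (long)L.W.n_elem + (long)L.b.n_elem;
  return (int)total;
}
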
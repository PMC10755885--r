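// Compact seeded 1D-CNN training engine.
//
// Layer layout convention: an activation tensor for a minibatch of B
// sequences of length L with C channels is stored as an arma::mat with C
// rows and L*B columns; columns [s*L, (s+1)*L) belong to sample s.  All
// arithmetic is double precision.  Randomness (weight init, shuffling,
// dropout) flows from one 64-bit Mersenne Twister per call so results are
// reproducible for a fixed seed.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// ---------------------------------------------------------------------------
// RNG: mt19937_64 with hand-rolled uniform/normal so the stream does not
// depend on the standard library's distribution implementations.
struct Rng {
  std::mt19937_64 gen;
  explicit Rng(uint64_t seed) : gen(seed) {}
  double unif() {  // in [0, 1)
    return (gen() >> 11) * (1.0 / 9007199254740992.0);
  }
  double normal() {
    double u1 = unif(), u2 = unif();
    while (u1 <= 0.0) u1 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
  // Fisher-Yates
  void shuffle(std::vector<arma::uword>& idx) {
    for (arma::uword i = idx.size(); i > 1; --i) {
      arma::uword j = static_cast<arma::uword>(unif() * i);
      if (j >= i) j = i - 1;
      std::swap(idx[i - 1], idx[j]);
    }
  }
};

enum LayerKind { CONV, BNORM, DROPOUT, MAXPOOL, FLATTEN, DENSE };
enum Act { RELU = 0, SIGMOID = 1, TANH = 2 };

struct Layer {
  LayerKind kind;
  int filters = 0;   // conv
  int kernel = 0;    // conv
  int act = RELU;    // conv activation code
  double rate = 0.0; // dropout
  int pool = 0;      // max_pool
  int units = 0;     // dense
};

const double BN_EPS = 1e-3;
const double BN_MOMENTUM = 0.9;  // short window keeps inference stats close
                                 // to the current weights on small datasets
const double ADAM_B1 = 0.9;
const double ADAM_B2 = 0.999;
const double ADAM_EPS = 1e-7;

std::vector<Layer> parse_layers(const List& layers) {
  std::vector<Layer> out;
  for (R_xlen_t i = 0; i < layers.size(); ++i) {
    List li = layers[i];
    std::string kind = as<std::string>(li["kind"]);
    Layer L;
    if (kind == "conv") {
      L.kind = CONV;
      L.filters = as<int>(li["filters"]);
      L.kernel = as<int>(li["kernel"]);
      L.act = as<int>(li["activation"]);
    } else if (kind == "batch_norm") {
      L.kind = BNORM;
    } else if (kind == "dropout") {
      L.kind = DROPOUT;
      L.rate = as<double>(li["rate"]);
    } else if (kind == "max_pool") {
      L.kind = MAXPOOL;
      L.pool = as<int>(li["pool"]);
    } else if (kind == "flatten") {
      L.kind = FLATTEN;
    } else if (kind == "dense") {
      L.kind = DENSE;
      L.units = as<int>(li["units"]);
    } else {
      stop("unknown layer kind: " + kind);
    }
    out.push_back(L);
  }
  return out;
}

void apply_act(arma::mat& z, int act) {
  switch (act) {
    case RELU:    z.for_each([](double& v) { if (v < 0) v = 0; }); break;
    case SIGMOID: z.for_each([](double& v) { v = 1.0 / (1.0 + std::exp(-v)); }); break;
    case TANH:    z.for_each([](double& v) { v = std::tanh(v); }); break;
    default: stop("unknown activation code");
  }
}

// derivative wrt pre-activation, expressed through the activation output `a`
arma::mat act_grad(const arma::mat& a, const arma::mat& d, int act) {
  switch (act) {
    case RELU:    return d % arma::conv_to<arma::mat>::from(a > 0);
    case SIGMOID: return d % a % (1.0 - a);
    case TANH:    return d % (1.0 - arma::square(a));
    default: stop("unknown activation code");
  }
}

// im2col for same-padded 1D convolution on the (C, L*B) layout
arma::mat im2col(const arma::mat& A, int L, int B, int k) {
  const int C = A.n_rows;
  const int pad = (k - 1) / 2;
  arma::mat col(C * k, A.n_cols, arma::fill::zeros);
  for (int s = 0; s < B; ++s) {
    const int base = s * L;
    for (int j = 0; j < k; ++j) {
      const int off = j - pad;
      const int p0 = std::max(0, -off);
      const int p1 = L - 1 - std::max(0, off);
      if (p0 > p1) continue;
      col.submat(j * C, base + p0, (j + 1) * C - 1, base + p1) =
          A.cols(base + p0 + off, base + p1 + off);
    }
  }
  return col;
}

// scatter the im2col gradient back onto the input layout
arma::mat col2im(const arma::mat& dcol, int C, int L, int B, int k) {
  const int pad = (k - 1) / 2;
  arma::mat dA(C, L * B, arma::fill::zeros);
  for (int s = 0; s < B; ++s) {
    const int base = s * L;
    for (int j = 0; j < k; ++j) {
      const int off = j - pad;
      const int p0 = std::max(0, -off);
      const int p1 = L - 1 - std::max(0, off);
      if (p0 > p1) continue;
      dA.cols(base + p0 + off, base + p1 + off) +=
          dcol.submat(j * C, base + p0, (j + 1) * C - 1, base + p1);
    }
  }
  return dA;
}

// Per-layer forward cache for backprop
struct Cache {
  arma::mat in;      // layer input (as laid out)
  arma::mat out;     // layer output
  arma::mat col;     // conv: im2col of input
  arma::mat xhat;    // bnorm
  arma::rowvec dummy;
  arma::vec mu, var; // bnorm batch stats
  arma::mat mask;    // dropout
  arma::umat argmax; // max_pool source column per output cell
  int L_in = 0, L_out = 0, B = 0;
};

struct Weights {
  // parallel to layers; empty matrices where a layer has no parameters
  std::vector<arma::mat> W;   // conv/dense weight
  std::vector<arma::vec> b;   // conv/dense bias
  std::vector<arma::vec> gamma, beta, rmean, rvar; // bnorm
};

Weights init_weights(const std::vector<Layer>& layers, int input_len, Rng& rng) {
  Weights w;
  const size_t n = layers.size();
  w.W.resize(n); w.b.resize(n);
  w.gamma.resize(n); w.beta.resize(n); w.rmean.resize(n); w.rvar.resize(n);
  int C = 1, L = input_len;
  int flat = 0;
  for (size_t i = 0; i < n; ++i) {
    const Layer& ly = layers[i];
    switch (ly.kind) {
      case CONV: {
        const int fan_in = C * ly.kernel, fan_out = ly.filters * ly.kernel;
        const double lim = std::sqrt(6.0 / (fan_in + fan_out));
        arma::mat W(ly.filters, C * ly.kernel);
        W.for_each([&](double& v) { v = (2.0 * rng.unif() - 1.0) * lim; });
        w.W[i] = W;
        w.b[i] = arma::vec(ly.filters, arma::fill::zeros);
        C = ly.filters;
        break;
      }
      case BNORM:
        w.gamma[i] = arma::vec(C, arma::fill::ones);
        w.beta[i] = arma::vec(C, arma::fill::zeros);
        w.rmean[i] = arma::vec(C, arma::fill::zeros);
        w.rvar[i] = arma::vec(C, arma::fill::ones);
        break;
      case DROPOUT:
        break;
      case MAXPOOL:
        L = (L + ly.pool - 1) / ly.pool;
        if (L < 1) stop("sequence length collapsed to zero during pooling");
        break;
      case FLATTEN:
        flat = C * L;
        break;
      case DENSE: {
        const int fan_in = flat, fan_out = ly.units;
        const double lim = std::sqrt(6.0 / (fan_in + fan_out));
        arma::mat W(ly.units, flat);
        W.for_each([&](double& v) { v = (2.0 * rng.unif() - 1.0) * lim; });
        w.W[i] = W;
        w.b[i] = arma::vec(ly.units, arma::fill::zeros);
        break;
      }
    }
  }
  return w;
}

List weights_to_list(const Weights& w) {
  const size_t n = w.W.size();
  List out(n);
  for (size_t i = 0; i < n; ++i) {
    if (w.W[i].n_elem > 0) {
      out[i] = List::create(_["W"] = w.W[i], _["b"] = w.b[i]);
    } else if (w.gamma[i].n_elem > 0) {
      out[i] = List::create(_["gamma"] = w.gamma[i], _["beta"] = w.beta[i],
                            _["running_mean"] = w.rmean[i],
                            _["running_var"] = w.rvar[i]);
    } else {
      out[i] = List::create();
    }
  }
  return out;
}

Weights weights_from_list(const List& lst, const std::vector<Layer>& layers) {
  Weights w;
  const size_t n = layers.size();
  if (static_cast<size_t>(lst.size()) != n) stop("weights/layers length mismatch");
  w.W.resize(n); w.b.resize(n);
  w.gamma.resize(n); w.beta.resize(n); w.rmean.resize(n); w.rvar.resize(n);
  for (size_t i = 0; i < n; ++i) {
    List li = lst[i];
    if (layers[i].kind == CONV || layers[i].kind == DENSE) {
      w.W[i] = as<arma::mat>(li["W"]);
      w.b[i] = as<arma::vec>(li["b"]);
    } else if (layers[i].kind == BNORM) {
      w.gamma[i] = as<arma::vec>(li["gamma"]);
      w.beta[i] = as<arma::vec>(li["beta"]);
      w.rmean[i] = as<arma::vec>(li["running_mean"]);
      w.rvar[i] = as<arma::vec>(li["running_var"]);
    }
  }
  return w;
}

// Forward pass.  `training` enables batch statistics, dropout and caching.
// Returns the final (units, B) probability matrix.
arma::mat forward(const std::vector<Layer>& layers, Weights& w,
                  const arma::mat& X, int L0, int B, bool training,
                  std::vector<Cache>* caches, Rng* rng,
                  std::vector<std::pair<int,int>>* shapes) {
  arma::mat A = X;  // (1, L0*B)
  int L = L0;
  for (size_t i = 0; i < layers.size(); ++i) {
    const Layer& ly = layers[i];
    Cache cc;
    cc.L_in = L; cc.B = B;
    if (training) cc.in = A;
    switch (ly.kind) {
      case CONV: {
        arma::mat col = im2col(A, L, B, ly.kernel);
        arma::mat Z = w.W[i] * col;
        Z.each_col() += w.b[i];
        apply_act(Z, ly.act);
        if (training) { cc.col = std::move(col); }
        A = std::move(Z);
        break;
      }
      case BNORM: {
        if (training) {
          arma::vec mu = arma::mean(A, 1);
          arma::mat cen = A.each_col() - mu;
          arma::vec var = arma::mean(arma::square(cen), 1);
          arma::vec isd = 1.0 / arma::sqrt(var + BN_EPS);
          arma::mat xhat = cen.each_col() % isd;
          w.rmean[i] = BN_MOMENTUM * w.rmean[i] + (1 - BN_MOMENTUM) * mu;
          w.rvar[i] = BN_MOMENTUM * w.rvar[i] + (1 - BN_MOMENTUM) * var;
          arma::mat out = xhat.each_col() % w.gamma[i];
          out.each_col() += w.beta[i];
          cc.xhat = std::move(xhat); cc.mu = mu; cc.var = var;
          A = std::move(out);
        } else {
          arma::vec isd = 1.0 / arma::sqrt(w.rvar[i] + BN_EPS);
          arma::mat out = A.each_col() - w.rmean[i];
          out.each_col() %= (w.gamma[i] % isd);
          out.each_col() += w.beta[i];
          A = std::move(out);
        }
        break;
      }
      case DROPOUT: {
        if (training && ly.rate > 0) {
          arma::mat mask(A.n_rows, A.n_cols);
          const double keep = 1.0 - ly.rate;
          mask.for_each([&](double& v) { v = (rng->unif() >= ly.rate) ? 1.0 / keep : 0.0; });
          A %= mask;
          cc.mask = std::move(mask);
        }
        break;
      }
      case MAXPOOL: {
        const int m = ly.pool;
        const int Lo = (L + m - 1) / m;
        const int C = A.n_rows;
        arma::mat out(C, Lo * B);
        arma::umat amax(C, Lo * B);
        for (int s = 0; s < B; ++s) {
          const int ibase = s * L, obase = s * Lo;
          for (int p = 0; p < Lo; ++p) {
            const int c0 = ibase + p * m;
            const int c1 = std::min(ibase + (p + 1) * m, ibase + L) - 1;
            for (int c = 0; c < C; ++c) {
              double best = A(c, c0); int barg = c0;
              for (int q = c0 + 1; q <= c1; ++q)
                if (A(c, q) > best) { best = A(c, q); barg = q; }
              out(c, obase + p) = best;
              amax(c, obase + p) = barg;
            }
          }
        }
        if (training) cc.argmax = std::move(amax);
        A = std::move(out);
        L = Lo;
        break;
      }
      case FLATTEN: {
        const int C = A.n_rows;
        arma::mat out(C * L, B);
        for (int s = 0; s < B; ++s)
          out.col(s) = arma::vectorise(A.cols(s * L, (s + 1) * L - 1));
        A = std::move(out);
        break;
      }
      case DENSE: {
        arma::mat Z = w.W[i] * A;
        Z.each_col() += w.b[i];
        // softmax per column
        for (arma::uword cidx = 0; cidx < Z.n_cols; ++cidx) {
          arma::vec z = Z.col(cidx);
          z -= z.max();
          z = arma::exp(z);
          Z.col(cidx) = z / arma::accu(z);
        }
        A = std::move(Z);
        break;
      }
    }
    cc.L_out = L;
    if (training) cc.out = A;
    if (caches) (*caches)[i] = std::move(cc);
    if (shapes) {
      if (ly.kind == FLATTEN || ly.kind == DENSE)
        shapes->push_back({static_cast<int>(A.n_rows), -1});
      else
        shapes->push_back({L, static_cast<int>(A.n_rows)});
    }
  }
  return A;
}

struct Grads {
  std::vector<arma::mat> W;
  std::vector<arma::vec> b, gamma, beta;
};

// Backward pass from softmax-cross-entropy given probabilities P and labels.
Grads backward(const std::vector<Layer>& layers, const Weights& w,
               const std::vector<Cache>& caches, const arma::mat& P,
               const arma::ivec& y) {
  const size_t n = layers.size();
  Grads g;
  g.W.resize(n); g.b.resize(n); g.gamma.resize(n); g.beta.resize(n);
  const int B = P.n_cols;
  arma::mat d = P;  // dL/dZ for the softmax+CE head
  for (int s = 0; s < B; ++s) d(y[s], s) -= 1.0;
  d /= static_cast<double>(B);
  for (int ii = static_cast<int>(n) - 1; ii >= 0; --ii) {
    const Layer& ly = layers[ii];
    const Cache& cc = caches[ii];
    switch (ly.kind) {
      case DENSE: {
        g.W[ii] = d * cc.in.t();
        g.b[ii] = arma::sum(d, 1);
        d = w.W[ii].t() * d;
        break;
      }
      case FLATTEN: {
        const int C = cc.in.n_rows;
        const int L = cc.L_in;
        arma::mat dd(C, L * cc.B);
        for (int s = 0; s < cc.B; ++s)
          dd.cols(s * L, (s + 1) * L - 1) = arma::reshape(d.col(s), C, L);
        d = std::move(dd);
        break;
      }
      case MAXPOOL: {
        const int C = cc.in.n_rows;
        arma::mat dd(C, cc.in.n_cols, arma::fill::zeros);
        for (arma::uword j = 0; j < d.n_cols; ++j)
          for (int c = 0; c < C; ++c)
            dd(c, cc.argmax(c, j)) += d(c, j);
        d = std::move(dd);
        break;
      }
      case DROPOUT: {
        if (ly.rate > 0) d %= cc.mask;
        break;
      }
      case BNORM: {
        const double N = static_cast<double>(d.n_cols);
        g.gamma[ii] = arma::sum(d % cc.xhat, 1);
        g.beta[ii] = arma::sum(d, 1);
        arma::vec isd = 1.0 / arma::sqrt(cc.var + BN_EPS);
        arma::vec m1 = arma::sum(d, 1) / N;
        arma::vec m2 = arma::sum(d % cc.xhat, 1) / N;
        arma::mat dd = d;
        dd.each_col() -= m1;
        dd -= cc.xhat.each_col() % m2;
        dd.each_col() %= (w.gamma[ii] % isd);
        d = std::move(dd);
        break;
      }
      case CONV: {
        arma::mat dz = act_grad(cc.out, d, ly.act);
        g.W[ii] = dz * cc.col.t();
        g.b[ii] = arma::sum(dz, 1);
        if (ii > 0) {  // no need to propagate into the input signal
          arma::mat dcol = w.W[ii].t() * dz;
          d = col2im(dcol, cc.in.n_rows, cc.L_in, cc.B, ly.kernel);
        }
        break;
      }
    }
  }
  return g;
}

struct Adam {
  std::vector<arma::mat> mW, vW;
  std::vector<arma::vec> mb, vb, mg, vg, mB, vB;
  long step = 0;
  explicit Adam(const Weights& w) {
    const size_t n = w.W.size();
    mW.resize(n); vW.resize(n); mb.resize(n); vb.resize(n);
    mg.resize(n); vg.resize(n); mB.resize(n); vB.resize(n);
    for (size_t i = 0; i < n; ++i) {
      if (w.W[i].n_elem) {
        mW[i] = arma::mat(arma::size(w.W[i]), arma::fill::zeros);
        vW[i] = arma::mat(arma::size(w.W[i]), arma::fill::zeros);
        mb[i] = arma::vec(arma::size(w.b[i]), arma::fill::zeros);
        vb[i] = arma::vec(arma::size(w.b[i]), arma::fill::zeros);
      }
      if (w.gamma[i].n_elem) {
        mg[i] = arma::vec(arma::size(w.gamma[i]), arma::fill::zeros);
        vg[i] = arma::vec(arma::size(w.gamma[i]), arma::fill::zeros);
        mB[i] = arma::vec(arma::size(w.beta[i]), arma::fill::zeros);
        vB[i] = arma::vec(arma::size(w.beta[i]), arma::fill::zeros);
      }
    }
  }
  template <typename M>
  void upd(M& p, M& m, M& v, const M& grad, double lr) {
    m = ADAM_B1 * m + (1 - ADAM_B1) * grad;
    v = ADAM_B2 * v + (1 - ADAM_B2) * (grad % grad);
    const double bc1 = 1 - std::pow(ADAM_B1, step);
    const double bc2 = 1 - std::pow(ADAM_B2, step);
    p -= lr * (m / bc1) / (arma::sqrt(v / bc2) + ADAM_EPS);
  }
  void apply(Weights& w, const Grads& g, double lr) {
    ++step;
    for (size_t i = 0; i < w.W.size(); ++i) {
      if (w.W[i].n_elem) {
        upd(w.W[i], mW[i], vW[i], g.W[i], lr);
        upd(w.b[i], mb[i], vb[i], g.b[i], lr);
      }
      if (w.gamma[i].n_elem) {
        upd(w.gamma[i], mg[i], vg[i], g.gamma[i], lr);
        upd(w.beta[i], mB[i], vB[i], g.beta[i], lr);
      }
    }
  }
};

// Pack a subset of rows of the n x L input matrix into the (1, L*B) layout.
arma::mat pack_rows(const arma::mat& X, const std::vector<arma::uword>& idx,
                    arma::uword from, arma::uword to) {
  const int L = X.n_cols;
  const int B = to - from;
  arma::mat A(1, static_cast<arma::uword>(L) * B);
  for (int s = 0; s < B; ++s) {
    const arma::uword r = idx[from + s];
    for (int p = 0; p < L; ++p) A(0, s * L + p) = X(r, p);
  }
  return A;
}

double mean_ce(const arma::mat& P, const arma::ivec& y) {
  double acc = 0;
  for (arma::uword s = 0; s < P.n_cols; ++s) {
    double p = P(y[s], s);
    if (p < 1e-12) p = 1e-12;
    acc -= std::log(p);
  }
  return acc / P.n_cols;
}

// Inference over a dataset in batches; returns (K, n) probabilities.
arma::mat predict_all(const std::vector<Layer>& layers, Weights& w,
                      const arma::mat& X, int batch) {
  const arma::uword n = X.n_rows;
  std::vector<arma::uword> idx(n);
  for (arma::uword i = 0; i < n; ++i) idx[i] = i;
  arma::mat out;
  for (arma::uword s = 0; s < n; s += batch) {
    const arma::uword e = std::min(n, s + static_cast<arma::uword>(batch));
    arma::mat A = pack_rows(X, idx, s, e);
    arma::mat P = forward(layers, w, A, X.n_cols, e - s, false,
                          nullptr, nullptr, nullptr);
    out = out.n_elem ? arma::join_rows(out, P) : P;
  }
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".cnn_init")]]
List cnn_init(List layers, int input_len, int seed) {
  std::vector<Layer> ly = parse_layers(layers);
  Rng rng(static_cast<uint64_t>(seed));
  Weights w = init_weights(ly, input_len, rng);
  return weights_to_list(w);
}

// [[Rcpp::export(name = ".cnn_predict")]]
NumericMatrix cnn_predict(List layers, List weights, NumericMatrix X,
                          int batch = 256) {
  std::vector<Layer> ly = parse_layers(layers);
  Weights w = weights_from_list(weights, ly);
  arma::mat Xm(X.begin(), X.nrow(), X.ncol(), false);
  arma::mat P = predict_all(ly, w, Xm, batch);
  return wrap(arma::mat(P.t()));  // n x K
}

// [[Rcpp::export(name = ".cnn_forward_shapes")]]
IntegerMatrix cnn_forward_shapes(List layers, List weights, int input_len) {
  std::vector<Layer> ly = parse_layers(layers);
  Weights w = weights_from_list(weights, ly);
  arma::mat A(1, input_len, arma::fill::zeros);
  std::vector<std::pair<int,int>> shapes;
  forward(ly, w, A, input_len, 1, false, nullptr, nullptr, &shapes);
  IntegerMatrix out(shapes.size(), 2);
  for (size_t i = 0; i < shapes.size(); ++i) {
    out(i, 0) = shapes[i].first;
    out(i, 1) = shapes[i].second;
  }
  colnames(out) = CharacterVector::create("length", "channels");
  return out;
}

// [[Rcpp::export(name = ".cnn_train")]]
List cnn_train(List layers, List weights, NumericMatrix X, IntegerVector y,
               NumericMatrix Xval, IntegerVector yval, int epochs,
               int batch_size, double lr, int seed) {
  std::vector<Layer> ly = parse_layers(layers);
  Weights w = weights_from_list(weights, ly);
  Rng rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);
  arma::mat Xm(X.begin(), X.nrow(), X.ncol(), false);
  arma::mat Xv(Xval.begin(), Xval.nrow(), Xval.ncol(), false);
  arma::ivec yv(Xval.nrow());
  for (int i = 0; i < Xval.nrow(); ++i) yv[i] = yval[i];
  const arma::uword n = Xm.n_rows;
  const int L0 = Xm.n_cols;
  std::vector<arma::uword> idx(n);
  for (arma::uword i = 0; i < n; ++i) idx[i] = i;

  Adam opt(w);
  NumericVector tr_loss(epochs), va_loss(epochs), va_acc(epochs);
  Weights best = w;
  double best_acc = -1.0;
  int best_epoch = 0;
  bool diverged = false;
  int done = 0;

  for (int ep = 0; ep < epochs && !diverged; ++ep) {
    rng.shuffle(idx);
    double loss_sum = 0;
    arma::uword seen = 0;
    for (arma::uword s = 0; s < n; s += batch_size) {
      const arma::uword e = std::min(n, s + static_cast<arma::uword>(batch_size));
      const int B = e - s;
      arma::mat A = pack_rows(Xm, idx, s, e);
      arma::ivec yb(B);
      for (int k = 0; k < B; ++k) yb[k] = y[idx[s + k]];
      std::vector<Cache> caches(ly.size());
      arma::mat P = forward(ly, w, A, L0, B, true, &caches, &rng, nullptr);
      const double lo = mean_ce(P, yb);
      if (!std::isfinite(lo)) { diverged = true; break; }
      loss_sum += lo * B;
      seen += B;
      Grads g = backward(ly, w, caches, P, yb);
      opt.apply(w, g, lr);
    }
    if (diverged) break;
    tr_loss[ep] = loss_sum / seen;
    arma::mat Pv = predict_all(ly, w, Xv, 512);
    va_loss[ep] = mean_ce(Pv, yv);
    arma::uword correct = 0;
    for (arma::uword s = 0; s < Pv.n_cols; ++s)
      if (static_cast<arma::sword>(Pv.col(s).index_max()) == yv[s]) ++correct;
    va_acc[ep] = static_cast<double>(correct) / Pv.n_cols;
    if (va_acc[ep] > best_acc) {
      best_acc = va_acc[ep];
      best = w;
      best_epoch = ep + 1;
    }
    done = ep + 1;
    Rcpp::checkUserInterrupt();
  }

  DataFrame history;
  if (done > 0) {
    history = DataFrame::create(
        _["epoch"] = seq_len(done),
        _["train_loss"] = tr_loss[Range(0, done - 1)],
        _["val_loss"] = va_loss[Range(0, done - 1)],
        _["val_acc"] = va_acc[Range(0, done - 1)]);
  } else {
    history = DataFrame::create(
        _["epoch"] = IntegerVector(0), _["train_loss"] = NumericVector(0),
        _["val_loss"] = NumericVector(0), _["val_acc"] = NumericVector(0));
  }
  return List::create(_["weights"] = weights_to_list(w),
                      _["best_weights"] = weights_to_list(best),
                      _["best_epoch"] = best_epoch,
                      _["best_val_acc"] = best_acc,
                      _["history"] = history,
                      _["diverged"] = diverged);
}
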
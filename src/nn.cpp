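// Residual CNN for contour QA: two-channel (image, mask) input, stages of
// 3x3 residual blocks with 2x2 max-pooling, global average pooling, then a
// fully connected head that consumes the one-hot structure code with dropout
// before every FC layer. Forward, backprop, BCE-with-logits loss and Adam
// are implemented here; the R side owns configuration, data assembly,
// epoch building and checkpointing (weights live in one flat numeric
// vector whose layout is reported by cpp_param_shapes).
#include <RcppArmadillo.h>
#include <random>
#include <map>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct NetCfg {
  int in_ch;            // input channels (image + mask = 2)
  int K;                // structure-code length
  ivec ch;              // channels per stage
  ivec nb;              // residual blocks per stage
  ivec fc;              // hidden FC widths (output unit appended)
  double dropout;       // dropout probability for FC inputs
};

NetCfg parse_cfg(const Rcpp::List& cfg) {
  NetCfg c;
  c.in_ch   = Rcpp::as<int>(cfg["in_channels"]);
  c.K       = Rcpp::as<int>(cfg["structure_code_length"]);
  c.ch      = Rcpp::as<ivec>(cfg["stage_channels"]);
  c.nb      = Rcpp::as<ivec>(cfg["stage_blocks"]);
  c.fc      = Rcpp::as<ivec>(cfg["fc_sizes"]);
  c.dropout = Rcpp::as<double>(cfg["dropout_rate"]);
  if (c.ch.n_elem != c.nb.n_elem)
    Rcpp::stop("stage_channels and stage_blocks lengths differ");
  return c;
}

struct Shape { std::string name; int nr, nc; };

// Parameter walk; the flat weight vector concatenates these column-major.
std::vector<Shape> build_shapes(const NetCfg& c) {
  std::vector<Shape> s;
  const int S = c.ch.n_elem;
  s.push_back({"stem.W", 9 * c.in_ch, (int)c.ch(0)});
  s.push_back({"stem.b", (int)c.ch(0), 1});
  for (int st = 0; st < S; ++st) {
    const int cout = c.ch(st);
    for (int b = 0; b < c.nb(st); ++b) {
      const int cin = (b == 0) ? (st == 0 ? (int)c.ch(0) : (int)c.ch(st - 1)) : cout;
      const std::string p = "s" + std::to_string(st + 1) + ".b" + std::to_string(b + 1) + ".";
      s.push_back({p + "c1.W", 9 * cin, cout});
      s.push_back({p + "c1.b", cout, 1});
      s.push_back({p + "c2.W", 9 * cout, cout});
      s.push_back({p + "c2.b", cout, 1});
      if (cin != cout) {
        s.push_back({p + "proj.W", cin, cout});
        s.push_back({p + "proj.b", cout, 1});
      }
    }
  }
  int din = c.ch(S - 1) + c.K;
  for (uword i = 0; i < c.fc.n_elem; ++i) {
    const std::string p = "fc" + std::to_string(i + 1) + ".";
    s.push_back({p + "W", din, (int)c.fc(i)});
    s.push_back({p + "b", (int)c.fc(i), 1});
    din = c.fc(i);
  }
  s.push_back({"out.W", din, 1});
  s.push_back({"out.b", 1, 1});
  return s;
}

size_t total_params(const std::vector<Shape>& s) {
  size_t n = 0;
  for (const auto& sh : s) n += (size_t)sh.nr * sh.nc;
  return n;
}

// Read-only / accumulating matrix views over the flat parameter buffers.
struct ParamViews {
  std::vector<mat> W;                       // aliases into the flat buffer
  std::map<std::string, int> idx;
  ParamViews(double* base, const std::vector<Shape>& shapes) {
    // reserve up front: vector growth would relocate the arma::mat views and
    // detach them from the external buffer they alias
    W.reserve(shapes.size());
    size_t off = 0;
    for (size_t i = 0; i < shapes.size(); ++i) {
      W.emplace_back(base + off, shapes[i].nr, shapes[i].nc, false, true);
      idx[shapes[i].name] = (int)i;
      off += (size_t)shapes[i].nr * shapes[i].nc;
    }
  }
  mat& operator[](const std::string& name) {
    auto it = idx.find(name);
    if (it == idx.end()) Rcpp::stop("unknown parameter: " + name);
    return W[it->second];
  }
  bool has(const std::string& name) const { return idx.count(name) > 0; }
};

// im2col for 3x3 "same" convolution over a batch stored as a cube with
// slice index n*C + c. Output: (H*W*N) x (9*C); pixel order is column-major
// within each image, samples stacked.
mat im2col3(const cube& X, int C, int N) {
  const int H = X.n_rows, W = X.n_cols;
  mat out((size_t)H * W * N, 9 * C, fill::zeros);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const mat& Sl = X.slice((size_t)n * C + c);
      for (int kj = -1; kj <= 1; ++kj) {
        for (int ki = -1; ki <= 1; ++ki) {
          const int r = ((kj + 1) * 3 + (ki + 1)) * C + c;
          double* col = out.colptr(r);
          for (int j = 0; j < W; ++j) {
            const int js = j + kj;
            if (js < 0 || js >= W) continue;
            const size_t base = (size_t)n * H * W + (size_t)j * H;
            const int i0 = std::max(0, -ki), i1 = std::min(H, H - ki);
            const double* src = Sl.colptr(js);
            for (int i = i0; i < i1; ++i) col[base + i] = src[i + ki];
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col3: accumulate (H*W*N) x (9*C) gradients back to a cube.
cube col2im3(const mat& dcols, int H, int W, int C, int N) {
  cube dX(H, W, (size_t)N * C, fill::zeros);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      mat& Sl = dX.slice((size_t)n * C + c);
      for (int kj = -1; kj <= 1; ++kj) {
        for (int ki = -1; ki <= 1; ++ki) {
          const int r = ((kj + 1) * 3 + (ki + 1)) * C + c;
          const double* col = dcols.colptr(r);
          for (int j = 0; j < W; ++j) {
            const int js = j + kj;
            if (js < 0 || js >= W) continue;
            const size_t base = (size_t)n * H * W + (size_t)j * H;
            const int i0 = std::max(0, -ki), i1 = std::min(H, H - ki);
            double* dst = Sl.colptr(js);
            for (int i = i0; i < i1; ++i) dst[i + ki] += col[base + i];
          }
        }
      }
    }
  }
  return dX;
}

// Channel-features matrix (H*W*N) x C from a batched cube, and back.
mat cube2feat(const cube& X, int C, int N) {
  const size_t HW = (size_t)X.n_rows * X.n_cols;
  mat out(HW * N, C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      std::memcpy(out.colptr(c) + n * HW, X.slice((size_t)n * C + c).memptr(),
                  HW * sizeof(double));
  return out;
}

cube feat2cube(const mat& Y, int H, int W, int C, int N) {
  const size_t HW = (size_t)H * W;
  cube out(H, W, (size_t)N * C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      std::memcpy(out.slice((size_t)n * C + c).memptr(), Y.colptr(c) + n * HW,
                  HW * sizeof(double));
  return out;
}

void add_bias(mat& Y, const mat& b) {
  for (uword c = 0; c < Y.n_cols; ++c) Y.col(c) += b(c, 0);
}

// 2x2 max-pooling with argmax bookkeeping (linear index within slice).
cube maxpool2(const cube& X, ucube& arg) {
  const int H = X.n_rows, W = X.n_cols, NS = X.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube out(Ho, Wo, NS);
  arg.set_size(Ho, Wo, NS);
  for (int s = 0; s < NS; ++s) {
    const mat& Sl = X.slice(s);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const int i2 = 2 * i, j2 = 2 * j;
        double best = Sl(i2, j2); uword bi = (uword)j2 * H + i2;
        const int di[3] = {1, 0, 1}, dj[3] = {0, 1, 1};
        for (int k = 0; k < 3; ++k) {
          const double v = Sl(i2 + di[k], j2 + dj[k]);
          if (v > best) { best = v; bi = (uword)(j2 + dj[k]) * H + (i2 + di[k]); }
        }
        out(i, j, s) = best; arg(i, j, s) = bi;
      }
    }
  }
  return out;
}

cube maxpool2_back(const cube& dY, const ucube& arg, int H, int W) {
  cube dX(H, W, dY.n_slices, fill::zeros);
  for (uword s = 0; s < dY.n_slices; ++s) {
    mat& Sl = dX.slice(s);
    for (uword j = 0; j < dY.n_cols; ++j)
      for (uword i = 0; i < dY.n_rows; ++i)
        Sl(arg(i, j, s)) += dY(i, j, s);
  }
  return dX;
}

struct BlockCache {
  cube x_in, h1, y_out;   // input, post-ReLU inner activation, block output
  mat cols1, cols2;       // im2col matrices for the two convolutions
  mat featx;              // channel features of x_in (projection blocks only)
  int cin, cout;
};

struct FcCache { mat a_drop, mask, z; };

struct StageCache { std::vector<BlockCache> blocks; ucube poolarg; int Hin, Win; };

// One forward (and optional backward) pass over a batch.
class BatchRun {
public:
  BatchRun(const NetCfg& cfg, ParamViews& P, std::mt19937_64& rng,
           bool dropout_on)
      : c(cfg), P(P), rng(rng), dropout_on(dropout_on) {}

  vec forward(const cube& X0, const mat& codes, bool keep_caches) {
    keep = keep_caches;
    N = codes.n_rows;
    const int S = c.ch.n_elem;
    int H = X0.n_rows, W = X0.n_cols;

    // stem: conv3x3 -> ReLU -> maxpool2
    mat cols = im2col3(X0, c.in_ch, N);
    mat y = cols * P["stem.W"]; add_bias(y, P["stem.b"]);
    if (keep) stem_cols = std::move(cols);
    cube a = feat2cube(y, H, W, c.ch(0), N);
    a.transform([](double v) { return v > 0 ? v : 0.0; });
    if (keep) stem_relu = a;
    a = maxpool2(a, stem_poolarg);
    stem_H = H; stem_W = W;
    H /= 2; W /= 2;

    stages.assign(S, StageCache());
    for (int st = 0; st < S; ++st) {
      stages[st].Hin = H; stages[st].Win = W;
      for (int b = 0; b < c.nb(st); ++b)
        a = run_block(a, st, b, H, W);
      a = maxpool2(a, stages[st].poolarg);
      H /= 2; W /= 2;
    }

    // global average pooling, then append the structure code
    const int Clast = c.ch(S - 1);
    gap_H = H; gap_W = W;
    mat feat(N, Clast + c.K);
    for (uword n = 0; n < (uword)N; ++n)
      for (int ch = 0; ch < Clast; ++ch)
        feat(n, ch) = accu(a.slice((size_t)n * Clast + ch)) / (H * W);
    feat.cols(Clast, Clast + c.K - 1) = codes;

    // FC head with dropout before every layer
    fcs.clear();
    mat h = feat;
    const int L = c.fc.n_elem;
    for (int i = 0; i <= L; ++i) {
      const std::string p = (i < L) ? "fc" + std::to_string(i + 1) + "." : "out.";
      FcCache fc;
      fc.mask = dropout_mask(h.n_rows, h.n_cols);
      fc.a_drop = h % fc.mask;
      fc.z = fc.a_drop * P[p + "W"]; add_bias_rows(fc.z, P[p + "b"]);
      if (i < L) fc.z.transform([](double v) { return v > 0 ? v : 0.0; });
      h = fc.z;
      fcs.push_back(std::move(fc));
    }
    logits = h.col(0);
    return 1.0 / (1.0 + exp(-logits));
  }

  // Backward from BCE-with-logits; accumulates into gradient views G.
  double backward(const vec& labels, ParamViews& G) {
    const int S = c.ch.n_elem;
    const int L = c.fc.n_elem;
    const vec p = 1.0 / (1.0 + exp(-logits));
    // mean BCE loss, numerically stable
    double loss = 0.0;
    for (uword n = 0; n < (uword)N; ++n) {
      const double z = logits(n);
      loss += (z > 0 ? z + std::log1p(std::exp(-z)) : std::log1p(std::exp(z)))
              - labels(n) * z;
    }
    loss /= N;

    mat dh = mat(p - labels) / (double)N;   // N x 1
    for (int i = L; i >= 0; --i) {
      const std::string pr = (i < L) ? "fc" + std::to_string(i + 1) + "." : "out.";
      FcCache& fc = fcs[i];
      if (i < L) dh %= conv_to<mat>::from(fc.z > 0);
      G[pr + "W"] += fc.a_drop.t() * dh;
      G[pr + "b"] += sum(dh, 0).t();
      dh = (dh * P[pr + "W"].t()) % fc.mask;
    }

    const int Clast = c.ch(S - 1);
    mat dfeat = dh.cols(0, Clast - 1);      // code columns carry no gradient
    cube da(gap_H, gap_W, (size_t)N * Clast);
    for (uword n = 0; n < (uword)N; ++n)
      for (int ch = 0; ch < Clast; ++ch)
        da.slice((size_t)n * Clast + ch).fill(dfeat(n, ch) / (gap_H * gap_W));

    for (int st = S - 1; st >= 0; --st) {
      StageCache& sc = stages[st];
      int H = sc.Hin, W = sc.Win;
      da = maxpool2_back(da, sc.poolarg, H, W);
      for (int b = c.nb(st) - 1; b >= 0; --b)
        da = block_back(da, st, b, H, W, G);
    }

    da = maxpool2_back(da, stem_poolarg, stem_H, stem_W);
    da %= conv_to<cube>::from(stem_relu > 0);
    mat dy = cube2feat(da, c.ch(0), N);
    G["stem.W"] += stem_cols.t() * dy;
    G["stem.b"] += sum(dy, 0).t();
    return loss;
  }

private:
  const NetCfg& c;
  ParamViews& P;
  std::mt19937_64& rng;
  bool dropout_on, keep = false;
  int N = 0, stem_H = 0, stem_W = 0, gap_H = 0, gap_W = 0;
  mat stem_cols; cube stem_relu; ucube stem_poolarg;
  std::vector<StageCache> stages;
  std::vector<FcCache> fcs;
  cube last_act;
  vec logits;

  static void add_bias_rows(mat& Z, const mat& b) {
    for (uword c2 = 0; c2 < Z.n_cols; ++c2) Z.col(c2) += b(c2, 0);
  }

  mat dropout_mask(uword nr, uword nc) {
    if (!dropout_on || c.dropout <= 0) return mat(nr, nc, fill::ones);
    std::uniform_real_distribution<double> U(0.0, 1.0);
    mat m(nr, nc);
    const double keep_p = 1.0 - c.dropout;
    // fixed draw order (column-major) so a seed fully determines the pass
    for (uword j = 0; j < nc; ++j)
      for (uword i = 0; i < nr; ++i)
        m(i, j) = (U(rng) < keep_p) ? 1.0 / keep_p : 0.0;
    return m;
  }

  cube run_block(const cube& x, int st, int b, int H, int W) {
    const int cout = c.ch(st);
    const int cin = (b == 0) ? (st == 0 ? (int)c.ch(0) : (int)c.ch(st - 1)) : cout;
    const std::string p = "s" + std::to_string(st + 1) + ".b" + std::to_string(b + 1) + ".";
    BlockCache bc; bc.cin = cin; bc.cout = cout;
    bc.cols1 = im2col3(x, cin, N);
    mat y1 = bc.cols1 * P[p + "c1.W"]; add_bias(y1, P[p + "c1.b"]);
    cube h1 = feat2cube(y1, H, W, cout, N);
    h1.transform([](double v) { return v > 0 ? v : 0.0; });
    bc.cols2 = im2col3(h1, cout, N);
    mat y2 = bc.cols2 * P[p + "c2.W"]; add_bias(y2, P[p + "c2.b"]);
    cube out = feat2cube(y2, H, W, cout, N);
    if (cin != cout) {
      bc.featx = cube2feat(x, cin, N);
      mat yp = bc.featx * P[p + "proj.W"]; add_bias(yp, P[p + "proj.b"]);
      out += feat2cube(yp, H, W, cout, N);
    } else {
      out += x;
    }
    out.transform([](double v) { return v > 0 ? v : 0.0; });
    if (!keep) return out;
    bc.h1 = std::move(h1);
    bc.y_out = out;
    stages[st].blocks.push_back(std::move(bc));
    return out;
  }

  cube block_back(const cube& dy_in, int st, int b, int H, int W, ParamViews& G) {
    BlockCache& bc = stages[st].blocks[b];
    const std::string p = "s" + std::to_string(st + 1) + ".b" + std::to_string(b + 1) + ".";
    cube dy = dy_in % conv_to<cube>::from(bc.y_out > 0);

    mat dy2 = cube2feat(dy, bc.cout, N);
    G[p + "c2.W"] += bc.cols2.t() * dy2;
    G[p + "c2.b"] += sum(dy2, 0).t();
    cube dh1 = col2im3(dy2 * P[p + "c2.W"].t(), H, W, bc.cout, N);
    dh1 %= conv_to<cube>::from(bc.h1 > 0);

    mat dy1 = cube2feat(dh1, bc.cout, N);
    G[p + "c1.W"] += bc.cols1.t() * dy1;
    G[p + "c1.b"] += sum(dy1, 0).t();
    cube dx = col2im3(dy1 * P[p + "c1.W"].t(), H, W, bc.cin, N);

    if (bc.cin != bc.cout) {
      mat dyp = cube2feat(dy, bc.cout, N);
      G[p + "proj.W"] += bc.featx.t() * dyp;
      G[p + "proj.b"] += sum(dyp, 0).t();
      dx += feat2cube(dyp * P[p + "proj.W"].t(), H, W, bc.cin, N);
    } else {
      dx += dy;
    }
    return dx;
  }
};

cube batch_cube(const double* x, int H, int W, int C, int N,
                const uvec& rows_keep) {
  // x is an R array [H, W, C, Ntotal]; select the given samples
  cube out(H, W, (size_t)rows_keep.n_elem * C);
  const size_t HW = (size_t)H * W;
  for (uword k = 0; k < rows_keep.n_elem; ++k) {
    const size_t n = rows_keep(k);
    for (int c = 0; c < C; ++c)
      std::memcpy(out.slice((size_t)k * C + c).memptr(),
                  x + n * HW * C + (size_t)c * HW, HW * sizeof(double));
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_param_shapes(Rcpp::List cfg) {
  NetCfg c = parse_cfg(cfg);
  auto shapes = build_shapes(c);
  Rcpp::CharacterVector nm(shapes.size());
  Rcpp::IntegerVector nr(shapes.size()), nc(shapes.size());
  for (size_t i = 0; i < shapes.size(); ++i) {
    nm[i] = shapes[i].name; nr[i] = shapes[i].nr; nc[i] = shapes[i].nc;
  }
  return Rcpp::List::create(Rcpp::Named("name") = nm, Rcpp::Named("nrow") = nr,
                            Rcpp::Named("ncol") = nc);
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_forward(Rcpp::List cfg, Rcpp::NumericVector theta,
                                Rcpp::NumericVector x, Rcpp::IntegerVector xdim,
                                Rcpp::NumericMatrix codes, bool dropout_on,
                                int seed) {
  NetCfg c = parse_cfg(cfg);
  auto shapes = build_shapes(c);
  if ((size_t)theta.size() != total_params(shapes))
    Rcpp::stop("weight vector length does not match the architecture");
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  if (C != c.in_ch) Rcpp::stop("input channel count mismatch");
  if (codes.nrow() != N || codes.ncol() != c.K)
    Rcpp::stop("structure code matrix has wrong shape");
  ParamViews P(theta.begin(), shapes);
  std::mt19937_64 rng((uint64_t)seed);
  uvec all = regspace<uvec>(0, N - 1);
  cube X0 = batch_cube(x.begin(), H, W, C, N, all);
  mat cd(codes.begin(), N, c.K, false, true);
  BatchRun run(c, P, rng, dropout_on);
  vec p = run.forward(X0, cd, false);
  return Rcpp::NumericVector(p.begin(), p.end());
}

// [[Rcpp::export]]
Rcpp::List cpp_loss_grad(Rcpp::List cfg, Rcpp::NumericVector theta,
                         Rcpp::NumericVector x, Rcpp::IntegerVector xdim,
                         Rcpp::NumericMatrix codes, Rcpp::NumericVector labels,
                         bool dropout_on, int seed) {
  NetCfg c = parse_cfg(cfg);
  auto shapes = build_shapes(c);
  const size_t np = total_params(shapes);
  if ((size_t)theta.size() != np) Rcpp::stop("weight vector length mismatch");
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  ParamViews P(theta.begin(), shapes);
  std::mt19937_64 rng((uint64_t)seed);
  uvec all = regspace<uvec>(0, N - 1);
  cube X0 = batch_cube(x.begin(), H, W, C, N, all);
  mat cd(codes.begin(), N, c.K, false, true);
  vec lab(labels.begin(), N, false, true);
  vec grad(np, fill::zeros);
  ParamViews G(grad.memptr(), shapes);
  BatchRun run(c, P, rng, dropout_on);
  vec p = run.forward(X0, cd, true);
  const double loss = run.backward(lab, G);
  return Rcpp::List::create(
      Rcpp::Named("loss") = loss,
      Rcpp::Named("grad") = Rcpp::NumericVector(grad.begin(), grad.end()),
      Rcpp::Named("probs") = Rcpp::NumericVector(p.begin(), p.end()));
}

// [[Rcpp::export]]
Rcpp::List cpp_train_epoch(Rcpp::List cfg, Rcpp::NumericVector theta,
                           Rcpp::NumericVector m, Rcpp::NumericVector v,
                           int adam_t, Rcpp::NumericVector x,
                           Rcpp::IntegerVector xdim, Rcpp::NumericMatrix codes,
                           Rcpp::NumericVector labels, double lr,
                           int batch_size, int seed) {
  NetCfg c = parse_cfg(cfg);
  auto shapes = build_shapes(c);
  const size_t np = total_params(shapes);
  if ((size_t)theta.size() != np) Rcpp::stop("weight vector length mismatch");
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  if (labels.size() != N) Rcpp::stop("labels length mismatch");

  vec th(theta.begin(), np);        // working copies; caller state untouched
  vec mm(m.begin(), np), vv(v.begin(), np);
  std::mt19937_64 rng((uint64_t)seed);
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  int t = adam_t;

  const int nbatch = (N + batch_size - 1) / batch_size;
  Rcpp::NumericVector batch_loss(nbatch);
  mat cd_all(codes.begin(), N, c.K, false, true);
  vec lab_all(labels.begin(), N, false, true);

  for (int bi = 0; bi < nbatch; ++bi) {
    const int lo = bi * batch_size;
    const int hi = std::min(N, lo + batch_size) - 1;
    uvec idx = regspace<uvec>(lo, hi);
    cube X0 = batch_cube(x.begin(), H, W, C, N, idx);
    mat cd = cd_all.rows(idx);
    vec lab = lab_all(idx);

    ParamViews P(th.memptr(), shapes);
    vec grad(np, fill::zeros);
    ParamViews G(grad.memptr(), shapes);
    BatchRun run(c, P, rng, true);
    run.forward(X0, cd, true);
    const double loss = run.backward(lab, G);
    if (!std::isfinite(loss)) Rcpp::stop("training loss diverged (non-finite)");
    batch_loss[bi] = loss;

    ++t;
    mm = b1 * mm + (1.0 - b1) * grad;
    vv = b2 * vv + (1.0 - b2) * square(grad);
    const double bc1 = 1.0 - std::pow(b1, t), bc2 = 1.0 - std::pow(b2, t);
    th -= lr * (mm / bc1) / (sqrt(vv / bc2) + eps);
  }

  return Rcpp::List::create(
      Rcpp::Named("theta") = Rcpp::NumericVector(th.begin(), th.end()),
      Rcpp::Named("m") = Rcpp::NumericVector(mm.begin(), mm.end()),
      Rcpp::Named("v") = Rcpp::NumericVector(vv.begin(), vv.end()),
      Rcpp::Named("adam_t") = t, Rcpp::Named("batch_loss") = batch_loss);
}
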
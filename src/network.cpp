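// Forward and backward passes of the pairwise score network.
//
// Architecture: two conv blocks -> M residual blocks (distinct weights) ->
// one shared residual block applied N times (same weights every pass) ->
// a shared readout (1x1 conv block + 1x1 conv, one output channel) applied
// to the output of every shared pass. Every conv block is convolution +
// batch normalization + LeakyReLU; residual blocks are two conv blocks
// with an identity skip added before the final activation. The loss is
// the masked mean-squared error between each pass output and the binary
// target, averaged over the N passes.
//
// Feature maps are stored per sample as (L*L x C) column-major matrices
// (identical memory layout to an R array of dim c(L, L, C)), convolutions
// are im2col + GEMM, and batch statistics pool over all samples of a
// mini-batch. Gradients are analytic; the test suite checks them against
// finite differences.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

typedef std::vector<arma::mat> BatchMats;  // one (HW x C) matrix per sample

arma::mat im2col(const arma::mat& X, int H, int W, int Cin, int k) {
  if (k == 1) return X;
  int pad = k / 2;
  arma::mat cols(
      static_cast<size_t>(H) * W, static_cast<size_t>(k) * k * Cin,
      arma::fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    const double* src = X.colptr(c);
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        int col = c * k * k + dj * k + di;
        double* dst = cols.colptr(col);
        int oi = di - pad, oj = dj - pad;  // dst(i,j) = src(i+oi, j+oj)
        int i0 = std::max(0, -oi), i1 = std::min(H, H - oi) - 1;
        int j0 = std::max(0, -oj), j1 = std::min(W, W - oj) - 1;
        if (i1 < i0) continue;
        for (int j = j0; j <= j1; ++j) {
          std::memcpy(dst + static_cast<size_t>(j) * H + i0,
                      src + static_cast<size_t>(j + oj) * H + (i0 + oi),
                      sizeof(double) * (i1 - i0 + 1));
        }
      }
    }
  }
  return cols;
}

arma::mat col2im(const arma::mat& dcols, int H, int W, int Cin, int k) {
  if (k == 1) return dcols;
  int pad = k / 2;
  arma::mat dX(static_cast<size_t>(H) * W, Cin, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    double* dst = dX.colptr(c);
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        int col = c * k * k + dj * k + di;
        const double* src = dcols.colptr(col);
        int oi = di - pad, oj = dj - pad;  // dX(i+oi, j+oj) += dcols(i,j)
        int i0 = std::max(0, -oi), i1 = std::min(H, H - oi) - 1;
        int j0 = std::max(0, -oj), j1 = std::min(W, W - oj) - 1;
        for (int j = j0; j <= j1; ++j) {
          double* d = dst + static_cast<size_t>(j + oj) * H + oi;
          const double* s = src + static_cast<size_t>(j) * H;
          for (int i = i0; i <= i1; ++i) d[i] += s[i];
        }
      }
    }
  }
  return dX;
}

struct ConvBN {
  int k, cin, cout;
  bool relu;
  arma::mat W;                        // (k*k*cin x cout)
  arma::vec gamma, beta, rmean, rvar;
  arma::mat dW;
  arma::vec dgamma, dbeta;
  std::string conv_name, bn_name;

  void load(const List& params, const List& running, const std::string& cn,
            const std::string& bn, int k_, int cin_, int cout_, bool relu_) {
    k = k_; cin = cin_; cout = cout_; relu = relu_;
    conv_name = cn; bn_name = bn;
    NumericVector w = params[cn + ".W"];
    if (w.size() != static_cast<R_xlen_t>(k) * k * cin * cout)
      stop("parameter %s.W has the wrong size", cn);
    W = arma::mat(w.begin(), static_cast<size_t>(k) * k * cin, cout);
    NumericVector ga = params[bn + ".gamma"], be = params[bn + ".beta"];
    gamma = arma::vec(ga.begin(), cout);
    beta = arma::vec(be.begin(), cout);
    NumericVector rm = running[bn + ".mean"], rv = running[bn + ".var"];
    rmean = arma::vec(rm.begin(), cout);
    rvar = arma::vec(rv.begin(), cout);
    dW.zeros(W.n_rows, W.n_cols);
    dgamma.zeros(cout);
    dbeta.zeros(cout);
  }
};

// one application of a conv+BN(+LReLU) block on a batch
struct StageCache {
  const BatchMats* in;    // conv input (owned elsewhere)
  BatchMats z;            // conv output = BN input
  arma::vec mean, invstd; // batch statistics used in this application
};

struct Net {
  int M, N, C, k;
  double slope, eps, momentum;
  ConvBN conv1, conv2;
  std::vector<ConvBN> resA, resB;
  ConvBN sharedA, sharedB, read1;
  arma::mat readW;   // (C x 1)
  double readb;
  arma::mat dreadW;
  double dreadb;

  void load(const List& params, const List& running, const List& cfg) {
    M = as<int>(cfg["M"]);
    N = as<int>(cfg["N"]);
    C = as<int>(cfg["channels"]);
    k = as<int>(cfg["kernel"]);
    slope = as<double>(cfg["leaky_slope"]);
    eps = as<double>(cfg["bn_eps"]);
    momentum = as<double>(cfg["bn_momentum"]);
    conv1.load(params, running, "conv1", "bn1", k, 8, C, true);
    conv2.load(params, running, "conv2", "bn2", k, C, C, true);
    resA.resize(M);
    resB.resize(M);
    for (int m = 0; m < M; ++m) {
      std::string p = "res" + std::to_string(m + 1);
      resA[m].load(params, running, p + ".convA", p + ".bnA", k, C, C, true);
      resB[m].load(params, running, p + ".convB", p + ".bnB", k, C, C, false);
    }
    sharedA.load(params, running, "shared.convA", "shared.bnA", k, C, C, true);
    sharedB.load(params, running, "shared.convB", "shared.bnB", k, C, C, false);
    read1.load(params, running, "read.conv1", "read.bn", 1, C, C, true);
    NumericVector rw = params["read.conv2.W"];
    if (rw.size() != C) stop("read.conv2.W has the wrong size");
    readW = arma::mat(rw.begin(), C, 1);
    readb = as<double>(params["read.conv2.b"]);
    dreadW.zeros(C, 1);
    dreadb = 0.0;
  }
};

void bn_stats(const BatchMats& z, double eps, arma::vec& mean, arma::vec& invstd,
              double& m_total) {
  int C = z[0].n_cols;
  arma::vec s(C, arma::fill::zeros), s2(C, arma::fill::zeros);
  m_total = 0;
  for (size_t b = 0; b < z.size(); ++b) {
    s += arma::sum(z[b], 0).t();
    s2 += arma::sum(arma::square(z[b]), 0).t();
    m_total += z[b].n_rows;
  }
  mean = s / m_total;
  arma::vec var = s2 / m_total - arma::square(mean);
  var.transform([](double v) { return v < 0 ? 0 : v; });
  invstd = 1.0 / arma::sqrt(var + eps);
}

// forward through conv + BN (+ LReLU). Lengths per sample in Ls.
BatchMats convbn_fwd(ConvBN& layer, const BatchMats& in,
                     const std::vector<int>& Ls, bool train, double slope,
                     double eps, double momentum, StageCache* cache) {
  size_t B = in.size();
  BatchMats z(B);
  for (size_t b = 0; b < B; ++b) {
    int L = Ls[b];
    if (layer.k == 1) {
      z[b] = in[b] * layer.W;
    } else {
      z[b] = im2col(in[b], L, L, layer.cin, layer.k) * layer.W;
    }
  }
  arma::vec mean, invstd;
  if (train) {
    double m_total = 0;
    bn_stats(z, eps, mean, invstd, m_total);
    // unbiased variance for the running estimate, as is conventional
    arma::vec var = 1.0 / arma::square(invstd) - eps;
    double corr = m_total > 1 ? m_total / (m_total - 1.0) : 1.0;
    layer.rmean = (1.0 - momentum) * layer.rmean + momentum * mean;
    layer.rvar = (1.0 - momentum) * layer.rvar + momentum * (var * corr);
  } else {
    mean = layer.rmean;
    arma::vec var = layer.rvar;
    var.transform([](double v) { return v < 0 ? 0 : v; });
    invstd = 1.0 / arma::sqrt(var + eps);
  }
  BatchMats out(B);
  arma::rowvec shift = (layer.beta - layer.gamma % mean % invstd).t();
  arma::rowvec scale = (layer.gamma % invstd).t();
  for (size_t b = 0; b < B; ++b) {
    out[b] = z[b];
    out[b].each_row() %= scale;
    out[b].each_row() += shift;
    if (layer.relu) {
      out[b].transform([slope](double v) { return v > 0 ? v : slope * v; });
    }
  }
  if (cache) {
    cache->in = &in;
    cache->z = std::move(z);
    cache->mean = mean;
    cache->invstd = invstd;
  }
  return out;
}

// backward through the same block; returns d(input), accumulates layer grads
BatchMats convbn_bwd(ConvBN& layer, const StageCache& cache, BatchMats dout,
                     const std::vector<int>& Ls, double slope) {
  size_t B = dout.size();
  int C = layer.cout;
  arma::rowvec scale = (layer.gamma % cache.invstd).t();
  arma::rowvec shift = (layer.beta - layer.gamma % cache.mean % cache.invstd).t();

  double m_total = 0;
  for (size_t b = 0; b < B; ++b) m_total += cache.z[b].n_rows;

  // LReLU backward (mask from the recomputed BN output), then BN backward
  arma::vec sum_dxh(C, arma::fill::zeros), sum_dxh_xh(C, arma::fill::zeros);
  std::vector<arma::mat> xhat(B);
  for (size_t b = 0; b < B; ++b) {
    if (layer.relu) {
      arma::mat h = cache.z[b];
      h.each_row() %= scale;
      h.each_row() += shift;
      dout[b] %= (arma::conv_to<arma::mat>::from(h > 0) * (1.0 - slope) + slope);
    }
    xhat[b] = cache.z[b];
    xhat[b].each_row() -= cache.mean.t();
    xhat[b].each_row() %= cache.invstd.t();
    layer.dbeta += arma::sum(dout[b], 0).t();
    layer.dgamma += arma::sum(dout[b] % xhat[b], 0).t();
    // dxhat = dout * gamma
    sum_dxh += (arma::sum(dout[b], 0).t()) % layer.gamma;
    sum_dxh_xh += (arma::sum(dout[b] % xhat[b], 0).t()) % layer.gamma;
  }
  BatchMats dz(B);
  for (size_t b = 0; b < B; ++b) {
    arma::mat dxh = dout[b];
    dxh.each_row() %= layer.gamma.t();
    dz[b] = dxh * m_total;
    dz[b].each_row() -= sum_dxh.t();
    dz[b] -= xhat[b] * arma::diagmat(sum_dxh_xh);
    dz[b].each_row() %= (cache.invstd.t() / m_total);
  }
  // conv backward
  BatchMats din(B);
  for (size_t b = 0; b < B; ++b) {
    int L = Ls[b];
    if (layer.k == 1) {
      layer.dW += (*cache.in)[b].t() * dz[b];
      din[b] = dz[b] * layer.W.t();
    } else {
      arma::mat cols = im2col((*cache.in)[b], L, L, layer.cin, layer.k);
      layer.dW += cols.t() * dz[b];
      din[b] = col2im(dz[b] * layer.W.t(), L, L, layer.cin, layer.k);
    }
  }
  return din;
}

void lrelu_inplace(BatchMats& x, double slope) {
  for (size_t b = 0; b < x.size(); ++b)
    x[b].transform([slope](double v) { return v > 0 ? v : slope * v; });
}

List running_to_list(Net& net) {
  List out;
  std::vector<ConvBN*> layers = {&net.conv1, &net.conv2};
  for (int m = 0; m < net.M; ++m) {
    layers.push_back(&net.resA[m]);
    layers.push_back(&net.resB[m]);
  }
  layers.push_back(&net.sharedA);
  layers.push_back(&net.sharedB);
  layers.push_back(&net.read1);
  for (size_t i = 0; i < layers.size(); ++i) {
    out[layers[i]->bn_name + ".mean"] =
        NumericVector(layers[i]->rmean.begin(), layers[i]->rmean.end());
    out[layers[i]->bn_name + ".var"] =
        NumericVector(layers[i]->rvar.begin(), layers[i]->rvar.end());
  }
  return out;
}

List grads_to_list(Net& net) {
  List out;
  std::vector<ConvBN*> layers = {&net.conv1, &net.conv2};
  for (int m = 0; m < net.M; ++m) {
    layers.push_back(&net.resA[m]);
    layers.push_back(&net.resB[m]);
  }
  layers.push_back(&net.sharedA);
  layers.push_back(&net.sharedB);
  layers.push_back(&net.read1);
  for (size_t i = 0; i < layers.size(); ++i) {
    ConvBN* l = layers[i];
    NumericVector dw(l->dW.begin(), l->dW.end());
    dw.attr("dim") = IntegerVector::create(l->k, l->k, l->cin, l->cout);
    out[l->conv_name + ".W"] = dw;
    out[l->bn_name + ".gamma"] = NumericVector(l->dgamma.begin(), l->dgamma.end());
    out[l->bn_name + ".beta"] = NumericVector(l->dbeta.begin(), l->dbeta.end());
  }
  NumericVector drw(net.dreadW.begin(), net.dreadW.end());
  drw.attr("dim") = IntegerVector::create(1, 1, net.C, 1);
  out["read.conv2.W"] = drw;
  out["read.conv2.b"] = net.dreadb;
  return out;
}

}  // namespace

// Runs the network on a batch. X: list of (L x L x 8) arrays. If
// want_grad, target and vmask must be lists of (L x L) matrices and the
// returned list contains parameter gradients of the averaged masked MSE.
// train toggles batch statistics (and running-stat updates) vs running
// statistics.
// [[Rcpp::export]]
List cpp_net_run(List params, List running, List cfg, List X,
                 List target, List vmask, bool train, bool want_grad) {
  Net net;
  net.load(params, running, cfg);
  size_t B = X.size();
  if (B == 0) stop("empty batch");
  std::vector<int> Ls(B);
  BatchMats A0(B);
  for (size_t b = 0; b < B; ++b) {
    NumericVector x = X[b];
    IntegerVector dim = x.attr("dim");
    if (dim.size() != 3 || dim[0] != dim[1] || dim[2] != 8)
      stop("each input must be an L x L x 8 array");
    Ls[b] = dim[0];
    A0[b] = arma::mat(x.begin(), static_cast<size_t>(dim[0]) * dim[1], 8);
  }

  double slope = net.slope, eps = net.eps, mom = net.momentum;
  StageCache c_conv1, c_conv2;
  std::vector<StageCache> c_resA(net.M), c_resB(net.M);
  std::vector<StageCache> c_shA(net.N), c_shB(net.N), c_read(net.N);
  std::vector<BatchMats> acts;  // owned activations, addresses must persist
  acts.reserve(4 + 2 * net.M + 4 * net.N);

  acts.push_back(A0);
  acts.push_back(convbn_fwd(net.conv1, acts.back(), Ls, train, slope, eps, mom,
                            want_grad ? &c_conv1 : nullptr));
  acts.push_back(convbn_fwd(net.conv2, acts.back(), Ls, train, slope, eps, mom,
                            want_grad ? &c_conv2 : nullptr));

  std::vector<int> block_in_idx(net.M), sh_in_idx(net.N), sh_out_idx(net.N),
      read_in_idx(net.N);
  for (int m = 0; m < net.M; ++m) {
    block_in_idx[m] = acts.size() - 1;
    BatchMats u1 = convbn_fwd(net.resA[m], acts.back(), Ls, train, slope, eps,
                              mom, want_grad ? &c_resA[m] : nullptr);
    acts.push_back(std::move(u1));
    BatchMats u2 = convbn_fwd(net.resB[m], acts.back(), Ls, train, slope, eps,
                              mom, want_grad ? &c_resB[m] : nullptr);
    const BatchMats& skip = acts[block_in_idx[m]];
    for (size_t b = 0; b < B; ++b) u2[b] += skip[b];
    lrelu_inplace(u2, slope);
    acts.push_back(std::move(u2));
  }

  std::vector<std::vector<arma::vec> > y(net.N,
                                         std::vector<arma::vec>(B));
  int cur = acts.size() - 1;  // feature map entering the shared block
  for (int n = 0; n < net.N; ++n) {
    sh_in_idx[n] = cur;
    BatchMats u1 = convbn_fwd(net.sharedA, acts[cur], Ls, train, slope, eps,
                              mom, want_grad ? &c_shA[n] : nullptr);
    acts.push_back(std::move(u1));
    BatchMats u2 = convbn_fwd(net.sharedB, acts.back(), Ls, train, slope, eps,
                              mom, want_grad ? &c_shB[n] : nullptr);
    const BatchMats& skip = acts[sh_in_idx[n]];
    for (size_t b = 0; b < B; ++b) u2[b] += skip[b];
    lrelu_inplace(u2, slope);
    acts.push_back(std::move(u2));
    sh_out_idx[n] = acts.size() - 1;
    cur = sh_out_idx[n];
    BatchMats r = convbn_fwd(net.read1, acts[cur], Ls, train, slope, eps,
                             mom, want_grad ? &c_read[n] : nullptr);
    acts.push_back(std::move(r));
    read_in_idx[n] = acts.size() - 1;
    for (size_t b = 0; b < B; ++b) {
      y[n][b] = acts.back()[b] * net.readW + net.readb;
    }
  }

  // pack outputs as L x L matrices per pass per sample
  List outputs(net.N);
  for (int n = 0; n < net.N; ++n) {
    List per_b(B);
    for (size_t b = 0; b < B; ++b) {
      NumericMatrix m(Ls[b], Ls[b]);
      std::copy(y[n][b].begin(), y[n][b].end(), m.begin());
      per_b[b] = m;
    }
    outputs[n] = per_b;
  }

  double loss = NA_REAL;
  List grads;
  bool have_t = target.size() > 0;
  if (want_grad && !have_t) stop("gradients require targets and masks");
  if (have_t) {
    if (target.size() != static_cast<R_xlen_t>(B) ||
        vmask.size() != static_cast<R_xlen_t>(B))
      stop("target and vmask must match the batch");
    std::vector<arma::vec> tv(B), mv(B);
    std::vector<double> msize(B);
    for (size_t b = 0; b < B; ++b) {
      NumericMatrix t = target[b], v = vmask[b];
      if (t.nrow() != Ls[b] || v.nrow() != Ls[b])
        stop("target/vmask dimensions must match the input");
      tv[b] = arma::vec(t.begin(), static_cast<size_t>(Ls[b]) * Ls[b]);
      mv[b] = arma::vec(v.begin(), static_cast<size_t>(Ls[b]) * Ls[b]);
      msize[b] = arma::accu(mv[b]);
      if (msize[b] == 0) stop("valid mask of sample %d is empty", (int)b + 1);
    }
    loss = 0.0;
    for (int n = 0; n < net.N; ++n) {
      for (size_t b = 0; b < B; ++b) {
        arma::vec diff = (y[n][b] - tv[b]) % mv[b];
        loss += arma::dot(diff, diff) / msize[b];
      }
    }
    loss /= net.N * static_cast<double>(B);
  }

  if (want_grad) {
    std::vector<arma::vec> tv(B), mv(B);
    std::vector<double> msize(B);
    for (size_t b = 0; b < B; ++b) {
      NumericMatrix t = target[b], v = vmask[b];
      tv[b] = arma::vec(t.begin(), static_cast<size_t>(Ls[b]) * Ls[b]);
      mv[b] = arma::vec(v.begin(), static_cast<size_t>(Ls[b]) * Ls[b]);
      msize[b] = arma::accu(mv[b]);
    }
    std::vector<std::vector<arma::vec> > dy(net.N, std::vector<arma::vec>(B));
    for (int n = 0; n < net.N; ++n)
      for (size_t b = 0; b < B; ++b) {
        arma::vec diff = (y[n][b] - tv[b]) % mv[b];
        dy[n][b] = diff * (2.0 / (net.N * static_cast<double>(B) * msize[b]));
      }

    // ---- backward ----
    BatchMats dcur(B);
    for (size_t b = 0; b < B; ++b)
      dcur[b].zeros(static_cast<size_t>(Ls[b]) * Ls[b], net.C);

    for (int n = net.N - 1; n >= 0; --n) {
      // readout branch
      BatchMats dr(B);
      const BatchMats& rin = acts[read_in_idx[n]];
      for (size_t b = 0; b < B; ++b) {
        net.dreadW += rin[b].t() * dy[n][b];
        net.dreadb += arma::accu(dy[n][b]);
        dr[b] = dy[n][b] * net.readW.t();
      }
      BatchMats d_shout = convbn_bwd(net.read1, c_read[n], std::move(dr), Ls, slope);
      for (size_t b = 0; b < B; ++b) dcur[b] += d_shout[b];
      // final activation of the shared pass: recompute pre-activation sum
      const BatchMats& u1 = acts[sh_in_idx[n] + 1];
      const BatchMats& skip = acts[sh_in_idx[n]];
      {
        arma::rowvec scale = (net.sharedB.gamma % c_shB[n].invstd).t();
        arma::rowvec shift =
            (net.sharedB.beta - net.sharedB.gamma % c_shB[n].mean % c_shB[n].invstd).t();
        for (size_t b = 0; b < B; ++b) {
          arma::mat pre = c_shB[n].z[b];
          pre.each_row() %= scale;
          pre.each_row() += shift;
          pre += skip[b];
          dcur[b] %= (arma::conv_to<arma::mat>::from(pre > 0) * (1.0 - slope) + slope);
        }
      }
      BatchMats du1 = convbn_bwd(net.sharedB, c_shB[n], dcur, Ls, slope);
      BatchMats dmain = convbn_bwd(net.sharedA, c_shA[n], std::move(du1), Ls, slope);
      for (size_t b = 0; b < B; ++b) dcur[b] += dmain[b];  // += skip grad
      (void)u1;
    }

    for (int m = net.M - 1; m >= 0; --m) {
      const BatchMats& skip = acts[block_in_idx[m]];
      arma::rowvec scale = (net.resB[m].gamma % c_resB[m].invstd).t();
      arma::rowvec shift =
          (net.resB[m].beta - net.resB[m].gamma % c_resB[m].mean % c_resB[m].invstd).t();
      for (size_t b = 0; b < B; ++b) {
        arma::mat pre = c_resB[m].z[b];
        pre.each_row() %= scale;
        pre.each_row() += shift;
        pre += skip[b];
        dcur[b] %= (arma::conv_to<arma::mat>::from(pre > 0) * (1.0 - slope) + slope);
      }
      BatchMats du1 = convbn_bwd(net.resB[m], c_resB[m], dcur, Ls, slope);
      BatchMats dmain = convbn_bwd(net.resA[m], c_resA[m], std::move(du1), Ls, slope);
      for (size_t b = 0; b < B; ++b) dcur[b] += dmain[b];
    }

    BatchMats d_a1 = convbn_bwd(net.conv2, c_conv2, std::move(dcur), Ls, slope);
    convbn_bwd(net.conv1, c_conv1, std::move(d_a1), Ls, slope);  // dX discarded

    grads = grads_to_list(net);
  }

  return List::create(Named("outputs") = outputs,
                      Named("loss") = loss,
                      Named("grads") = grads,
                      Named("running") = running_to_list(net));
}
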
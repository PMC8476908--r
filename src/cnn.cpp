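// Four-branch convolutional network engine: 3x3 size-preserving
// convolutions (im2col + GEMM in a channels-last layout, so patch
// extraction is contiguous memcpy segments), 2x2 max pooling, a global
// average pool per branch, branch concatenation and two fully connected
// layers with softmax cross-entropy loss, trained with Adam. All state
// crosses the R boundary as plain numeric arrays so training is
// deterministic given the initial weights and the shuffle schedule.
//
// Activations are (h*w) x channels matrices, pixels column-major within an
// image. Conv weights are (cout) x (9*cin), rows matching the R-side
// initialisation; patch row order is channel-major then (kj, ki).
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct ConvLayer {
  int cin, cout;
  bool pool_after;
};

// Zero-pad each channel image by one pixel: (h*w x c) -> ((h+2)*(w+2) x c).
arma::mat pad1(const arma::mat& a, int h, int w) {
  int hp = h + 2, wp = w + 2;
  arma::mat p(hp * wp, a.n_cols, arma::fill::zeros);
  for (arma::uword c = 0; c < a.n_cols; ++c) {
    const double* src = a.colptr(c);
    double* dst = p.colptr(c);
    for (int j = 0; j < w; ++j)
      std::memcpy(dst + (j + 1) * hp + 1, src + j * h, h * sizeof(double));
  }
  return p;
}

// Patch matrix: (h*w) x (9*cin); column c*9 + (kj+1)*3 + (ki+1) holds the
// (ki, kj)-shifted image of channel c.
arma::mat im2col3(const arma::mat& padded, int h, int w) {
  int hp = h + 2;
  int cin = padded.n_cols;
  arma::mat cols(h * w, 9 * cin);
  for (int c = 0; c < cin; ++c) {
    const double* src = padded.colptr(c);
    for (int kj = -1; kj <= 1; ++kj) {
      for (int ki = -1; ki <= 1; ++ki) {
        double* dst = cols.colptr(c * 9 + (kj + 1) * 3 + (ki + 1));
        for (int j = 0; j < w; ++j)
          std::memcpy(dst + j * h,
                      src + (j + kj + 1) * hp + (ki + 1),
                      h * sizeof(double));
      }
    }
  }
  return cols;
}

// Adjoint: scatter-add patch-matrix gradients back onto channel images.
arma::mat col2im3(const arma::mat& dcols, int h, int w, int cin) {
  int hp = h + 2, wp = w + 2;
  arma::mat dpad(hp * wp, cin, arma::fill::zeros);
  for (int c = 0; c < cin; ++c) {
    double* dst = dpad.colptr(c);
    for (int kj = -1; kj <= 1; ++kj) {
      for (int ki = -1; ki <= 1; ++ki) {
        const double* src = dcols.colptr(c * 9 + (kj + 1) * 3 + (ki + 1));
        for (int j = 0; j < w; ++j) {
          double* d = dst + (j + kj + 1) * hp + (ki + 1);
          const double* s = src + j * h;
          for (int i = 0; i < h; ++i) d[i] += s[i];
        }
      }
    }
  }
  arma::mat dx(h * w, cin);
  for (int c = 0; c < cin; ++c) {
    const double* src = dpad.colptr(c);
    double* dst = dx.colptr(c);
    for (int j = 0; j < w; ++j)
      std::memcpy(dst + j * h, src + (j + 1) * hp + 1, h * sizeof(double));
  }
  return dx;
}

arma::mat maxpool2(const arma::mat& a, int h, int w, arma::umat& argmax) {
  int ho = h / 2, wo = w / 2, cc = a.n_cols;
  arma::mat y(ho * wo, cc);
  argmax.set_size(ho * wo, cc);
  for (int c = 0; c < cc; ++c) {
    const double* src = a.colptr(c);
    for (int j = 0; j < wo; ++j) {
      for (int i = 0; i < ho; ++i) {
        int base = 2 * j * h + 2 * i;
        int cand[4] = {base, base + 1, base + h, base + h + 1};
        int best = cand[0];
        for (int k = 1; k < 4; ++k)
          if (src[cand[k]] > src[best]) best = cand[k];
        y(j * ho + i, c) = src[best];
        argmax(j * ho + i, c) = best;
      }
    }
  }
  return y;
}

arma::mat maxpool2_back(const arma::mat& dy, const arma::umat& argmax,
                        int h, int w) {
  arma::mat dx(h * w, dy.n_cols, arma::fill::zeros);
  for (arma::uword c = 0; c < dy.n_cols; ++c)
    for (arma::uword p = 0; p < dy.n_rows; ++p)
      dx(argmax(p, c), c) += dy(p, c);
  return dx;
}

struct BranchCache {
  std::vector<arma::mat> cols; // patch matrix per conv layer
  std::vector<arma::mat> act;  // post-ReLU activation per conv layer
  std::vector<arma::umat> argmax;
  std::vector<int> hs, ws;     // spatial size entering each layer
  int final_h = 0, final_w = 0;
};

// Forward through one branch; returns the global-average-pooled vector.
arma::vec branch_forward(const arma::mat& input, int h0, int w0,
                         const std::vector<ConvLayer>& plan,
                         const std::vector<arma::mat>& W,
                         const std::vector<arma::vec>& b,
                         BranchCache* cache) {
  arma::mat x = input; // (h*w) x cin
  int h = h0, w = w0;
  for (size_t l = 0; l < plan.size(); ++l) {
    arma::mat cols = im2col3(pad1(x, h, w), h, w);
    arma::mat out = cols * W[l].t(); // (h*w) x cout
    out.each_row() += b[l].t();
    out.transform([](double v) { return v > 0 ? v : 0.0; }); // ReLU
    if (cache) {
      cache->cols.push_back(std::move(cols));
      cache->act.push_back(out);
      cache->hs.push_back(h);
      cache->ws.push_back(w);
    }
    if (plan[l].pool_after) {
      arma::umat am;
      arma::mat pooled = maxpool2(out, h, w, am);
      if (cache) cache->argmax.push_back(std::move(am));
      x = std::move(pooled);
      h /= 2; w /= 2;
    } else {
      x = std::move(out);
    }
  }
  if (cache) { cache->final_h = h; cache->final_w = w; }
  return arma::mean(x, 0).t(); // global average pool per channel
}

// Backward through one branch given the gradient of its pooled feature
// vector; accumulates weight gradients.
void branch_backward(const std::vector<ConvLayer>& plan,
                     const std::vector<arma::mat>& W,
                     const BranchCache& cache, const arma::vec& dfeat,
                     std::vector<arma::mat>& dW,
                     std::vector<arma::vec>& db) {
  int L = plan.size();
  int npix = cache.final_h * cache.final_w;
  arma::mat dx(npix, dfeat.n_elem);
  for (arma::uword c = 0; c < dfeat.n_elem; ++c)
    dx.col(c).fill(dfeat(c) / npix);
  int pool_idx = cache.argmax.size();
  for (int l = L - 1; l >= 0; --l) {
    int h = cache.hs[l], w = cache.ws[l];
    if (plan[l].pool_after) {
      --pool_idx;
      dx = maxpool2_back(dx, cache.argmax[pool_idx], h, w);
    }
    dx.elem(arma::find(cache.act[l] <= 0)).zeros(); // ReLU gate
    dW[l] += dx.t() * cache.cols[l];
    db[l] += arma::sum(dx, 0).t();
    if (l > 0) dx = col2im3(dx * W[l], h, w, plan[l].cin);
  }
}

struct Net {
  std::vector<ConvLayer> plan;
  std::vector<std::vector<arma::mat>> W; // [branch][layer]
  std::vector<std::vector<arma::vec>> b;
  arma::mat fc1_W, fc2_W;
  arma::vec fc1_b, fc2_b;
};

std::vector<ConvLayer> layer_plan(const IntegerVector& cin,
                                  const IntegerVector& cout,
                                  const LogicalVector& pool_after) {
  std::vector<ConvLayer> plan(cin.size());
  for (int l = 0; l < cin.size(); ++l)
    plan[l] = ConvLayer{cin[l], cout[l], pool_after[l] == TRUE};
  return plan;
}

Net unpack(const List& weights, const IntegerVector& cin,
           const IntegerVector& cout, const LogicalVector& pool_after) {
  Net net;
  net.plan = layer_plan(cin, cout, pool_after);
  List branches = weights["branches"];
  for (int bidx = 0; bidx < 4; ++bidx) {
    List br = branches[bidx];
    std::vector<arma::mat> Ws;
    std::vector<arma::vec> bs;
    for (int l = 0; l < br.size(); ++l) {
      List layer = br[l];
      Ws.push_back(as<arma::mat>(layer["W"]));
      bs.push_back(as<arma::vec>(layer["b"]));
    }
    net.W.push_back(std::move(Ws));
    net.b.push_back(std::move(bs));
  }
  net.fc1_W = as<arma::mat>(weights["fc1_W"]);
  net.fc1_b = as<arma::vec>(weights["fc1_b"]);
  net.fc2_W = as<arma::mat>(weights["fc2_W"]);
  net.fc2_b = as<arma::vec>(weights["fc2_b"]);
  return net;
}

List pack(const Net& net) {
  List branches(4);
  for (int bidx = 0; bidx < 4; ++bidx) {
    List br(net.W[bidx].size());
    for (size_t l = 0; l < net.W[bidx].size(); ++l)
      br[l] = List::create(_["W"] = net.W[bidx][l], _["b"] = net.b[bidx][l]);
    branches[bidx] = br;
  }
  return List::create(_["branches"] = branches,
                      _["fc1_W"] = net.fc1_W, _["fc1_b"] = net.fc1_b,
                      _["fc2_W"] = net.fc2_W, _["fc2_b"] = net.fc2_b);
}

// Branch input as an (h*w) x 1 matrix (one input channel per branch).
arma::mat get_input(const NumericVector& X, int h, int w, int branch,
                    int sample) {
  const double* base = X.begin() +
    (static_cast<size_t>(sample) * 4 + branch) * h * w;
  return arma::mat(const_cast<double*>(base), h * w, 1, /*copy*/ true);
}

arma::vec softmax(const arma::vec& z) {
  arma::vec e = arma::exp(z - z.max());
  return e / arma::accu(e);
}

arma::vec net_forward(const Net& net, const NumericVector& X, int h, int w,
                      int sample, std::vector<BranchCache>* caches,
                      arma::vec* concat_out, arma::vec* hid_out) {
  arma::vec concat(net.fc1_W.n_cols);
  int off = 0;
  for (int bidx = 0; bidx < 4; ++bidx) {
    BranchCache* cache = caches ? &((*caches)[bidx]) : nullptr;
    arma::vec feat = branch_forward(get_input(X, h, w, bidx, sample), h, w,
                                    net.plan, net.W[bidx], net.b[bidx],
                                    cache);
    concat.subvec(off, off + feat.n_elem - 1) = feat;
    off += feat.n_elem;
  }
  arma::vec hid = net.fc1_W * concat + net.fc1_b;
  hid.transform([](double v) { return v > 0 ? v : 0.0; });
  arma::vec scores = net.fc2_W * hid + net.fc2_b;
  if (concat_out) *concat_out = concat;
  if (hid_out) *hid_out = hid;
  return scores;
}

void adam_update(arma::mat& w, const arma::mat& g, arma::mat& m, arma::mat& v,
                 double lr, double b1, double b2, double eps, double bc1,
                 double bc2) {
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  w -= lr * (m / bc1) / (arma::sqrt(v / bc2) + eps);
}

} // namespace

// [[Rcpp::export]]
NumericMatrix cpp_cnn_predict(const List& weights, const NumericVector& X,
                              int h, int w, int n_samples,
                              const IntegerVector& cin,
                              const IntegerVector& cout,
                              const LogicalVector& pool_after) {
  Net net = unpack(weights, cin, cout, pool_after);
  int n_classes = net.fc2_W.n_rows;
  NumericMatrix out(n_samples, n_classes);
  for (int s = 0; s < n_samples; ++s) {
    arma::vec p = softmax(net_forward(net, X, h, w, s, nullptr, nullptr,
                                      nullptr));
    for (int k = 0; k < n_classes; ++k) out(s, k) = p(k);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_cnn_train(const List& weights, const NumericVector& X,
                   const IntegerVector& y, int h, int w, int n_samples,
                   const IntegerVector& cin, const IntegerVector& cout,
                   const LogicalVector& pool_after,
                   const IntegerMatrix& order, int batch_size, double lr,
                   double beta1, double beta2, double eps) {
  Net net = unpack(weights, cin, cout, pool_after);
  int epochs = order.nrow();
  int L = net.plan.size();

  // Adam state mirrors every weight tensor
  std::vector<std::vector<arma::mat>> mW(4), vW(4);
  std::vector<std::vector<arma::mat>> mb(4), vb(4);
  for (int bidx = 0; bidx < 4; ++bidx)
    for (int l = 0; l < L; ++l) {
      mW[bidx].push_back(arma::mat(arma::size(net.W[bidx][l]),
                                   arma::fill::zeros));
      vW[bidx].push_back(arma::mat(arma::size(net.W[bidx][l]),
                                   arma::fill::zeros));
      mb[bidx].push_back(arma::mat(net.b[bidx][l].n_elem, 1,
                                   arma::fill::zeros));
      vb[bidx].push_back(arma::mat(net.b[bidx][l].n_elem, 1,
                                   arma::fill::zeros));
    }
  arma::mat m_fc1W(arma::size(net.fc1_W), arma::fill::zeros), v_fc1W = m_fc1W;
  arma::mat m_fc2W(arma::size(net.fc2_W), arma::fill::zeros), v_fc2W = m_fc2W;
  arma::mat m_fc1b(net.fc1_b.n_elem, 1, arma::fill::zeros), v_fc1b = m_fc1b;
  arma::mat m_fc2b(net.fc2_b.n_elem, 1, arma::fill::zeros), v_fc2b = m_fc2b;

  NumericVector loss_trace(epochs);
  long step = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    double ep_loss = 0.0;
    int done = 0;
    while (done < n_samples) {
      int bs = std::min(batch_size, n_samples - done);
      std::vector<std::vector<arma::mat>> gW(4);
      std::vector<std::vector<arma::vec>> gb(4);
      for (int bidx = 0; bidx < 4; ++bidx)
        for (int l = 0; l < L; ++l) {
          gW[bidx].push_back(arma::mat(arma::size(net.W[bidx][l]),
                                       arma::fill::zeros));
          gb[bidx].push_back(arma::vec(net.b[bidx][l].n_elem,
                                       arma::fill::zeros));
        }
      arma::mat g_fc1W(arma::size(net.fc1_W), arma::fill::zeros);
      arma::mat g_fc2W(arma::size(net.fc2_W), arma::fill::zeros);
      arma::vec g_fc1b(net.fc1_b.n_elem, arma::fill::zeros);
      arma::vec g_fc2b(net.fc2_b.n_elem, arma::fill::zeros);

      for (int k = 0; k < bs; ++k) {
        int s = order(ep, done + k) - 1; // R-side 1-based
        std::vector<BranchCache> caches(4);
        arma::vec concat, hid;
        arma::vec scores = net_forward(net, X, h, w, s, &caches, &concat,
                                       &hid);
        arma::vec p = softmax(scores);
        if (!p.is_finite()) stop("CNN training diverged: non-finite loss");
        int cls = y[s] - 1;
        ep_loss += -std::log(std::max(p(cls), 1e-12));
        arma::vec dscore = p;
        dscore(cls) -= 1.0;
        dscore /= bs;
        g_fc2W += dscore * hid.t();
        g_fc2b += dscore;
        arma::vec dhid = net.fc2_W.t() * dscore;
        for (arma::uword ii = 0; ii < dhid.n_elem; ++ii)
          if (hid(ii) <= 0) dhid(ii) = 0;
        g_fc1W += dhid * concat.t();
        g_fc1b += dhid;
        arma::vec dconcat = net.fc1_W.t() * dhid;
        int off = 0;
        for (int bidx = 0; bidx < 4; ++bidx) {
          int nf = net.plan.back().cout;
          arma::vec dfeat = dconcat.subvec(off, off + nf - 1);
          off += nf;
          branch_backward(net.plan, net.W[bidx], caches[bidx], dfeat,
                          gW[bidx], gb[bidx]);
        }
      }

      ++step;
      double bc1 = 1 - std::pow(beta1, (double)step);
      double bc2 = 1 - std::pow(beta2, (double)step);
      for (int bidx = 0; bidx < 4; ++bidx)
        for (int l = 0; l < L; ++l) {
          adam_update(net.W[bidx][l], gW[bidx][l], mW[bidx][l], vW[bidx][l],
                      lr, beta1, beta2, eps, bc1, bc2);
          arma::mat gbm(gb[bidx][l]);
          arma::mat bm(net.b[bidx][l]);
          adam_update(bm, gbm, mb[bidx][l], vb[bidx][l], lr, beta1, beta2,
                      eps, bc1, bc2);
          net.b[bidx][l] = bm.col(0);
        }
      adam_update(net.fc1_W, g_fc1W, m_fc1W, v_fc1W, lr, beta1, beta2, eps,
                  bc1, bc2);
      adam_update(net.fc2_W, g_fc2W, m_fc2W, v_fc2W, lr, beta1, beta2, eps,
                  bc1, bc2);
      arma::mat b1m(net.fc1_b), g1m(g_fc1b), b2m(net.fc2_b), g2m(g_fc2b);
      adam_update(b1m, g1m, m_fc1b, v_fc1b, lr, beta1, beta2, eps, bc1, bc2);
      adam_update(b2m, g2m, m_fc2b, v_fc2b, lr, beta1, beta2, eps, bc1, bc2);
      net.fc1_b = b1m.col(0);
      net.fc2_b = b2m.col(0);
      done += bs;
    }
    loss_trace[ep] = ep_loss / n_samples;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["weights"] = pack(net), _["loss"] = loss_trace);
}
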
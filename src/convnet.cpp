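// Compact fully convolutional network: same-padded 2D convolutions evaluated
// as im2col + GEMM, with hand-derived backprop and an Adam optimizer.
// Feature maps are stored as (H*W) x C matrices; pixel p = i + j*H matches
// R's column-major matrix layout, so an R H x W matrix flattens directly.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::rowvec;

// Patch matrix for a k x k same-padded convolution. Offset slot
// o = (dj+r)*k + (di+r) holds input channel block o*C .. o*C+C-1, i.e. the
// input shifted by (di, dj) with zeros outside the image.
static void im2col(const mat& X, int H, int W, int k, mat& P) {
  const int r = k / 2;
  const int C = X.n_cols;
  P.zeros(X.n_rows, (arma::uword)k * k * C);
  if (k == 1) { P = X; return; }
  for (int dj = -r; dj <= r; ++dj) {
    for (int di = -r; di <= r; ++di) {
      const int o = (dj + r) * k + (di + r);
      const int i0 = std::max(0, -di), i1 = std::min(H - 1, H - 1 - di);
      if (i1 < i0) continue;
      const int j0 = std::max(0, -dj), j1 = std::min(W - 1, W - 1 - dj);
      for (int j = j0; j <= j1; ++j) {
        const int js = j + dj;
        P.submat(i0 + (arma::uword)j * H, (arma::uword)o * C,
                 i1 + (arma::uword)j * H, (arma::uword)o * C + C - 1) =
          X.rows(i0 + di + (arma::uword)js * H, i1 + di + (arma::uword)js * H);
      }
    }
  }
}

// Adjoint of im2col: scatter-add patch-space gradients back to the input.
static void col2im_acc(const mat& dP, int H, int W, int k, int C, mat& dX) {
  const int r = k / 2;
  dX.zeros(dP.n_rows, C);
  if (k == 1) { dX = dP; return; }
  for (int dj = -r; dj <= r; ++dj) {
    for (int di = -r; di <= r; ++di) {
      const int o = (dj + r) * k + (di + r);
      const int i0 = std::max(0, -di), i1 = std::min(H - 1, H - 1 - di);
      if (i1 < i0) continue;
      const int j0 = std::max(0, -dj), j1 = std::min(W - 1, W - 1 - dj);
      for (int j = j0; j <= j1; ++j) {
        const int js = j + dj;
        dX.rows(i0 + di + (arma::uword)js * H, i1 + di + (arma::uword)js * H) +=
          dP.submat(i0 + (arma::uword)j * H, (arma::uword)o * C,
                    i1 + (arma::uword)j * H, (arma::uword)o * C + C - 1);
      }
    }
  }
}

static std::vector<mat> as_mats(const List& L) {
  std::vector<mat> out;
  out.reserve(L.size());
  for (int i = 0; i < L.size(); ++i) {
    NumericMatrix m = L[i];
    out.emplace_back(m.begin(), m.nrow(), m.ncol());
  }
  return out;
}

static std::vector<rowvec> as_rowvecs(const List& L) {
  std::vector<rowvec> out;
  out.reserve(L.size());
  for (int i = 0; i < L.size(); ++i) {
    NumericVector v = L[i];
    out.emplace_back(rowvec(v.begin(), v.size()));
  }
  return out;
}

static List wrap_mats(const std::vector<mat>& v) {
  List out(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    NumericMatrix m(v[i].n_rows, v[i].n_cols);
    std::copy(v[i].begin(), v[i].end(), m.begin());
    out[i] = m;
  }
  return out;
}

static List wrap_rowvecs(const std::vector<rowvec>& v) {
  List out(v.size());
  for (size_t i = 0; i < v.size(); ++i)
    out[i] = NumericVector(v[i].begin(), v[i].end());
  return out;
}

// Forward through all layers: ReLU between, logistic sigmoid after the last.
// If caches are requested (training), P and post-activation A are kept.
static mat net_forward(const mat& x, int H, int W,
                       const std::vector<mat>& Ws,
                       const std::vector<rowvec>& bs,
                       const IntegerVector& ks,
                       std::vector<mat>* Pcache,
                       std::vector<mat>* Acache) {
  const int L = Ws.size();
  mat A = x, P;
  for (int l = 0; l < L; ++l) {
    im2col(A, H, W, ks[l], P);
    mat Z = P * Ws[l];
    Z.each_row() += bs[l];
    if (Pcache) Pcache->at(l) = P;
    if (l < L - 1) {
      Z.elem(arma::find(Z < 0.0)).zeros();   // ReLU
    } else {
      Z = 1.0 / (1.0 + arma::exp(-Z));       // sigmoid
    }
    A = Z;
    if (Acache) Acache->at(l) = A;
  }
  return A;
}

// [[Rcpp::export(name = ".cpp_forward")]]
NumericMatrix cpp_forward(NumericMatrix xflat, int H, int W,
                          List Ws_, List bs_, IntegerVector ks) {
  std::vector<mat> Ws = as_mats(Ws_);
  std::vector<rowvec> bs = as_rowvecs(bs_);
  mat x(xflat.begin(), xflat.nrow(), xflat.ncol());
  mat y = net_forward(x, H, W, Ws, bs, ks, nullptr, nullptr);
  NumericMatrix out(H, W);
  std::copy(y.begin(), y.end(), out.begin());
  return out;
}

// Run `order.size()` single-pair training iterations (batch size 1).
// BCE loss (predictions clamped to [eps_clip, 1-eps_clip] for the reported
// value), gradient through sigmoid+BCE taken in its stable fused form
// (p - t)/N, and an Adam update per iteration. Returns updated parameters,
// optimizer state and the per-iteration pre-update losses.
// [[Rcpp::export(name = ".cpp_train_chunk")]]
List cpp_train_chunk(List Ws_, List bs_, IntegerVector ks, List adam,
                     List inputs_, List targets_,
                     IntegerVector Hs, IntegerVector Wd,
                     IntegerVector order, double lr,
                     double beta1, double beta2, double eps) {
  const double eps_clip = 1e-7;
  std::vector<mat> Ws = as_mats(Ws_), mW = as_mats(adam["mW"]), vW = as_mats(adam["vW"]);
  std::vector<rowvec> bs = as_rowvecs(bs_), mb = as_rowvecs(adam["mb"]), vb = as_rowvecs(adam["vb"]);
  long t = as<double>(adam["t"]);
  std::vector<mat> inputs = as_mats(inputs_), targets = as_mats(targets_);
  const int L = Ws.size();
  const int niter = order.size();
  NumericVector losses(niter);

  std::vector<mat> P(L), A(L);
  for (int it = 0; it < niter; ++it) {
    const int idx = order[it] - 1;
    const int H = Hs[idx], W = Wd[idx];
    const mat& x = inputs[idx];
    const mat& tgt = targets[idx];
    const double N = (double)tgt.n_elem;

    mat out = net_forward(x, H, W, Ws, bs, ks, &P, &A);
    mat pc = arma::clamp(out, eps_clip, 1.0 - eps_clip);
    const double loss =
      -arma::accu(tgt % arma::log(pc) + (1.0 - tgt) % arma::log(1.0 - pc)) / N;
    if (!std::isfinite(loss))
      stop("non-finite training loss at iteration %d", it + 1);
    losses[it] = loss;

    // backward
    mat dZ = (out - tgt) / N;  // fused sigmoid + BCE gradient
    ++t;
    const double corr1 = 1.0 - std::pow(beta1, (double)t);
    const double corr2 = 1.0 - std::pow(beta2, (double)t);
    for (int l = L - 1; l >= 0; --l) {
      mat dW = P[l].t() * dZ;
      rowvec db = arma::sum(dZ, 0);
      mat dP;
      if (l > 0) {
        dP = dZ * Ws[l].t();
      }
      // Adam update for layer l
      mW[l] = beta1 * mW[l] + (1.0 - beta1) * dW;
      vW[l] = beta2 * vW[l] + (1.0 - beta2) * arma::square(dW);
      Ws[l] -= lr * (mW[l] / corr1) / (arma::sqrt(vW[l] / corr2) + eps);
      mb[l] = beta1 * mb[l] + (1.0 - beta1) * db;
      vb[l] = beta2 * vb[l] + (1.0 - beta2) * arma::square(db);
      bs[l] -= lr * (mb[l] / corr1) / (arma::sqrt(vb[l] / corr2) + eps);
      if (l > 0) {
        const int Cprev = A[l - 1].n_cols;
        mat dA;
        col2im_acc(dP, H, W, ks[l], Cprev, dA);
        // ReLU derivative from the cached activation
        dZ = dA % arma::conv_to<mat>::from(A[l - 1] > 0.0);
      }
    }
  }

  return List::create(
    _["W"] = wrap_mats(Ws), _["b"] = wrap_rowvecs(bs),
    _["adam"] = List::create(_["mW"] = wrap_mats(mW), _["vW"] = wrap_mats(vW),
                             _["mb"] = wrap_rowvecs(mb), _["vb"] = wrap_rowvecs(vb),
                             _["t"] = (double)t),
    _["losses"] = losses);
}
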
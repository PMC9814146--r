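// Compiled kernels for the CNN engine.
//
// Activations are [features x batch] matrices; an image tensor (H, W, C) is
// flattened column-major with the row index fastest, so "flatten" between
// the convolutional and fully connected stacks is a no-op. A convolution
// block (im2col convolution -> optional batch normalization -> rectifier ->
// optional 2x2 max pool) is fused into one forward and one backward call:
// the convolution result stays in the filter-major GEMM layout (f x HW*B),
// batch norm and the rectifier are evaluated on the fly inside the pooling
// loops, and the backward pass recomputes the GEMM from the cached block
// input instead of shipping multi-megabyte caches through the R heap every
// mini-batch (recomputation is bit-identical and the FLOPs are cheap next
// to the memory traffic they replace). GEMMs go through Armadillo and hence
// the same BLAS R uses. The fully connected stack lives in R; only its
// batch-norm and rectifier element-wise passes are compiled here.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#ifdef __GLIBC__
#include <malloc.h>
#endif
using namespace Rcpp;

// Training cycles multi-megabyte activation buffers every mini-batch; with
// glibc's default mmap threshold each one is mmap'd and munmap'd, so every
// iteration pays page faults for the same memory. Keeping large blocks on
// the heap lets the allocator reuse them.
// [[Rcpp::export(rng = false)]]
void tune_allocator_cpp() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
#endif
}

// idx: (k*k*C) x (H*W) 1-based im2col gather map into the flattened input
// image; sentinel npx+1 means "zero pad".
static arma::mat gather_patches(const arma::mat& X, const IntegerMatrix& idx) {
  const int npx = X.n_rows, B = X.n_cols;
  const int kkC = idx.nrow(), HW = idx.ncol();
  arma::mat A(kkC, (size_t)HW * B);
  for (int bb = 0; bb < B; ++bb) {
    const double* xb = X.colptr(bb);
    for (int p = 0; p < HW; ++p) {
      double* ac = A.colptr((size_t)p + (size_t)bb * HW);
      const int* ic = &idx(0, p);
      for (int r = 0; r < kkC; ++r) {
        const int v = ic[r];
        ac[r] = (v <= npx) ? xb[v - 1] : 0.0;
      }
    }
  }
  return A;
}

// Batch statistics per filter row of Z (bias folded in afterwards: adding
// the filter bias shifts the mean and leaves the variance unchanged).
static void filter_stats(const arma::mat& Z, const arma::vec& b,
                         arma::vec& mu, arma::vec& var) {
  const int f = Z.n_rows;
  const size_t n = Z.n_cols;
  arma::vec s(f, arma::fill::zeros), s2(f, arma::fill::zeros);
  for (size_t col = 0; col < n; ++col) {
    const double* zc = Z.colptr(col);
    for (int c = 0; c < f; ++c) { s[c] += zc[c]; s2[c] += zc[c] * zc[c]; }
  }
  mu = s / (double)n;
  var = arma::max(s2 / (double)n - mu % mu, arma::zeros<arma::vec>(f));
  mu += b;
}

// [[Rcpp::export(rng = false)]]
List block_fwd_cpp(const arma::mat& X, const IntegerMatrix& idx,
                   const arma::mat& W, const arma::vec& b,
                   bool use_bn, const arma::vec& gamma, const arma::vec& beta,
                   double eps, bool training,
                   const arma::vec& run_mean, const arma::vec& run_var,
                   bool use_pool, const IntegerMatrix& Q) {
  const int HW = idx.ncol(), f = W.n_rows, B = X.n_cols;
  arma::mat A = gather_patches(X, idx);
  arma::mat Z = W * A;                    // f x HW*B, bias not yet added
  arma::vec mu, var, invstd;
  if (use_bn) {
    if (training) filter_stats(Z, b, mu, var);
    else { mu = run_mean; var = run_var; }
    invstd = 1.0 / arma::sqrt(var + eps);
  }
  // activation at image-layout position (p + c*HW, bb)
  auto act_at = [&](int c, size_t col) {
    double v = Z(c, col) + b[c];
    if (use_bn) v = gamma[c] * ((v - mu[c]) * invstd[c]) + beta[c];
    return v > 0 ? v : 0.0;
  };
  if (use_pool) {
    const int m = Q.nrow();
    arma::mat out(m, B);
    IntegerMatrix amax(m, B);
    for (int bb = 0; bb < B; ++bb) {
      const size_t base = (size_t)bb * HW;
      double* oc = out.colptr(bb);
      for (int i = 0; i < m; ++i) {
        int arg = 0;
        double best = -1e300;
        for (int k = 0; k < 4; ++k) {
          const int a0 = Q(i, k) - 1;
          const double v = act_at(a0 / HW, base + a0 % HW);
          if (v > best) { best = v; arg = k; }
        }
        oc[i] = best;
        amax(i, bb) = arg;
      }
    }
    return List::create(_["out"] = out, _["amax"] = amax,
                        _["mu"] = mu, _["var"] = var);
  }
  arma::mat out((size_t)HW * f, B);
  for (int bb = 0; bb < B; ++bb) {
    const size_t base = (size_t)bb * HW;
    double* oc = out.colptr(bb);
    for (int c = 0; c < f; ++c) {
      for (int p = 0; p < HW; ++p) oc[p + (size_t)c * HW] = act_at(c, base + p);
    }
  }
  return List::create(_["out"] = out, _["amax"] = IntegerMatrix(0, 0),
                      _["mu"] = mu, _["var"] = var);
}

// Backward pass; recomputes the convolution GEMM from the cached input and
// reuses the forward pass's batch statistics and pooling argmax.
// [[Rcpp::export(rng = false)]]
List block_bwd_cpp(const arma::mat& X, const arma::mat& dOut,
                   const IntegerMatrix& idx,
                   const arma::mat& W, const arma::vec& b,
                   bool use_bn, const arma::vec& gamma, const arma::vec& beta,
                   double eps, const arma::vec& mu, const arma::vec& var,
                   bool use_pool, const IntegerMatrix& Q,
                   const IntegerMatrix& amax) {
  const int npx = X.n_rows, B = X.n_cols;
  const int HW = idx.ncol(), f = W.n_rows, kkC = idx.nrow();
  arma::mat A = gather_patches(X, idx);
  arma::mat Z = W * A;                    // f x HW*B, bias not added
  arma::vec invstd = use_bn ? arma::vec(1.0 / arma::sqrt(var + eps))
                            : arma::vec();
  auto preact = [&](int c, size_t col) { return Z(c, col) + b[c]; };
  auto relu_open = [&](int c, size_t col) {
    double v = preact(c, col);
    if (use_bn) v = gamma[c] * ((v - mu[c]) * invstd[c]) + beta[c];
    return v > 0;
  };

  // rectifier-gated upstream gradient, in filter layout (sparse when pooled)
  arma::mat dG(f, (size_t)HW * B, arma::fill::zeros);
  arma::vec dgamma(use_bn ? f : 0, arma::fill::zeros),
            dbeta(use_bn ? f : 0, arma::fill::zeros);
  if (use_pool) {
    const int m = Q.nrow();
    for (int bb = 0; bb < B; ++bb) {
      const size_t base = (size_t)bb * HW;
      const double* oc = dOut.colptr(bb);
      for (int i = 0; i < m; ++i) {
        const int a0 = Q(i, amax(i, bb)) - 1;
        const int c = a0 / HW;
        const size_t col = base + a0 % HW;
        if (relu_open(c, col)) {
          const double d = oc[i];
          dG(c, col) = d;
          if (use_bn) {
            dbeta[c] += d;
            dgamma[c] += d * ((preact(c, col) - mu[c]) * invstd[c]);
          }
        }
      }
    }
  } else {
    for (int bb = 0; bb < B; ++bb) {
      const size_t base = (size_t)bb * HW;
      const double* oc = dOut.colptr(bb);
      for (int c = 0; c < f; ++c) {
        for (int p = 0; p < HW; ++p) {
          const size_t col = base + p;
          if (relu_open(c, col)) {
            const double d = oc[p + (size_t)c * HW];
            dG(c, col) = d;
            if (use_bn) {
              dbeta[c] += d;
              dgamma[c] += d * ((preact(c, col) - mu[c]) * invstd[c]);
            }
          }
        }
      }
    }
  }

  // batch-norm backward turns dG into the gradient at the convolution
  // output; the mean-correction terms act on every position, not just the
  // pool-selected ones.
  arma::vec db(f, arma::fill::zeros);
  if (use_bn) {
    const double m = (double)HW * B;
    const size_t ncol = (size_t)HW * B;
    for (size_t col = 0; col < ncol; ++col) {
      double* gc = dG.colptr(col);
      const double* zc = Z.colptr(col);
      for (int c = 0; c < f; ++c) {
        const double xh = (zc[c] + b[c] - mu[c]) * invstd[c];
        gc[c] = invstd[c] * (gamma[c] * gc[c]
                             - gamma[c] * dbeta[c] / m
                             - xh * gamma[c] * dgamma[c] / m);
        db[c] += gc[c];
      }
    }
  } else {
    for (size_t col = 0, ncol = (size_t)HW * B; col < ncol; ++col) {
      const double* gc = dG.colptr(col);
      for (int c = 0; c < f; ++c) db[c] += gc[c];
    }
  }

  arma::mat dW = dG * A.t();
  arma::mat dA = W.t() * dG;
  arma::mat dX(npx, B, arma::fill::zeros);
  for (int bb = 0; bb < B; ++bb) {
    double* xb = dX.colptr(bb);
    for (int p = 0; p < HW; ++p) {
      const double* ac = dA.colptr((size_t)p + (size_t)bb * HW);
      const int* ic = &idx(0, p);
      for (int r = 0; r < kkC; ++r) {
        const int v = ic[r];
        if (v <= npx) xb[v - 1] += ac[r];
      }
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db,
                      _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// ---- standalone batch normalization (fully connected stack) ----
// Rows [c*group, (c+1)*group) share channel c's statistics; group is 1 for
// fully connected neurons.

static void channel_stats(const arma::mat& X, int C, int group,
                          arma::vec& mu, arma::vec& var) {
  const int B = X.n_cols;
  arma::vec s(C, arma::fill::zeros), s2(C, arma::fill::zeros);
  for (int bb = 0; bb < B; ++bb) {
    const double* xb = X.colptr(bb);
    for (int c = 0; c < C; ++c) {
      double a = 0, a2 = 0;
      const double* xr = xb + (size_t)c * group;
      for (int r = 0; r < group; ++r) { a += xr[r]; a2 += xr[r] * xr[r]; }
      s[c] += a; s2[c] += a2;
    }
  }
  const double m = (double)group * B;
  mu = s / m;
  var = arma::max(s2 / m - mu % mu, arma::zeros<arma::vec>(C));
}

// [[Rcpp::export(rng = false)]]
List bn_fwd_cpp(const arma::mat& X, int C, int group, const arma::vec& gamma,
                const arma::vec& beta, double eps, bool training,
                const arma::vec& run_mean, const arma::vec& run_var) {
  const int B = X.n_cols;
  arma::vec mu, var;
  if (training) channel_stats(X, C, group, mu, var);
  else { mu = run_mean; var = run_var; }
  arma::vec invstd = 1.0 / arma::sqrt(var + eps);
  arma::mat out(X.n_rows, B);
  for (int bb = 0; bb < B; ++bb) {
    const double* xb = X.colptr(bb);
    double* ob = out.colptr(bb);
    for (int c = 0; c < C; ++c) {
      const double mc = mu[c], ic = invstd[c], gc = gamma[c], bc = beta[c];
      const size_t off = (size_t)c * group;
      for (int r = 0; r < group; ++r) {
        ob[off + r] = gc * ((xb[off + r] - mc) * ic) + bc;
      }
    }
  }
  return List::create(_["out"] = out, _["mu"] = mu, _["var"] = var,
                      _["invstd"] = invstd);
}

// [[Rcpp::export(rng = false)]]
List bn_bwd_cpp(const arma::mat& dOut, const arma::mat& X,
                const arma::vec& mu, const arma::vec& invstd,
                const arma::vec& gamma, int group) {
  const int B = dOut.n_cols, C = invstd.n_elem;
  arma::vec dgamma(C, arma::fill::zeros), dbeta(C, arma::fill::zeros);
  for (int bb = 0; bb < B; ++bb) {
    const double* oc = dOut.colptr(bb);
    const double* xc = X.colptr(bb);
    for (int c = 0; c < C; ++c) {
      const double mc = mu[c], ic = invstd[c];
      const size_t off = (size_t)c * group;
      for (int r = 0; r < group; ++r) {
        dbeta[c] += oc[off + r];
        dgamma[c] += oc[off + r] * ((xc[off + r] - mc) * ic);
      }
    }
  }
  const double m = (double)group * B;
  arma::mat dX(dOut.n_rows, B);
  for (int bb = 0; bb < B; ++bb) {
    const double* oc = dOut.colptr(bb);
    const double* xc = X.colptr(bb);
    double* xb = dX.colptr(bb);
    for (int c = 0; c < C; ++c) {
      const double mc = mu[c], ic = invstd[c], gc = gamma[c];
      const double a1 = gc * dbeta[c] / m, a2 = gc * dgamma[c] / m;
      const size_t off = (size_t)c * group;
      for (int r = 0; r < group; ++r) {
        const double xh = (xc[off + r] - mc) * ic;
        xb[off + r] = ic * (gc * oc[off + r] - a1 - xh * a2);
      }
    }
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// ---- rectifier (fully connected stack) ----

// [[Rcpp::export(rng = false)]]
arma::mat relu_fwd_cpp(const arma::mat& X) {
  arma::mat out = X;
  for (size_t i = 0; i < out.n_elem; ++i) if (out[i] < 0) out[i] = 0.0;
  return out;
}

// [[Rcpp::export(rng = false)]]
arma::mat relu_bwd_cpp(const arma::mat& dOut, const arma::mat& out) {
  arma::mat dX(dOut.n_rows, dOut.n_cols);
  for (size_t i = 0; i < dOut.n_elem; ++i) {
    dX[i] = (out[i] > 0) ? dOut[i] : 0.0;
  }
  return dX;
}
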
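// Core of the depth-20 residual network: fully-convolutional forward pass
// and analytic gradients, organised as im2col + GEMM so BLAS carries the
// arithmetic. Layout conventions (shared with the R wrappers):
//   - a layer's weights are a (9*Cin) x Cout matrix; row index r encodes the
//     kernel tap (di, dj, c) as r = di + 3*dj + 9*c with di, dj in {0,1,2}
//     meaning source offset (di-1, dj-1) (column-major over a 3x3xCin array);
//   - images are H x W matrices (column-major, as in R); batches are
//     H x W x N cubes; feature maps H x W x C cubes;
//   - every convolution zero-pads by 1 px so spatial dims are preserved;
//   - hidden layers are followed by ReLU, the last layer is linear.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Fill `col` (HW x 9C) from feature cube `a` (H x W x C), zero padding 1 px.
static void im2col(const arma::cube& a, arma::mat& col) {
  const int H = a.n_rows, W = a.n_cols, C = a.n_slices;
  col.zeros(H * (arma::uword)W, 9 * (arma::uword)C);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < 3; ++dj) {
      for (int di = 0; di < 3; ++di) {
        double* dst = col.colptr(di + 3 * dj + 9 * c);
        const int i0 = std::max(0, 1 - di);        // valid output rows
        const int i1 = std::min(H, H + 1 - di);
        if (i1 <= i0) continue;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - 1;
          if (sj < 0 || sj >= W) continue;
          const double* src = a.slice_colptr(c, sj) + (i0 + di - 1);
          std::memcpy(dst + (arma::uword)j * H + i0, src,
                      sizeof(double) * (i1 - i0));
        }
      }
    }
  }
}

// Adjoint of im2col: accumulate `dcol` (HW x 9C) back into a gradient
// cube (H x W x C).
static void col2im(const arma::mat& dcol, arma::cube& da) {
  const int H = da.n_rows, W = da.n_cols, C = da.n_slices;
  da.zeros();
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < 3; ++dj) {
      for (int di = 0; di < 3; ++di) {
        const double* src = dcol.colptr(di + 3 * dj + 9 * c);
        const int i0 = std::max(0, 1 - di);
        const int i1 = std::min(H, H + 1 - di);
        if (i1 <= i0) continue;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - 1;
          if (sj < 0 || sj >= W) continue;
          double* dst = da.slice_colptr(c, sj) + (i0 + di - 1);
          const double* s = src + (arma::uword)j * H + i0;
          for (int i = 0; i < i1 - i0; ++i) dst[i] += s[i];
        }
      }
    }
  }
}

// One conv layer applied to cube `a`: returns H x W x Cout cube.
// `relu` applies the in-place rectifier after the bias.
static arma::cube conv_layer(const arma::cube& a, const arma::mat& Wm,
                             const arma::vec& b, bool relu, arma::mat& colbuf) {
  const int H = a.n_rows, W = a.n_cols;
  im2col(a, colbuf);
  arma::mat z = colbuf * Wm;                 // (HW x Cout)
  z.each_row() += b.t();
  if (relu) z.for_each([](double& v) { if (v < 0) v = 0; });
  // (HW x Cout) column-major is exactly an H x W x Cout cube
  return arma::cube(z.memptr(), H, W, Wm.n_cols);
}

// Forward pass of the whole network on a batch (H x W x N of single-channel
// images). Returns the residual prediction as an H x W x N cube.
// [[Rcpp::export]]
arma::cube cpp_vdsr_forward(List Wl, List bl, const arma::cube& x) {
  const int L = Wl.size();
  const int H = x.n_rows, W = x.n_cols, N = x.n_slices;
  arma::cube out(H, W, N);
  arma::mat colbuf;
  for (int n = 0; n < N; ++n) {
    arma::cube act(H, W, 1);
    act.slice(0) = x.slice(n);
    for (int l = 0; l < L; ++l) {
      arma::mat Wm = as<arma::mat>(Wl[l]);
      arma::vec b = as<arma::vec>(bl[l]);
      act = conv_layer(act, Wm, b, l < L - 1, colbuf);
    }
    out.slice(n) = act.slice(0);
  }
  return out;
}

// Loss 0.5 * mean((f(x) - r)^2) over the whole batch plus analytic gradients
// with respect to every weight matrix and bias.
// [[Rcpp::export]]
List cpp_vdsr_loss_grad(List Wl, List bl, const arma::cube& x,
                        const arma::cube& r) {
  const int L = Wl.size();
  const int H = x.n_rows, W = x.n_cols, N = x.n_slices;
  const double denom = (double)H * W * N;

  std::vector<arma::mat> Wm(L);
  std::vector<arma::vec> bv(L);
  for (int l = 0; l < L; ++l) {
    Wm[l] = as<arma::mat>(Wl[l]);
    bv[l] = as<arma::vec>(bl[l]);
  }
  std::vector<arma::mat> gW(L);
  std::vector<arma::vec> gb(L);
  for (int l = 0; l < L; ++l) {
    gW[l].zeros(Wm[l].n_rows, Wm[l].n_cols);
    gb[l].zeros(bv[l].n_elem);
  }

  double loss = 0.0;
  arma::mat colbuf;
  for (int n = 0; n < N; ++n) {
    // forward with cached post-activation maps (acts[0] is the input)
    std::vector<arma::cube> acts(L + 1);
    acts[0] = arma::cube(H, W, 1);
    acts[0].slice(0) = x.slice(n);
    for (int l = 0; l < L; ++l)
      acts[l + 1] = conv_layer(acts[l], Wm[l], bv[l], l < L - 1, colbuf);

    arma::mat diff = acts[L].slice(0) - r.slice(n);
    loss += 0.5 * arma::accu(arma::square(diff)) / denom;

    // backward: delta holds dLoss/d(pre-activation) as (HW x C)
    arma::mat delta(diff.memptr(), (arma::uword)H * W, 1);
    delta /= denom;
    for (int l = L - 1; l >= 0; --l) {
      im2col(acts[l], colbuf);
      gW[l] += colbuf.t() * delta;
      gb[l] += arma::sum(delta, 0).t();
      if (l > 0) {
        arma::mat dcol = delta * Wm[l].t();        // (HW x 9*Cin)
        arma::cube da(H, W, Wm[l].n_rows / 9);
        col2im(dcol, da);
        // ReLU mask of the producing layer's output
        const arma::cube& alc = acts[l];
        delta.set_size((arma::uword)H * W, da.n_slices);
        for (arma::uword c = 0; c < da.n_slices; ++c) {
          const double* av = alc.slice_colptr(c, 0);
          const double* dv = da.slice_colptr(c, 0);
          double* out = delta.colptr(c);
          for (arma::uword k = 0; k < (arma::uword)H * W; ++k)
            out[k] = (av[k] > 0) ? dv[k] : 0.0;
        }
      }
    }
  }

  List gWl(L), gbl(L);
  for (int l = 0; l < L; ++l) {
    gWl[l] = wrap(gW[l]);
    gbl[l] = wrap(gb[l]);
  }
  return List::create(_["loss"] = loss, _["gW"] = gWl, _["gb"] = gbl);
}
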
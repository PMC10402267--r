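#include <Rcpp.h>
using namespace Rcpp;

// Patch-gather / scatter primitives behind the 2D encoder layers.
// Convolutions are evaluated as GEMMs in R: Y = im2col(X) %*% matrix(W); the
// adjoint uses col2im. Column ordering matches R's column-major flattening
// of a (k, k, C) kernel array, so weights reshape with a plain matrix()
// call. The 3D decoder uses the direct kernels below instead: its finest
// level would materialize a (voxels x k^3 C) patch matrix whose repeated
// allocation dominates run time.

// [[Rcpp::export(name = ".im2col2d")]]
NumericMatrix im2col2d(NumericVector x, int H, int W, int C,
                       int k, int stride, int pad) {
  const int oh = (H + 2 * pad - k) / stride + 1;
  const int ow = (W + 2 * pad - k) / stride + 1;
  NumericMatrix cols(oh * ow, k * k * C);
  const double* px = REAL(x);
  double* pc = REAL(cols);
  const int nrow = oh * ow;
  for (int c = 0; c < C; ++c) {
    const double* plane = px + (R_xlen_t)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int col = ki + kj * k + c * k * k;
        double* dst = pc + (R_xlen_t)col * nrow;
        for (int oj = 0; oj < ow; ++oj) {
          const int j = oj * stride - pad + kj;
          const bool jin = (j >= 0 && j < W);
          for (int oi = 0; oi < oh; ++oi) {
            const int i = oi * stride - pad + ki;
            dst[oi + oj * oh] =
              (jin && i >= 0 && i < H) ? plane[i + j * H] : 0.0;
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export(name = ".col2im2d")]]
NumericVector col2im2d(NumericMatrix cols, int H, int W, int C,
                       int k, int stride, int pad) {
  const int oh = (H + 2 * pad - k) / stride + 1;
  const int ow = (W + 2 * pad - k) / stride + 1;
  NumericVector x((R_xlen_t)H * W * C);
  double* px = REAL(x);
  const double* pc = REAL(cols);
  const int nrow = oh * ow;
  for (int c = 0; c < C; ++c) {
    double* plane = px + (R_xlen_t)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int col = ki + kj * k + c * k * k;
        const double* src = pc + (R_xlen_t)col * nrow;
        for (int oj = 0; oj < ow; ++oj) {
          const int j = oj * stride - pad + kj;
          if (j < 0 || j >= W) continue;
          for (int oi = 0; oi < oh; ++oi) {
            const int i = oi * stride - pad + ki;
            if (i < 0 || i >= H) continue;
            plane[i + j * H] += src[oi + oj * oh];
          }
        }
      }
    }
  }
  return x;
}

// Direct stride-1 3D convolution kernels for the decoder. These avoid the
// large im2col patch matrices: the decoder's finest level would otherwise
// materialize a (voxels x k^3 C) buffer per step.

// [[Rcpp::export(name = ".conv3d_fwd")]]
NumericVector conv3d_fwd(NumericVector x, IntegerVector xd,
                         NumericVector w, NumericVector b,
                         int k, int pad) {
  const int H = xd[0], W = xd[1], D = xd[2], C = xd[3];
  const int cout = b.size();
  const int oh = H + 2 * pad - k + 1, ow = W + 2 * pad - k + 1,
            od = D + 2 * pad - k + 1;
  NumericVector y((R_xlen_t)oh * ow * od * cout);
  double* py = REAL(y);
  const double* px = REAL(x);
  const double* pw = REAL(w);
  for (int co = 0; co < cout; ++co) {
    double* yc = py + (R_xlen_t)co * oh * ow * od;
    for (R_xlen_t t = 0; t < (R_xlen_t)oh * ow * od; ++t) yc[t] = b[co];
    for (int ci = 0; ci < C; ++ci) {
      const double* xc = px + (R_xlen_t)ci * H * W * D;
      for (int kd = 0; kd < k; ++kd) {
        for (int kj = 0; kj < k; ++kj) {
          for (int ki = 0; ki < k; ++ki) {
            const double wv =
              pw[ki + kj * k + kd * k * k + ci * k * k * k +
                 (R_xlen_t)co * k * k * k * C];
            if (wv == 0.0) continue;
            for (int odx = 0; odx < od; ++odx) {
              const int d = odx - pad + kd;
              if (d < 0 || d >= D) continue;
              for (int oj = 0; oj < ow; ++oj) {
                const int j = oj - pad + kj;
                if (j < 0 || j >= W) continue;
                const double* xs = xc + (R_xlen_t)j * H + (R_xlen_t)d * H * W;
                double* ys = yc + (R_xlen_t)oj * oh + (R_xlen_t)odx * oh * ow;
                const int i0 = pad - ki > 0 ? pad - ki : 0;
                const int i1 = H + pad - ki < oh ? H + pad - ki : oh;
                for (int oi = i0; oi < i1; ++oi)
                  ys[oi] += wv * xs[oi - pad + ki];
              }
            }
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(oh, ow, od, cout);
  return y;
}

// gradient w.r.t. the input: scatter dY back through the kernel
// [[Rcpp::export(name = ".conv3d_bwd_x")]]
NumericVector conv3d_bwd_x(NumericVector dy, IntegerVector yd,
                           NumericVector w, IntegerVector xd,
                           int k, int pad) {
  const int H = xd[0], W = xd[1], D = xd[2], C = xd[3];
  const int oh = yd[0], ow = yd[1], od = yd[2], cout = yd[3];
  NumericVector dx((R_xlen_t)H * W * D * C);
  double* pdx = REAL(dx);
  const double* pdy = REAL(dy);
  const double* pw = REAL(w);
  for (int co = 0; co < cout; ++co) {
    const double* gc = pdy + (R_xlen_t)co * oh * ow * od;
    for (int ci = 0; ci < C; ++ci) {
      double* xc = pdx + (R_xlen_t)ci * H * W * D;
      for (int kd = 0; kd < k; ++kd) {
        for (int kj = 0; kj < k; ++kj) {
          for (int ki = 0; ki < k; ++ki) {
            const double wv =
              pw[ki + kj * k + kd * k * k + ci * k * k * k +
                 (R_xlen_t)co * k * k * k * C];
            if (wv == 0.0) continue;
            for (int odx = 0; odx < od; ++odx) {
              const int d = odx - pad + kd;
              if (d < 0 || d >= D) continue;
              for (int oj = 0; oj < ow; ++oj) {
                const int j = oj - pad + kj;
                if (j < 0 || j >= W) continue;
                double* xs = xc + (R_xlen_t)j * H + (R_xlen_t)d * H * W;
                const double* gs = gc + (R_xlen_t)oj * oh +
                                   (R_xlen_t)odx * oh * ow;
                const int i0 = pad - ki > 0 ? pad - ki : 0;
                const int i1 = H + pad - ki < oh ? H + pad - ki : oh;
                for (int oi = i0; oi < i1; ++oi)
                  xs[oi - pad + ki] += wv * gs[oi];
              }
            }
          }
        }
      }
    }
  }
  return dx;
}

// gradient w.r.t. the weights (and bias as column sums done in R)
// [[Rcpp::export(name = ".conv3d_bwd_w")]]
NumericVector conv3d_bwd_w(NumericVector x, IntegerVector xd,
                           NumericVector dy, IntegerVector yd,
                           int k, int pad) {
  const int H = xd[0], W = xd[1], D = xd[2], C = xd[3];
  const int oh = yd[0], ow = yd[1], od = yd[2], cout = yd[3];
  NumericVector dw((R_xlen_t)k * k * k * C * cout);
  double* pdw = REAL(dw);
  const double* px = REAL(x);
  const double* pdy = REAL(dy);
  for (int co = 0; co < cout; ++co) {
    const double* gc = pdy + (R_xlen_t)co * oh * ow * od;
    for (int ci = 0; ci < C; ++ci) {
      const double* xc = px + (R_xlen_t)ci * H * W * D;
      for (int kd = 0; kd < k; ++kd) {
        for (int kj = 0; kj < k; ++kj) {
          for (int ki = 0; ki < k; ++ki) {
            double acc = 0.0;
            for (int odx = 0; odx < od; ++odx) {
              const int d = odx - pad + kd;
              if (d < 0 || d >= D) continue;
              for (int oj = 0; oj < ow; ++oj) {
                const int j = oj - pad + kj;
                if (j < 0 || j >= W) continue;
                const double* xs = xc + (R_xlen_t)j * H + (R_xlen_t)d * H * W;
                const double* gs = gc + (R_xlen_t)oj * oh +
                                   (R_xlen_t)odx * oh * ow;
                const int i0 = pad - ki > 0 ? pad - ki : 0;
                const int i1 = H + pad - ki < oh ? H + pad - ki : oh;
                for (int oi = i0; oi < i1; ++oi)
                  acc += gs[oi] * xs[oi - pad + ki];
              }
            }
            pdw[ki + kj * k + kd * k * k + ci * k * k * k +
                (R_xlen_t)co * k * k * k * C] = acc;
          }
        }
      }
    }
  }
  dw.attr("dim") = IntegerVector::create(k, k, k, C, cout);
  return dw;
}

// In-place parameter-set arithmetic. The parameter set is ~5M doubles;
// allocating fresh copies for every optimizer step dominates run time on a
// single core, so accumulation and the Adam update mutate their arguments.

// [[Rcpp::export(name = ".axpy_inplace")]]
void axpy_inplace(List a, List b, double s) {
  const int n = a.size();
  for (int i = 0; i < n; ++i) {
    NumericVector av = a[i], bv = b[i];
    double* pa = REAL(av);
    const double* pb = REAL(bv);
    const R_xlen_t m = av.size();
    for (R_xlen_t j = 0; j < m; ++j) pa[j] += s * pb[j];
  }
}

// [[Rcpp::export(name = ".scale_inplace")]]
void scale_inplace(List a, double s) {
  const int n = a.size();
  for (int i = 0; i < n; ++i) {
    NumericVector av = a[i];
    double* pa = REAL(av);
    const R_xlen_t m = av.size();
    for (R_xlen_t j = 0; j < m; ++j) pa[j] *= s;
  }
}

// [[Rcpp::export(name = ".adam_inplace")]]
void adam_inplace(List p, List g, List m, List v, int t, double lr,
                  double beta1, double beta2, double eps) {
  const double bc1 = 1.0 - std::pow(beta1, t);
  const double bc2 = 1.0 - std::pow(beta2, t);
  const int n = p.size();
  for (int i = 0; i < n; ++i) {
    NumericVector pv = p[i], gv = g[i], mv = m[i], vv = v[i];
    double* pp = REAL(pv);
    const double* pg = REAL(gv);
    double* pm = REAL(mv);
    double* pvv = REAL(vv);
    const R_xlen_t len = pv.size();
    for (R_xlen_t j = 0; j < len; ++j) {
      pm[j] = beta1 * pm[j] + (1.0 - beta1) * pg[j];
      pvv[j] = beta2 * pvv[j] + (1.0 - beta2) * pg[j] * pg[j];
      const double mhat = pm[j] / bc1;
      const double vhat = pvv[j] / bc2;
      pp[j] -= lr * mhat / (std::sqrt(vhat) + eps);
    }
  }
}

// Composite MAE + forward-difference gradient loss and its gradient w.r.t.
// `pred`, fused in one pass over the volume.
// [[Rcpp::export(name = ".loss_grad")]]
List loss_grad(NumericVector pred, NumericVector ref, IntegerVector dims,
               double w, bool want_grad) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  const double* pp = REAL(pred);
  const double* pr = REAL(ref);
  NumericVector grad(want_grad ? n : 0);
  double* pg = want_grad ? REAL(grad) : nullptr;
  double mae = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double d = pp[i] - pr[i];
    mae += std::fabs(d);
    if (want_grad) pg[i] = (d > 0) - (d < 0);
  }
  mae /= n;
  if (want_grad) for (R_xlen_t i = 0; i < n; ++i) pg[i] /= n;

  const int nd[3] = { n1, n2, n3 };
  const R_xlen_t stride[3] = { 1, n1, (R_xlen_t)n1 * n2 };
  int naxes = 0;
  for (int a = 0; a < 3; ++a) if (nd[a] >= 2) ++naxes;
  double gl = 0.0;
  if (w > 0.0 && naxes > 0) {
    for (int a = 0; a < 3; ++a) {
      if (nd[a] < 2) continue;
      const R_xlen_t st = stride[a];
      const R_xlen_t ne = n / nd[a] * (nd[a] - 1);
      double acc = 0.0;
      const double sc = w / ((double)ne * naxes);
      for (int k3 = 0; k3 < n3; ++k3) {
        if (a == 2 && k3 == n3 - 1) continue;
        for (int k2 = 0; k2 < n2; ++k2) {
          if (a == 1 && k2 == n2 - 1) continue;
          const R_xlen_t base = (R_xlen_t)k2 * n1 + (R_xlen_t)k3 * n1 * n2;
          const int i1 = (a == 0) ? n1 - 1 : n1;
          for (int k1 = 0; k1 < i1; ++k1) {
            const R_xlen_t i = base + k1;
            const double e = (pp[i + st] - pr[i + st]) - (pp[i] - pr[i]);
            acc += std::fabs(e);
            if (want_grad) {
              const double s = ((e > 0) - (e < 0)) * sc;
              pg[i + st] += s;
              pg[i] -= s;
            }
          }
        }
      }
      gl += acc / ne;
    }
    gl /= naxes;
  }
  List out = List::create(Named("loss") = mae + w * gl);
  if (want_grad) {
    grad.attr("dim") = dims;
    out["grad"] = grad;
  }
  return out;
}
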
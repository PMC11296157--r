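// Small 3-level 3D U-Net with hand-written forward/backward passes and a
// Keras-style SGD (momentum, Nesterov, 1/(1+decay*t) learning-rate decay).
// Tensors use R's column-major volume layout: a (z, y, x)-indexed array of
// dim (Z, Y, X) stores voxel (z, y, x) at z + Z*(y + Y*x); channels are
// stacked as [c][volume]. Convolutions are 3x3x3, zero ("same") padding.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

namespace {

struct Dims {
  int Z, Y, X;
  long n() const { return (long)Z * Y * X; }
};

inline long vidx(int z, int y, int x, const Dims& d) {
  return (long)z + (long)d.Z * ((long)y + (long)d.Y * x);
}

typedef std::vector<double> Vec;

// out[oc] = b[oc] + sum_ic W[oc][ic] (*) in[ic], 3x3x3 same padding.
// W layout: [oc][ic][kz+1][ky+1][kx+1] flattened, k = (kz+1)*9+(ky+1)*3+(kx+1)
void conv3_fwd(const Vec& in, Vec& out, const double* W, const double* b,
               int IC, int OC, const Dims& d) {
  long n = d.n();
  out.assign((size_t)OC * n, 0.0);
  for (int oc = 0; oc < OC; ++oc) {
    double* o = &out[(size_t)oc * n];
    for (long i = 0; i < n; ++i) o[i] = b[oc];
    for (int ic = 0; ic < IC; ++ic) {
      const double* xch = &in[(size_t)ic * n];
      const double* w = W + ((size_t)oc * IC + ic) * 27;
      for (int x = 0; x < d.X; ++x)
        for (int y = 0; y < d.Y; ++y)
          for (int z = 0; z < d.Z; ++z) {
            double s = 0.0;
            int k = 0;
            for (int dz = -1; dz <= 1; ++dz) {
              int zz = z + dz;
              for (int dy = -1; dy <= 1; ++dy) {
                int yy = y + dy;
                for (int dx = -1; dx <= 1; ++dx, ++k) {
                  int xx = x + dx;
                  if (zz < 0 || zz >= d.Z || yy < 0 || yy >= d.Y ||
                      xx < 0 || xx >= d.X)
                    continue;
                  s += w[k] * xch[vidx(zz, yy, xx, d)];
                }
              }
            }
            o[vidx(z, y, x, d)] += s;
          }
    }
  }
}

void conv3_bwd(const Vec& in, const Vec& gout, const double* W, double* gW,
               double* gb, Vec& gin, int IC, int OC, const Dims& d) {
  long n = d.n();
  gin.assign((size_t)IC * n, 0.0);
  for (int oc = 0; oc < OC; ++oc) {
    const double* go = &gout[(size_t)oc * n];
    double s = 0.0;
    for (long i = 0; i < n; ++i) s += go[i];
    gb[oc] += s;
    for (int ic = 0; ic < IC; ++ic) {
      const double* xch = &in[(size_t)ic * n];
      double* gx = &gin[(size_t)ic * n];
      const double* w = W + ((size_t)oc * IC + ic) * 27;
      double* gw = gW + ((size_t)oc * IC + ic) * 27;
      for (int x = 0; x < d.X; ++x)
        for (int y = 0; y < d.Y; ++y)
          for (int z = 0; z < d.Z; ++z) {
            double g = go[vidx(z, y, x, d)];
            if (g == 0.0) continue;
            int k = 0;
            for (int dz = -1; dz <= 1; ++dz) {
              int zz = z + dz;
              for (int dy = -1; dy <= 1; ++dy) {
                int yy = y + dy;
                for (int dx = -1; dx <= 1; ++dx, ++k) {
                  int xx = x + dx;
                  if (zz < 0 || zz >= d.Z || yy < 0 || yy >= d.Y ||
                      xx < 0 || xx >= d.X)
                    continue;
                  long ii = vidx(zz, yy, xx, d);
                  gw[k] += g * xch[ii];
                  gx[ii] += g * w[k];
                }
              }
            }
          }
    }
  }
}

void conv1_fwd(const Vec& in, Vec& out, const double* W, const double* b,
               int IC, int OC, const Dims& d) {
  long n = d.n();
  out.assign((size_t)OC * n, 0.0);
  for (int oc = 0; oc < OC; ++oc) {
    double* o = &out[(size_t)oc * n];
    for (long i = 0; i < n; ++i) o[i] = b[oc];
    for (int ic = 0; ic < IC; ++ic) {
      const double w = W[(size_t)oc * IC + ic];
      const double* xch = &in[(size_t)ic * n];
      for (long i = 0; i < n; ++i) o[i] += w * xch[i];
    }
  }
}

void conv1_bwd(const Vec& in, const Vec& gout, const double* W, double* gW,
               double* gb, Vec& gin, int IC, int OC, const Dims& d) {
  long n = d.n();
  gin.assign((size_t)IC * n, 0.0);
  for (int oc = 0; oc < OC; ++oc) {
    const double* go = &gout[(size_t)oc * n];
    double s = 0.0;
    for (long i = 0; i < n; ++i) s += go[i];
    gb[oc] += s;
    for (int ic = 0; ic < IC; ++ic) {
      const double* xch = &in[(size_t)ic * n];
      double* gx = &gin[(size_t)ic * n];
      double gw = 0.0;
      const double w = W[(size_t)oc * IC + ic];
      for (long i = 0; i < n; ++i) {
        gw += go[i] * xch[i];
        gx[i] += go[i] * w;
      }
      gW[(size_t)oc * IC + ic] += gw;
    }
  }
}

void relu_fwd(Vec& a) {
  for (size_t i = 0; i < a.size(); ++i)
    if (a[i] < 0) a[i] = 0;
}

// g *= 1[a > 0], where a is the post-activation value
void relu_bwd(Vec& g, const Vec& a) {
  for (size_t i = 0; i < g.size(); ++i)
    if (a[i] <= 0) g[i] = 0;
}

void pool_fwd(const Vec& in, Vec& out, std::vector<long>& arg, int C,
              const Dims& d, Dims& dh) {
  dh.Z = d.Z / 2; dh.Y = d.Y / 2; dh.X = d.X / 2;
  long n = d.n(), nh = dh.n();
  out.assign((size_t)C * nh, 0.0);
  arg.assign((size_t)C * nh, 0);
  for (int c = 0; c < C; ++c) {
    const double* xch = &in[(size_t)c * n];
    double* o = &out[(size_t)c * nh];
    long* a = &arg[(size_t)c * nh];
    for (int x = 0; x < dh.X; ++x)
      for (int y = 0; y < dh.Y; ++y)
        for (int z = 0; z < dh.Z; ++z) {
          double best = -1e300;
          long bi = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                long ii = vidx(2 * z + dz, 2 * y + dy, 2 * x + dx, d);
                if (xch[ii] > best) { best = xch[ii]; bi = ii; }
              }
          long oi = vidx(z, y, x, dh);
          o[oi] = best;
          a[oi] = bi;
        }
  }
}

void pool_bwd(const Vec& gout, const std::vector<long>& arg, Vec& gin, int C,
              const Dims& d, const Dims& dh) {
  long n = d.n(), nh = dh.n();
  gin.assign((size_t)C * n, 0.0);
  for (int c = 0; c < C; ++c) {
    const double* go = &gout[(size_t)c * nh];
    const long* a = &arg[(size_t)c * nh];
    double* gi = &gin[(size_t)c * n];
    for (long i = 0; i < nh; ++i) gi[a[i]] += go[i];
  }
}

void upsample_fwd(const Vec& in, Vec& out, int C, const Dims& dh,
                  const Dims& d) {
  long n = d.n(), nh = dh.n();
  out.assign((size_t)C * n, 0.0);
  for (int c = 0; c < C; ++c) {
    const double* xch = &in[(size_t)c * nh];
    double* o = &out[(size_t)c * n];
    for (int x = 0; x < d.X; ++x)
      for (int y = 0; y < d.Y; ++y)
        for (int z = 0; z < d.Z; ++z)
          o[vidx(z, y, x, d)] = xch[vidx(z / 2, y / 2, x / 2, dh)];
  }
}

void upsample_bwd(const Vec& gout, Vec& gin, int C, const Dims& dh,
                  const Dims& d) {
  long n = d.n(), nh = dh.n();
  gin.assign((size_t)C * nh, 0.0);
  for (int c = 0; c < C; ++c) {
    const double* go = &gout[(size_t)c * n];
    double* gi = &gin[(size_t)c * nh];
    for (int x = 0; x < d.X; ++x)
      for (int y = 0; y < d.Y; ++y)
        for (int z = 0; z < d.Z; ++z)
          gi[vidx(z / 2, y / 2, x / 2, dh)] += go[vidx(z, y, x, d)];
  }
}

struct Params {
  // 11 conv layers: W and b pointers plus channel counts
  std::vector<double*> W, b;
  std::vector<int> IC, OC;
};

const int N_CONV = 11;

void layer_channels(int C, std::vector<int>& IC, std::vector<int>& OC) {
  int ic[N_CONV] = {1, C, C, 2 * C, 2 * C, 4 * C, 6 * C, 2 * C, 3 * C, C, C};
  int oc[N_CONV] = {C, C, 2 * C, 2 * C, 4 * C, 4 * C, 2 * C, 2 * C, C, C, 3};
  IC.assign(ic, ic + N_CONV);
  OC.assign(oc, oc + N_CONV);
}

// Wrap an R list of 22 numeric vectors (W1, b1, ..., W11, b11) without copy
Params wrap_params(List weights, int C) {
  Params p;
  layer_channels(C, p.IC, p.OC);
  if (weights.size() != 2 * N_CONV)
    stop("weights list must hold %d elements (W and b per conv layer)",
         2 * N_CONV);
  for (int l = 0; l < N_CONV; ++l) {
    NumericVector W = weights[2 * l];
    NumericVector b = weights[2 * l + 1];
    size_t wlen = (l == N_CONV - 1)
        ? (size_t)p.IC[l] * p.OC[l]
        : (size_t)p.IC[l] * p.OC[l] * 27;
    if ((size_t)W.size() != wlen || b.size() != p.OC[l])
      stop("weight shapes do not match base channel count %d (layer %d)",
           C, l + 1);
    p.W.push_back(REAL(W));
    p.b.push_back(REAL(b));
  }
  return p;
}

struct Activations {
  Dims d0, d1, d2;
  Vec a1, a2, p1, a3, a4, p2, a5, a6, u2, cat2, a7, a8, u1, cat1, a9, a10,
      logits, prob;
  std::vector<long> arg1, arg2;
};

// Forward pass; fills act and returns softmax probabilities in act.prob
void forward(const Params& p, int C, const Vec& x0, const Dims& d0,
             Activations& act) {
  act.d0 = d0;
  conv3_fwd(x0, act.a1, p.W[0], p.b[0], 1, C, d0);
  relu_fwd(act.a1);
  conv3_fwd(act.a1, act.a2, p.W[1], p.b[1], C, C, d0);
  relu_fwd(act.a2);
  pool_fwd(act.a2, act.p1, act.arg1, C, d0, act.d1);
  conv3_fwd(act.p1, act.a3, p.W[2], p.b[2], C, 2 * C, act.d1);
  relu_fwd(act.a3);
  conv3_fwd(act.a3, act.a4, p.W[3], p.b[3], 2 * C, 2 * C, act.d1);
  relu_fwd(act.a4);
  pool_fwd(act.a4, act.p2, act.arg2, 2 * C, act.d1, act.d2);
  conv3_fwd(act.p2, act.a5, p.W[4], p.b[4], 2 * C, 4 * C, act.d2);
  relu_fwd(act.a5);
  conv3_fwd(act.a5, act.a6, p.W[5], p.b[5], 4 * C, 4 * C, act.d2);
  relu_fwd(act.a6);
  upsample_fwd(act.a6, act.u2, 4 * C, act.d2, act.d1);
  long n1 = act.d1.n();
  act.cat2.assign((size_t)6 * C * n1, 0.0);
  std::memcpy(&act.cat2[0], &act.u2[0], sizeof(double) * 4 * C * n1);
  std::memcpy(&act.cat2[(size_t)4 * C * n1], &act.a4[0],
              sizeof(double) * 2 * C * n1);
  conv3_fwd(act.cat2, act.a7, p.W[6], p.b[6], 6 * C, 2 * C, act.d1);
  relu_fwd(act.a7);
  conv3_fwd(act.a7, act.a8, p.W[7], p.b[7], 2 * C, 2 * C, act.d1);
  relu_fwd(act.a8);
  upsample_fwd(act.a8, act.u1, 2 * C, act.d1, d0);
  long n0 = d0.n();
  act.cat1.assign((size_t)3 * C * n0, 0.0);
  std::memcpy(&act.cat1[0], &act.u1[0], sizeof(double) * 2 * C * n0);
  std::memcpy(&act.cat1[(size_t)2 * C * n0], &act.a2[0],
              sizeof(double) * C * n0);
  conv3_fwd(act.cat1, act.a9, p.W[8], p.b[8], 3 * C, C, d0);
  relu_fwd(act.a9);
  conv3_fwd(act.a9, act.a10, p.W[9], p.b[9], C, C, d0);
  relu_fwd(act.a10);
  conv1_fwd(act.a10, act.logits, p.W[10], p.b[10], C, 3, d0);
  // softmax over the 3 class channels
  act.prob.assign((size_t)3 * n0, 0.0);
  for (long i = 0; i < n0; ++i) {
    double m = act.logits[i];
    for (int c = 1; c < 3; ++c)
      m = std::max(m, act.logits[(size_t)c * n0 + i]);
    double s = 0.0;
    for (int c = 0; c < 3; ++c) {
      double e = std::exp(act.logits[(size_t)c * n0 + i] - m);
      act.prob[(size_t)c * n0 + i] = e;
      s += e;
    }
    for (int c = 0; c < 3; ++c) act.prob[(size_t)c * n0 + i] /= s;
  }
}

// Class-weighted voxel-wise cross-entropy, normalized by the total
// weight in the patch (cw = (1,1,1) gives the plain mean).
double ce_loss(const Activations& act, const int* lab, const double* cw) {
  long n0 = act.d0.n();
  double loss = 0.0, wsum = 0.0;
  for (long i = 0; i < n0; ++i) {
    double pr = act.prob[(size_t)lab[i] * n0 + i];
    loss -= cw[lab[i]] * std::log(std::max(pr, 1e-12));
    wsum += cw[lab[i]];
  }
  return loss / std::max(wsum, 1e-12);
}

// Backward pass from weighted mean cross-entropy; accumulates into g
void backward(const Params& p, Params& g, int C, const Vec& x0,
              const int* lab, const Activations& act, const double* cw,
              double scale) {
  const Dims& d0 = act.d0;
  const Dims& d1 = act.d1;
  const Dims& d2 = act.d2;
  long n0 = d0.n(), n1 = d1.n();
  Vec glog((size_t)3 * n0);
  double wsum = 0.0;
  for (long i = 0; i < n0; ++i) wsum += cw[lab[i]];
  double w = scale / std::max(wsum, 1e-12);
  for (long i = 0; i < n0; ++i)
    for (int c = 0; c < 3; ++c)
      glog[(size_t)c * n0 + i] =
          w * cw[lab[i]] *
          (act.prob[(size_t)c * n0 + i] - (lab[i] == c ? 1.0 : 0.0));
  Vec ga10, ga9, gcat1, gu1, ga8, ga7, gcat2, gu2, ga6, ga5, gp2, ga4, ga3,
      gp1, ga2, ga1, gx0, tmp;
  conv1_bwd(act.a10, glog, p.W[10], g.W[10], g.b[10], ga10, C, 3, d0);
  relu_bwd(ga10, act.a10);
  conv3_bwd(act.a9, ga10, p.W[9], g.W[9], g.b[9], ga9, C, C, d0);
  relu_bwd(ga9, act.a9);
  conv3_bwd(act.cat1, ga9, p.W[8], g.W[8], g.b[8], gcat1, 3 * C, C, d0);
  gu1.assign(gcat1.begin(), gcat1.begin() + (size_t)2 * C * n0);
  ga2.assign(gcat1.begin() + (size_t)2 * C * n0, gcat1.end());  // skip grad
  upsample_bwd(gu1, ga8, 2 * C, d1, d0);
  relu_bwd(ga8, act.a8);
  conv3_bwd(act.a7, ga8, p.W[7], g.W[7], g.b[7], ga7, 2 * C, 2 * C, d1);
  relu_bwd(ga7, act.a7);
  conv3_bwd(act.cat2, ga7, p.W[6], g.W[6], g.b[6], gcat2, 6 * C, 2 * C, d1);
  gu2.assign(gcat2.begin(), gcat2.begin() + (size_t)4 * C * n1);
  ga4.assign(gcat2.begin() + (size_t)4 * C * n1, gcat2.end());  // skip grad
  upsample_bwd(gu2, ga6, 4 * C, d2, d1);
  relu_bwd(ga6, act.a6);
  conv3_bwd(act.a5, ga6, p.W[5], g.W[5], g.b[5], ga5, 4 * C, 4 * C, d2);
  relu_bwd(ga5, act.a5);
  conv3_bwd(act.p2, ga5, p.W[4], g.W[4], g.b[4], gp2, 2 * C, 4 * C, d2);
  pool_bwd(gp2, act.arg2, tmp, 2 * C, d1, d2);
  for (size_t i = 0; i < ga4.size(); ++i) ga4[i] += tmp[i];
  relu_bwd(ga4, act.a4);
  conv3_bwd(act.a3, ga4, p.W[3], g.W[3], g.b[3], ga3, 2 * C, 2 * C, d1);
  relu_bwd(ga3, act.a3);
  conv3_bwd(act.p1, ga3, p.W[2], g.W[2], g.b[2], gp1, C, 2 * C, d1);
  pool_bwd(gp1, act.arg1, tmp, C, d0, d1);
  for (size_t i = 0; i < ga2.size(); ++i) ga2[i] += tmp[i];
  relu_bwd(ga2, act.a2);
  conv3_bwd(act.a1, ga2, p.W[1], g.W[1], g.b[1], ga1, C, C, d0);
  relu_bwd(ga1, act.a1);
  conv3_bwd(x0, ga1, p.W[0], g.W[0], g.b[0], gx0, 1, C, d0);
}

Dims as_dims(IntegerVector d) {
  if (d.size() != 3) stop("dims must have length 3");
  Dims out;
  out.Z = d[0]; out.Y = d[1]; out.X = d[2];
  if (out.Z % 4 || out.Y % 4 || out.X % 4)
    stop("patch dimensions must be divisible by 4 (two pooling levels)");
  return out;
}

}  // namespace

// [[Rcpp::export]]
List unet_alloc_grads(int C) {
  std::vector<int> IC, OC;
  layer_channels(C, IC, OC);
  List out(2 * N_CONV);
  for (int l = 0; l < N_CONV; ++l) {
    size_t wlen = (l == N_CONV - 1) ? (size_t)IC[l] * OC[l]
                                    : (size_t)IC[l] * OC[l] * 27;
    out[2 * l] = NumericVector(wlen);
    out[2 * l + 1] = NumericVector(OC[l]);
  }
  return out;
}

// [[Rcpp::export]]
double unet_loss_cpp(List weights, NumericVector grey, IntegerVector lab,
                     IntegerVector patch_dim, int C,
                     NumericVector class_weights) {
  Dims d0 = as_dims(patch_dim);
  Params p = wrap_params(weights, C);
  Vec x0(grey.begin(), grey.end());
  Activations act;
  forward(p, C, x0, d0, act);
  return ce_loss(act, INTEGER(lab), REAL(class_weights));
}

// [[Rcpp::export]]
List unet_grad_cpp(List weights, NumericVector grey, IntegerVector lab,
                   IntegerVector patch_dim, int C,
                   NumericVector class_weights) {
  Dims d0 = as_dims(patch_dim);
  Params p = wrap_params(weights, C);
  List gl = unet_alloc_grads(C);
  Params g = wrap_params(gl, C);
  Vec x0(grey.begin(), grey.end());
  Activations act;
  forward(p, C, x0, d0, act);
  double loss = ce_loss(act, INTEGER(lab), REAL(class_weights));
  backward(p, g, C, x0, INTEGER(lab), act, REAL(class_weights), 1.0);
  return List::create(_["loss"] = loss, _["grads"] = gl);
}

// One epoch of mini-batch SGD over pre-extracted patches. `order` is a
// 1-based permutation of patch indices (shuffled in R with R's RNG so the
// whole run is reproducible from one seed). Weights and velocities are
// updated in place and returned together with the iteration counter and
// mean patch loss.
// [[Rcpp::export]]
List unet_sgd_epoch(List weights, List velocity, NumericVector grey_patches,
                    IntegerVector lab_patches, IntegerVector patch_dim,
                    IntegerVector order, int batch_size, int C, double lr,
                    double momentum, double decay, bool nesterov,
                    double iter0, NumericVector class_weights) {
  if (class_weights.size() != 3) stop("class_weights must have length 3");
  const double* cw = REAL(class_weights);
  Dims d0 = as_dims(patch_dim);
  long n = d0.n();
  int n_patches = order.size();
  if ((long)grey_patches.size() < (long)n_patches * n)
    stop("patch buffer shorter than implied by 'order'");
  Params p = wrap_params(weights, C);
  Params v = wrap_params(velocity, C);
  List gl = unet_alloc_grads(C);
  Params g = wrap_params(gl, C);
  double iter = iter0;
  double total_loss = 0.0;
  Activations act;
  const double* gp = REAL(grey_patches);
  const int* lp = INTEGER(lab_patches);
  for (int start = 0; start < n_patches; start += batch_size) {
    int bsz = std::min(batch_size, n_patches - start);
    for (int l = 0; l < N_CONV; ++l) {
      size_t wlen = (l == N_CONV - 1) ? (size_t)p.IC[l] * p.OC[l]
                                      : (size_t)p.IC[l] * p.OC[l] * 27;
      std::memset(g.W[l], 0, sizeof(double) * wlen);
      std::memset(g.b[l], 0, sizeof(double) * p.OC[l]);
    }
    for (int bi = 0; bi < bsz; ++bi) {
      long pi = order[start + bi] - 1;
      Vec x0(gp + pi * n, gp + (pi + 1) * n);
      const int* lab = lp + pi * n;
      forward(p, C, x0, d0, act);
      total_loss += ce_loss(act, lab, cw);
      backward(p, g, C, x0, lab, act, cw, 1.0 / bsz);
    }
    double lr_t = lr / (1.0 + decay * iter);
    iter += 1.0;
    for (int l = 0; l < N_CONV; ++l) {
      size_t wlen = (l == N_CONV - 1) ? (size_t)p.IC[l] * p.OC[l]
                                      : (size_t)p.IC[l] * p.OC[l] * 27;
      for (size_t i = 0; i < wlen; ++i) {
        double vi = momentum * v.W[l][i] - lr_t * g.W[l][i];
        v.W[l][i] = vi;
        p.W[l][i] += nesterov ? momentum * vi - lr_t * g.W[l][i] : vi;
      }
      for (int i = 0; i < p.OC[l]; ++i) {
        double vi = momentum * v.b[l][i] - lr_t * g.b[l][i];
        v.b[l][i] = vi;
        p.b[l][i] += nesterov ? momentum * vi - lr_t * g.b[l][i] : vi;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["weights"] = weights, _["velocity"] = velocity,
                      _["iter"] = iter,
                      _["loss"] = total_loss / std::max(n_patches, 1));
}

// Patch-stitched whole-volume inference: softmax class scores are
// accumulated over every overlapping patch; each voxel's class is the
// argmax of the accumulated scores (ties to the lowest class code).
// [[Rcpp::export]]
IntegerVector unet_predict_cpp(List weights, NumericVector vol,
                               IntegerVector vol_dim,
                               IntegerVector patch_dim, int stride, int C) {
  Dims dv;
  dv.Z = vol_dim[0]; dv.Y = vol_dim[1]; dv.X = vol_dim[2];
  Dims d0 = as_dims(patch_dim);
  if (dv.Z < d0.Z || dv.Y < d0.Y || dv.X < d0.X)
    stop("volume (%dx%dx%d) smaller than patch (%dx%dx%d)", dv.Z, dv.Y,
         dv.X, d0.Z, d0.Y, d0.X);
  Params p = wrap_params(weights, C);
  long nv = dv.n();
  Vec scores((size_t)3 * nv, 0.0);
  std::vector<int> starts[3];
  int vd[3] = {dv.Z, dv.Y, dv.X}, pd[3] = {d0.Z, d0.Y, d0.X};
  for (int a = 0; a < 3; ++a) {
    for (int s = 0; s + pd[a] <= vd[a]; s += stride)
      starts[a].push_back(s);
    if (starts[a].back() + pd[a] < vd[a])
      starts[a].push_back(vd[a] - pd[a]);  // snap final window to boundary
  }
  long n0 = d0.n();
  Vec x0((size_t)n0);
  Activations act;
  const double* vp = REAL(vol);
  for (size_t iz = 0; iz < starts[0].size(); ++iz)
    for (size_t iy = 0; iy < starts[1].size(); ++iy)
      for (size_t ix = 0; ix < starts[2].size(); ++ix) {
        int oz = starts[0][iz], oy = starts[1][iy], ox = starts[2][ix];
        for (int x = 0; x < d0.X; ++x)
          for (int y = 0; y < d0.Y; ++y)
            for (int z = 0; z < d0.Z; ++z)
              x0[vidx(z, y, x, d0)] = vp[vidx(oz + z, oy + y, ox + x, dv)];
        forward(p, C, x0, d0, act);
        for (int c = 0; c < 3; ++c)
          for (int x = 0; x < d0.X; ++x)
            for (int y = 0; y < d0.Y; ++y)
              for (int z = 0; z < d0.Z; ++z)
                scores[(size_t)c * nv + vidx(oz + z, oy + y, ox + x, dv)] +=
                    act.prob[(size_t)c * n0 + vidx(z, y, x, d0)];
        Rcpp::checkUserInterrupt();
      }
  IntegerVector out(nv);
  for (long i = 0; i < nv; ++i) {
    int best = 0;
    double bv = scores[i];
    for (int c = 1; c < 3; ++c)
      if (scores[(size_t)c * nv + i] > bv) {
        bv = scores[(size_t)c * nv + i];
        best = c;
      }
    out[i] = best;
  }
  return out;
}

// Trilinear resampling of a (z, y, x) volume (align-corners convention)
// [[Rcpp::export]]
NumericVector resize_trilinear_cpp(NumericVector vol, IntegerVector from,
                                   IntegerVector to) {
  Dims df, dt;
  df.Z = from[0]; df.Y = from[1]; df.X = from[2];
  dt.Z = to[0]; dt.Y = to[1]; dt.X = to[2];
  NumericVector out(dt.n());
  const double* v = REAL(vol);
  double* o = REAL(out);
  double sz = dt.Z > 1 ? (double)(df.Z - 1) / (dt.Z - 1) : 0.0;
  double sy = dt.Y > 1 ? (double)(df.Y - 1) / (dt.Y - 1) : 0.0;
  double sx = dt.X > 1 ? (double)(df.X - 1) / (dt.X - 1) : 0.0;
  for (int x = 0; x < dt.X; ++x)
    for (int y = 0; y < dt.Y; ++y)
      for (int z = 0; z < dt.Z; ++z) {
        double fz = z * sz, fy = y * sy, fx = x * sx;
        int z0 = (int)fz, y0 = (int)fy, x0 = (int)fx;
        int z1 = std::min(z0 + 1, df.Z - 1);
        int y1 = std::min(y0 + 1, df.Y - 1);
        int x1 = std::min(x0 + 1, df.X - 1);
        double wz = fz - z0, wy = fy - y0, wx = fx - x0;
        double c00 = v[vidx(z0, y0, x0, df)] * (1 - wz) +
                     v[vidx(z1, y0, x0, df)] * wz;
        double c10 = v[vidx(z0, y1, x0, df)] * (1 - wz) +
                     v[vidx(z1, y1, x0, df)] * wz;
        double c01 = v[vidx(z0, y0, x1, df)] * (1 - wz) +
                     v[vidx(z1, y0, x1, df)] * wz;
        double c11 = v[vidx(z0, y1, x1, df)] * (1 - wz) +
                     v[vidx(z1, y1, x1, df)] * wz;
        double c0 = c00 * (1 - wy) + c10 * wy;
        double c1 = c01 * (1 - wy) + c11 * wy;
        o[vidx(z, y, x, dt)] = c0 * (1 - wx) + c1 * wx;
      }
  return out;
}

// Nearest-neighbour resampling for label volumes
// [[Rcpp::export]]
IntegerVector resize_nearest_cpp(IntegerVector vol, IntegerVector from,
                                 IntegerVector to) {
  Dims df, dt;
  df.Z = from[0]; df.Y = from[1]; df.X = from[2];
  dt.Z = to[0]; dt.Y = to[1]; dt.X = to[2];
  IntegerVector out(dt.n());
  const int* v = INTEGER(vol);
  int* o = INTEGER(out);
  double sz = dt.Z > 1 ? (double)(df.Z - 1) / (dt.Z - 1) : 0.0;
  double sy = dt.Y > 1 ? (double)(df.Y - 1) / (dt.Y - 1) : 0.0;
  double sx = dt.X > 1 ? (double)(df.X - 1) / (dt.X - 1) : 0.0;
  for (int x = 0; x < dt.X; ++x)
    for (int y = 0; y < dt.Y; ++y)
      for (int z = 0; z < dt.Z; ++z) {
        int z0 = (int)(z * sz + 0.5), y0 = (int)(y * sy + 0.5),
            x0 = (int)(x * sx + 0.5);
        o[vidx(z, y, x, dt)] = v[vidx(std::min(z0, df.Z - 1),
                                      std::min(y0, df.Y - 1),
                                      std::min(x0, df.X - 1), df)];
      }
  return out;
}

// For each row of A, index (1-based) of the nearest row of B; ties go to
// the lowest index. Brute force, adequate at the package's point counts.
// [[Rcpp::export]]
IntegerVector nn_index_cpp(NumericMatrix A, NumericMatrix B) {
  int na = A.nrow(), nb = B.nrow();
  if (A.ncol() != 3 || B.ncol() != 3) stop("point matrices must be n x 3");
  IntegerVector out(na);
  for (int i = 0; i < na; ++i) {
    double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    double best = R_PosInf;
    int bi = 0;
    for (int j = 0; j < nb; ++j) {
      double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) { best = d; bi = j; }
    }
    out[i] = bi + 1;
  }
  return out;
}
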
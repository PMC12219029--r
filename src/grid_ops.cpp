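// Grid utilities: 4D multilinear prolongation and its transpose (multigrid
// decomposition), 3D resampling between arbitrary grids, an exact squared
// Euclidean distance transform with anisotropic spacing, and a Gibbs sampler
// for spatially correlated Gaussian noise.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Endpoint-aligned linear interpolation weights mapping an axis of size `nin`
// onto size `nout`: fine node i sits at coarse coordinate i*(nin-1)/(nout-1).
// Exact on constants and on linear ramps; degenerate axes clamp.
static void axis_weights(int nin, int nout,
                         std::vector<int>& i0, std::vector<int>& i1,
                         std::vector<double>& w1) {
  i0.resize(nout); i1.resize(nout); w1.resize(nout);
  for (int i = 0; i < nout; ++i) {
    if (nin == 1 || nout == 1) { i0[i] = 0; i1[i] = 0; w1[i] = 0.0; continue; }
    double pos = (double)i * (double)(nin - 1) / (double)(nout - 1);
    int lo = (int)std::floor(pos);
    if (lo > nin - 2) lo = nin - 2;
    i0[i] = lo; i1[i] = lo + 1; w1[i] = pos - lo;
  }
}

// Expand one axis of a 4D array from size na to fa by linear interpolation.
// The array is viewed as [pre, na, post] with `pre` fastest-varying.
static void expand_axis(const double* in, double* out, R_xlen_t pre, int na,
                        int fa, R_xlen_t post,
                        const std::vector<int>& i0, const std::vector<int>& i1,
                        const std::vector<double>& w1) {
  for (R_xlen_t p = 0; p < post; ++p) {
    const double* inp = in + p * na * pre;
    double* outp = out + p * fa * pre;
    for (int f = 0; f < fa; ++f) {
      const double w = w1[f];
      const double* s0 = inp + (R_xlen_t)i0[f] * pre;
      const double* s1 = inp + (R_xlen_t)i1[f] * pre;
      double* d = outp + (R_xlen_t)f * pre;
      if (w == 0.0) {
        std::copy(s0, s0 + pre, d);
      } else {
        const double omw = 1.0 - w;
        for (R_xlen_t q = 0; q < pre; ++q) d[q] = omw * s0[q] + w * s1[q];
      }
    }
  }
}

// Adjoint of expand_axis: scatter-add a fine gradient back to the coarse axis.
static void reduce_axis(const double* g, double* out, R_xlen_t pre, int na,
                        int fa, R_xlen_t post,
                        const std::vector<int>& i0, const std::vector<int>& i1,
                        const std::vector<double>& w1) {
  std::fill(out, out + pre * na * post, 0.0);
  for (R_xlen_t p = 0; p < post; ++p) {
    double* outp = out + p * na * pre;
    const double* gp = g + p * fa * pre;
    for (int f = 0; f < fa; ++f) {
      const double w = w1[f];
      const double omw = 1.0 - w;
      double* d0 = outp + (R_xlen_t)i0[f] * pre;
      double* d1 = outp + (R_xlen_t)i1[f] * pre;
      const double* s = gp + (R_xlen_t)f * pre;
      if (w == 0.0) {
        for (R_xlen_t q = 0; q < pre; ++q) d0[q] += s[q];
      } else {
        for (R_xlen_t q = 0; q < pre; ++q) {
          d0[q] += omw * s[q];
          d1[q] += w * s[q];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_interp4(NumericVector coarse, IntegerVector cdim, IntegerVector fdim) {
  std::vector<int> a0[4], a1[4];
  std::vector<double> w[4];
  for (int d = 0; d < 4; ++d) axis_weights(cdim[d], fdim[d], a0[d], a1[d], w[d]);
  R_xlen_t fsize = (R_xlen_t)fdim[0] * fdim[1] * fdim[2] * fdim[3];
  std::vector<double> buf_a(coarse.begin(), coarse.end()), buf_b;
  int dims[4] = {cdim[0], cdim[1], cdim[2], cdim[3]};
  for (int d = 0; d < 4; ++d) {
    if (dims[d] == fdim[d]) continue;
    R_xlen_t pre = 1, post = 1;
    for (int q = 0; q < d; ++q) pre *= dims[q];
    for (int q = d + 1; q < 4; ++q) post *= dims[q];
    buf_b.resize(pre * fdim[d] * post);
    expand_axis(buf_a.data(), buf_b.data(), pre, dims[d], fdim[d], post,
                a0[d], a1[d], w[d]);
    dims[d] = fdim[d];
    buf_a.swap(buf_b);
  }
  NumericVector out(fsize);
  std::copy(buf_a.begin(), buf_a.end(), out.begin());
  return out;
}

// Transpose of cpp_interp4: pulls a fine-grid gradient back to the coarse grid.
// [[Rcpp::export]]
NumericVector cpp_interp4_adj(NumericVector gfine, IntegerVector fdim, IntegerVector cdim) {
  std::vector<int> a0[4], a1[4];
  std::vector<double> w[4];
  for (int d = 0; d < 4; ++d) axis_weights(cdim[d], fdim[d], a0[d], a1[d], w[d]);
  std::vector<double> buf_a(gfine.begin(), gfine.end()), buf_b;
  int dims[4] = {fdim[0], fdim[1], fdim[2], fdim[3]};
  for (int d = 3; d >= 0; --d) {
    if (dims[d] == cdim[d]) continue;
    R_xlen_t pre = 1, post = 1;
    for (int q = 0; q < d; ++q) pre *= dims[q];
    for (int q = d + 1; q < 4; ++q) post *= dims[q];
    buf_b.resize(pre * cdim[d] * post);
    reduce_axis(buf_a.data(), buf_b.data(), pre, cdim[d], dims[d], post,
                a0[d], a1[d], w[d]);
    dims[d] = cdim[d];
    buf_a.swap(buf_b);
  }
  NumericVector out((R_xlen_t)cdim[0] * cdim[1] * cdim[2] * cdim[3]);
  std::copy(buf_a.begin(), buf_a.end(), out.begin());
  return out;
}

// 3D resampling between endpoint-aligned grids; trilinear for continuous
// volumes, nearest-neighbor for masks/labels.
// [[Rcpp::export]]
NumericVector cpp_resample3(NumericVector vol, IntegerVector idim, IntegerVector odim,
                            bool nearest) {
  std::vector<int> a0[3], a1[3];
  std::vector<double> w[3];
  for (int d = 0; d < 3; ++d) axis_weights(idim[d], odim[d], a0[d], a1[d], w[d]);
  const int ix = idim[0], ixy = idim[0] * idim[1];
  NumericVector out((R_xlen_t)odim[0] * odim[1] * odim[2]);
  R_xlen_t p = 0;
  for (int k = 0; k < odim[2]; ++k)
    for (int j = 0; j < odim[1]; ++j)
      for (int i = 0; i < odim[0]; ++i, ++p) {
        if (nearest) {
          const int kk = (w[2][k] >= 0.5) ? a1[2][k] : a0[2][k];
          const int jj = (w[1][j] >= 0.5) ? a1[1][j] : a0[1][j];
          const int ii = (w[0][i] >= 0.5) ? a1[0][i] : a0[0][i];
          out[p] = vol[ii + jj * ix + (R_xlen_t)kk * ixy];
        } else {
          double acc = 0.0;
          for (int bk = 0; bk < 2; ++bk) {
            const double pk = bk ? w[2][k] : 1.0 - w[2][k];
            if (pk == 0.0) continue;
            const R_xlen_t ok = (R_xlen_t)(bk ? a1[2][k] : a0[2][k]) * ixy;
            for (int bj = 0; bj < 2; ++bj) {
              const double pj = pk * (bj ? w[1][j] : 1.0 - w[1][j]);
              if (pj == 0.0) continue;
              const R_xlen_t oj = ok + (bj ? a1[1][j] : a0[1][j]) * ix;
              acc += pj * ((1.0 - w[0][i]) * vol[oj + a0[0][i]] + w[0][i] * vol[oj + a1[0][i]]);
            }
          }
          out[p] = acc;
        }
      }
  return out;
}

// One-dimensional squared distance transform (Felzenszwalb & Huttenlocher)
// on samples at coordinates x_i = i*h.
static void dt1d(const double* f, int n, double h, double* d,
                 std::vector<int>& v, std::vector<double>& z) {
  v.resize(n); z.resize(n + 1);
  int q = 0;
  v[0] = 0; z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int i = 1; i < n; ++i) {
    const double xi = i * h, fi = f[i];
    double s;
    while (true) {
      const double xq = v[q] * h;
      s = ((fi + xi * xi) - (f[v[q]] + xq * xq)) / (2.0 * (xi - xq));
      if (s <= z[q]) { --q; } else break;
    }
    ++q;
    v[q] = i; z[q] = s; z[q + 1] = std::numeric_limits<double>::infinity();
  }
  q = 0;
  for (int i = 0; i < n; ++i) {
    const double xi = i * h;
    while (z[q + 1] < xi) ++q;
    const double dx = xi - v[q] * h;
    d[i] = dx * dx + f[v[q]];
  }
}

// Squared Euclidean distance (mm^2) to the nearest TRUE voxel, honoring
// anisotropic spacing. Voxels of the set itself get 0; if the set is empty
// all distances are +Inf.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(IntegerVector mask, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  // large finite sentinel instead of Inf so parabola intersections stay
  // well-defined; the R wrapper maps anything at this scale back to Inf
  const double INF = 1e30;
  NumericVector d((R_xlen_t)nx * ny * nz);
  for (R_xlen_t v = 0; v < d.size(); ++v) d[v] = mask[v] ? 0.0 : INF;
  std::vector<int> vbuf;
  std::vector<double> zbuf, line, out;
  const int nmax = std::max(nx, std::max(ny, nz));
  line.resize(nmax); out.resize(nmax);
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      double* row = d.begin() + (R_xlen_t)(j + ny * k) * nx;
      dt1d(row, nx, spacing[0], out.data(), vbuf, zbuf);
      std::copy(out.begin(), out.begin() + nx, row);
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) line[j] = d[i + nx * (j + ny * k)];
      dt1d(line.data(), ny, spacing[1], out.data(), vbuf, zbuf);
      for (int j = 0; j < ny; ++j) d[i + nx * (j + ny * k)] = out[j];
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) line[k] = d[i + nx * (j + ny * k)];
      dt1d(line.data(), nz, spacing[2], out.data(), vbuf, zbuf);
      for (int k = 0; k < nz; ++k) d[i + nx * (j + ny * k)] = out[k];
    }
  return d;
}

// Gibbs sampler for a Gaussian Markov random field: raster sweeps drawing each
// voxel from Normal(coupling * mean(6-neighborhood), sigma^2). Uses R's RNG so
// set.seed() makes fields reproducible. coupling = 0 gives i.i.d. noise.
// [[Rcpp::export]]
NumericVector cpp_gibbs(IntegerVector dim, double coupling, double sigma, int nsweeps) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector x((R_xlen_t)nx * ny * nz);  // zero-initialized
  for (int sweep = 0; sweep < nsweeps; ++sweep) {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const R_xlen_t v = i + nx * (j + (R_xlen_t)ny * k);
          double s = 0.0; int c = 0;
          if (i > 0)      { s += x[v - 1]; ++c; }
          if (i + 1 < nx) { s += x[v + 1]; ++c; }
          if (j > 0)      { s += x[v - nx]; ++c; }
          if (j + 1 < ny) { s += x[v + nx]; ++c; }
          if (k > 0)      { s += x[v - (R_xlen_t)nx * ny]; ++c; }
          if (k + 1 < nz) { s += x[v + (R_xlen_t)nx * ny]; ++c; }
          const double mean = (c > 0) ? coupling * s / c : 0.0;
          x[v] = mean + sigma * norm_rand();
        }
  }
  return x;
}
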
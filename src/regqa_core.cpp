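#include <Rcpp.h>
using namespace Rcpp;

// Trilinear resampling of a moving volume onto a reference grid under the
// affine map y = A p + b from reference physical space (mm) into moving
// physical space. Points falling outside the moving grid get `background`.
// [[Rcpp::export]]
NumericVector resample_affine_cpp(NumericVector mdata, IntegerVector mdim,
                                  NumericVector mspacing, NumericVector morigin,
                                  IntegerVector rdim, NumericVector rspacing,
                                  NumericVector rorigin, NumericMatrix A,
                                  NumericVector b, double background) {
  const int nx = mdim[0], ny = mdim[1], nz = mdim[2];
  const int rx = rdim[0], ry = rdim[1], rz = rdim[2];
  NumericVector out((R_xlen_t)rx * ry * rz);
  const double a11 = A(0, 0), a12 = A(0, 1), a13 = A(0, 2);
  const double a21 = A(1, 0), a22 = A(1, 1), a23 = A(1, 2);
  const double a31 = A(2, 0), a32 = A(2, 1), a33 = A(2, 2);
  const double *md = mdata.begin();
  double *od = out.begin();
  R_xlen_t idx = 0;
  for (int k = 0; k < rz; ++k) {
    const double pz = rorigin[2] + k * rspacing[2];
    for (int j = 0; j < ry; ++j) {
      const double py = rorigin[1] + j * rspacing[1];
      for (int i = 0; i < rx; ++i, ++idx) {
        const double px = rorigin[0] + i * rspacing[0];
        const double yx = a11 * px + a12 * py + a13 * pz + b[0];
        const double yy = a21 * px + a22 * py + a23 * pz + b[1];
        const double yz = a31 * px + a32 * py + a33 * pz + b[2];
        const double u = (yx - morigin[0]) / mspacing[0];
        const double v = (yy - morigin[1]) / mspacing[1];
        const double w = (yz - morigin[2]) / mspacing[2];
        if (u < 0 || v < 0 || w < 0 ||
            u > nx - 1 || v > ny - 1 || w > nz - 1) {
          od[idx] = background;
          continue;
        }
        int i0 = (int)std::floor(u), j0 = (int)std::floor(v),
            k0 = (int)std::floor(w);
        if (i0 > nx - 2) i0 = nx - 2;
        if (j0 > ny - 2) j0 = ny - 2;
        if (k0 > nz - 2) k0 = nz - 2;
        if (i0 < 0) i0 = 0;
        if (j0 < 0) j0 = 0;
        if (k0 < 0) k0 = 0;
        const double fu = u - i0, fv = v - j0, fw = w - k0;
        const R_xlen_t base =
            (R_xlen_t)i0 + (R_xlen_t)nx * (j0 + (R_xlen_t)ny * k0);
        const R_xlen_t dz = (R_xlen_t)nx * ny;
        const double c000 = md[base], c100 = md[base + 1];
        const double c010 = md[base + nx], c110 = md[base + nx + 1];
        const double c001 = md[base + dz], c101 = md[base + dz + 1];
        const double c011 = md[base + dz + nx], c111 = md[base + dz + nx + 1];
        const double c00 = c000 + fu * (c100 - c000);
        const double c10 = c010 + fu * (c110 - c010);
        const double c01 = c001 + fu * (c101 - c001);
        const double c11 = c011 + fu * (c111 - c011);
        const double c0 = c00 + fv * (c10 - c00);
        const double c1 = c01 + fv * (c11 - c01);
        od[idx] = c0 + fw * (c1 - c0);
      }
    }
  }
  return out;
}

// Map intensities to 1..bins by linear binning between lo and hi, clamping
// out-of-range values into the edge bins.
// [[Rcpp::export]]
IntegerVector bin_intensities_cpp(NumericVector x, int bins, double lo,
                                  double hi) {
  const R_xlen_t n = x.size();
  IntegerVector out(n);
  const double width = (hi - lo) / bins;
  for (R_xlen_t i = 0; i < n; ++i) {
    int bi;
    if (width <= 0) {
      bi = 1;
    } else {
      bi = (int)std::floor((x[i] - lo) / width) + 1;
      if (bi < 1) bi = 1;
      if (bi > bins) bi = bins;
    }
    out[i] = bi;
  }
  return out;
}

// Joint histogram counts for two pre-binned intensity vectors (values 1..bins).
// [[Rcpp::export]]
NumericMatrix joint_hist_cpp(IntegerVector abin, IntegerVector bbin, int bins) {
  NumericMatrix h(bins, bins);
  const R_xlen_t n = abin.size();
  for (R_xlen_t i = 0; i < n; ++i)
    h(abin[i] - 1, bbin[i] - 1) += 1.0;
  return h;
}

// Parzen-windowed (linear B-spline) joint histogram: each sample deposits
// bilinear weights into the 2x2 neighbouring bins, making histogram-based
// metrics continuously differentiable in the intensities -- the smoothness
// an optimizer needs. Intensities outside [lo, hi] are clamped.
// [[Rcpp::export]]
NumericMatrix joint_hist_soft_cpp(NumericVector a, NumericVector b, int bins,
                                  double alo, double ahi, double blo,
                                  double bhi) {
  NumericMatrix h(bins, bins);
  const R_xlen_t n = a.size();
  const double wa = (ahi - alo) / bins, wb = (bhi - blo) / bins;
  for (R_xlen_t i = 0; i < n; ++i) {
    double ua = wa > 0 ? (a[i] - alo) / wa - 0.5 : 0.0;
    double ub = wb > 0 ? (b[i] - blo) / wb - 0.5 : 0.0;
    if (ua < 0) ua = 0;
    if (ua > bins - 1) ua = bins - 1;
    if (ub < 0) ub = 0;
    if (ub > bins - 1) ub = bins - 1;
    int ia = (int)std::floor(ua), ib = (int)std::floor(ub);
    if (ia > bins - 2) ia = bins - 2;
    if (ib > bins - 2) ib = bins - 2;
    const double fa = ua - ia, fb = ub - ib;
    h(ia, ib) += (1 - fa) * (1 - fb);
    h(ia + 1, ib) += fa * (1 - fb);
    h(ia, ib + 1) += (1 - fa) * fb;
    h(ia + 1, ib + 1) += fa * fb;
  }
  return h;
}

// Separable Gaussian smoothing of a 3D volume (sigma in voxels, reflected
// boundaries). Suppresses voxel noise and the interpolation artifacts that
// otherwise displace histogram-metric optima at grid-aligned transforms.
// [[Rcpp::export]]
NumericVector smooth_gaussian_cpp(NumericVector data, IntegerVector dims,
                                  double sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (sigma <= 0) return clone(data);
  const int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> kern(2 * rad + 1);
  double ksum = 0;
  for (int i = -rad; i <= rad; ++i) {
    kern[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    ksum += kern[i + rad];
  }
  for (double &k : kern) k /= ksum;
  NumericVector cur = clone(data);
  NumericVector nxt(n);
  const int nn[3] = {nx, ny, nz};
  const R_xlen_t strides[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    const int len = nn[ax];
    const R_xlen_t st = strides[ax];
    for (R_xlen_t idx = 0; idx < n; ++idx) {
      const int pos = (int)((idx / st) % len);
      double acc = 0;
      for (int o = -rad; o <= rad; ++o) {
        int p = pos + o;
        if (p < 0) p = -p - 1;            // reflect
        if (p > len - 1) p = 2 * len - 1 - p;
        acc += kern[o + rad] * cur[idx + (R_xlen_t)(p - pos) * st];
      }
      nxt[idx] = acc;
    }
    std::swap(cur, nxt);
  }
  return cur;
}

// Trilinear sampling of a volume at arbitrary physical points under the
// affine map y = A p + b. Used with a fixed jittered point set so that the
// fixed and moving images are interpolated comparably, which removes the
// grid-alignment bias of histogram metrics.
// [[Rcpp::export]]
NumericVector sample_points_cpp(NumericVector mdata, IntegerVector mdim,
                                NumericVector mspacing, NumericVector morigin,
                                NumericMatrix pts, NumericMatrix A,
                                NumericVector b, double background) {
  const int nx = mdim[0], ny = mdim[1], nz = mdim[2];
  const R_xlen_t n = pts.nrow();
  NumericVector out(n);
  const double a11 = A(0, 0), a12 = A(0, 1), a13 = A(0, 2);
  const double a21 = A(1, 0), a22 = A(1, 1), a23 = A(1, 2);
  const double a31 = A(2, 0), a32 = A(2, 1), a33 = A(2, 2);
  const double *md = mdata.begin();
  for (R_xlen_t q = 0; q < n; ++q) {
    const double px = pts(q, 0), py = pts(q, 1), pz = pts(q, 2);
    const double yx = a11 * px + a12 * py + a13 * pz + b[0];
    const double yy = a21 * px + a22 * py + a23 * pz + b[1];
    const double yz = a31 * px + a32 * py + a33 * pz + b[2];
    const double u = (yx - morigin[0]) / mspacing[0];
    const double v = (yy - morigin[1]) / mspacing[1];
    const double w = (yz - morigin[2]) / mspacing[2];
    if (u < 0 || v < 0 || w < 0 || u > nx - 1 || v > ny - 1 || w > nz - 1) {
      out[q] = background;
      continue;
    }
    int i0 = (int)std::floor(u), j0 = (int)std::floor(v),
        k0 = (int)std::floor(w);
    if (i0 > nx - 2) i0 = nx - 2;
    if (j0 > ny - 2) j0 = ny - 2;
    if (k0 > nz - 2) k0 = nz - 2;
    if (i0 < 0) i0 = 0;
    if (j0 < 0) j0 = 0;
    if (k0 < 0) k0 = 0;
    const double fu = u - i0, fv = v - j0, fw = w - k0;
    const R_xlen_t base =
        (R_xlen_t)i0 + (R_xlen_t)nx * (j0 + (R_xlen_t)ny * k0);
    const R_xlen_t dz = (R_xlen_t)nx * ny;
    const double c000 = md[base], c100 = md[base + 1];
    const double c010 = md[base + nx], c110 = md[base + nx + 1];
    const double c001 = md[base + dz], c101 = md[base + dz + 1];
    const double c011 = md[base + dz + nx], c111 = md[base + dz + nx + 1];
    const double c00 = c000 + fu * (c100 - c000);
    const double c10 = c010 + fu * (c110 - c010);
    const double c01 = c001 + fu * (c101 - c001);
    const double c11 = c011 + fu * (c111 - c011);
    const double c0 = c00 + fv * (c10 - c00);
    const double c1 = c01 + fv * (c11 - c01);
    out[q] = c0 + fw * (c1 - c0);
  }
  return out;
}
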
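#include <Rcpp.h>
#include <complex>

using namespace Rcpp;

// Monostatic frequency-domain back-propagation accumulator.
//
// Each voxel accumulates sum_p sum_f S(f,p) * exp(+2i k(f) d(p,v)), where
// the two-segment path applies the free-space wavenumber k0 above the
// surface and the (possibly complex, dispersive) tissue wavenumber below.
// On a regular scan/voxel grid most antenna-voxel pairs share one of a
// small set of path lengths, so the exponentials are evaluated once per
// frequency on the table of unique (air, tissue) path pairs and looked up.
//
// S:        nf x np complex spectra (frequency x aperture position)
// k0:       nf free-space wavenumbers (1/mm)
// kt_re/im: nf real/imaginary tissue wavenumber parts (im <= 0)
// d_air_u:  nu unique free-space path lengths (mm)
// d_tiss_u: nu unique in-tissue path lengths (mm)
// uidx:     np x nv 1-based indices into the unique-path table
// [[Rcpp::export]]
ComplexVector backproject_cpp(const ComplexMatrix S, const NumericVector k0,
                              const NumericVector kt_re,
                              const NumericVector kt_im,
                              const NumericVector d_air_u,
                              const NumericVector d_tiss_u,
                              const IntegerMatrix uidx) {
  const int nf = S.nrow(), np = S.ncol(), nv = uidx.ncol();
  const int nu = d_air_u.size();
  if (uidx.nrow() != np)
    stop("path index matrix does not match the aperture");
  if (k0.size() != nf || kt_re.size() != nf || kt_im.size() != nf)
    stop("wavenumber length does not match the spectrum");
  if (d_tiss_u.size() != nu) stop("unique path tables differ in length");

  std::vector<std::complex<double> > acc(nv, 0.0);
  std::vector<std::complex<double> > lut(nu);
  std::vector<std::complex<double> > s_col(np);

  for (int f = 0; f < nf; ++f) {
    for (int u = 0; u < nu; ++u) {
      const double mag = std::exp(-2.0 * kt_im[f] * d_tiss_u[u]);
      const double ang = 2.0 * (k0[f] * d_air_u[u] + kt_re[f] * d_tiss_u[u]);
      lut[u] = std::polar(mag, ang);
    }
    for (int p = 0; p < np; ++p) {
      const Rcomplex s = S(f, p);
      s_col[p] = std::complex<double>(s.r, s.i);
    }
    for (int v = 0; v < nv; ++v) {
      std::complex<double> a(0.0, 0.0);
      for (int p = 0; p < np; ++p)
        a += s_col[p] * lut[uidx(p, v) - 1];
      acc[v] += a;
    }
  }
  ComplexVector out(nv);
  for (int v = 0; v < nv; ++v) {
    out[v].r = acc[v].real();
    out[v].i = acc[v].imag();
  }
  return out;
}
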
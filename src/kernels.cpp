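#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Gaussian-enveloped carrier pulse, tabulated at 1/32-sample resolution so the
// per-echo inner loop is table lookups rather than exp/cos calls.
static void build_pulse_table(double sigma_samp, double f0_over_fs,
                              double half_width, std::vector<double> &tab,
                              int &n_tab, double &step) {
  step = 1.0 / 32.0;
  n_tab = (int)std::ceil(2.0 * half_width / step) + 2;
  tab.resize(n_tab);
  for (int i = 0; i < n_tab; ++i) {
    double u = -half_width + i * step; // samples
    tab[i] = std::exp(-0.5 * u * u / (sigma_samp * sigma_samp)) *
             std::cos(2.0 * M_PI * f0_over_fs * u);
  }
}

// Render one snapshot of the phantom: for every transmit (virtual source) and
// receive element, superpose the pulse-echo of every point scatterer at delay
// (|src-scat| + |scat-elem|)/c.  Time zero is the moment the wavefront leaves
// the virtual source.  Returns an array dim (n_samp, n_elem, n_angle).
// [[Rcpp::export]]
NumericVector cpp_render_frame(NumericVector x, NumericVector z,
                               NumericVector amp,
                               NumericVector ex, NumericVector ez,
                               NumericVector sx, NumericVector sz,
                               double c_mm_us, double fs_mhz, double f0_mhz,
                               double sigma_us, double t0_us, int n_samp,
                               double R, double elem_width) {
  const int ns = x.size(), ne = ex.size(), na = sx.size();
  const double inv_c = 1.0 / c_mm_us;
  const double sigma_samp = sigma_us * fs_mhz;
  const double half_width = 4.0 * sigma_samp; // pulse support in samples
  std::vector<double> tab;
  int n_tab;
  double step;
  build_pulse_table(sigma_samp, f0_mhz / fs_mhz, half_width, tab, n_tab, step);
  const double inv_step = 1.0 / step;

  NumericVector out(n_samp * ne * na);
  double *po = REAL(out);
  const double *px = REAL(x), *pz = REAL(z), *pa = REAL(amp);
  const double *pex = REAL(ex), *pez = REAL(ez);
  const double *ptab = tab.data();
  std::vector<double> dtx(ns);
  for (int a = 0; a < na; ++a) {
    const double sxa = sx[a], sza = sz[a];
    for (int s = 0; s < ns; ++s) {
      double dx = px[s] - sxa, dz = pz[s] - sza;
      dtx[s] = std::sqrt(dx * dx + dz * dz);
    }
    for (int e = 0; e < ne; ++e) {
      double *col = po + (size_t)a * n_samp * ne + (size_t)e * n_samp;
      const double exe = pex[e], eze = pez[e];
      // outward element normal (radial direction on the array arc)
      const double nx = exe / R, nz = (eze + R) / R;
      const double lambda = c_mm_us / f0_mhz;
      for (int s = 0; s < ns; ++s) {
        double dx = px[s] - exe, dz = pz[s] - eze;
        double drx = std::sqrt(dx * dx + dz * dz);
        double dirw = 1.0;
        if (elem_width > 0.0) {
          // soft-baffled piston directivity: sinc(w sin(phi)/lambda) cos(phi)
          double cphi = (dx * nx + dz * nz) / drx;
          if (cphi <= 0.0) continue;
          double sphi = std::sqrt(std::max(0.0, 1.0 - cphi * cphi));
          double u = M_PI * elem_width * sphi / lambda;
          dirw = (u < 1e-9 ? 1.0 : std::sin(u) / u) * cphi;
        }
        double spos = ((dtx[s] + drx) * inv_c - t0_us) * fs_mhz;
        int j0 = (int)(spos - half_width) + 1;
        int j1 = (int)(spos + half_width);
        if (j0 < 0) j0 = 0;
        if (j1 > n_samp - 1) j1 = n_samp - 1;
        double a_s = pa[s] * dirw;
        double ti = (j0 - spos + half_width) * inv_step;
        for (int j = j0; j <= j1; ++j, ti += inv_step) {
          int i0 = (int)ti;
          if (i0 < 0 || i0 >= n_tab - 1) continue;
          double fr = ti - i0;
          col[j] += a_s * (ptab[i0] + (ptab[i0 + 1] - ptab[i0]) * fr);
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(n_samp, ne, na);
  return out;
}

// Delay-and-sum one transmit onto a polar grid (depths along scanlines x
// line angles).  rf_t is (n_samp x n_elem) (samples down the columns, for
// cache-friendly depth sweeps).  Scanlines emanate from the curvature
// center at (0, -R).  The f-number aperture test and Hann apodization are
// evaluated on the squared lateral offset via a lookup table, so the inner
// loop has a single sqrt.  Pixels mapping outside the recorded window
// contribute zero and are counted.
// [[Rcpp::export]]
List cpp_das_frame(NumericMatrix rf_t, NumericVector ex, NumericVector ez,
                   double sx, double sz,
                   NumericVector depths, NumericVector sin_al,
                   NumericVector cos_al, double R,
                   double fs_mhz, double t0_us, double c_mm_us,
                   double fnum, int apod_hann) {
  const int n_samp = rf_t.nrow(), ne = rf_t.ncol();
  const int nd = depths.size(), nl = sin_al.size();
  const double inv_c = 1.0 / c_mm_us;
  const double four_f2 = 4.0 * fnum * fnum;
  // apodization vs squared normalized offset q in [0, 1]
  const int NQ = 512;
  static thread_local std::vector<double> qtab;
  qtab.resize(NQ + 1);
  for (int i = 0; i <= NQ; ++i)
    qtab[i] = apod_hann ?
      0.5 + 0.5 * std::cos(M_PI * std::sqrt((double)i / NQ)) : 1.0;
  NumericVector img(nd * nl);
  double *pimg = REAL(img);
  const double *prf = REAL(rf_t);
  long oor = 0;
  std::vector<double> aa(ne), bb(ne);
  for (int l = 0; l < nl; ++l) {
    const double ux = sin_al[l], uz = cos_al[l];
    for (int e = 0; e < ne; ++e) {
      // element position relative to the curvature center
      double cx = ex[e], cz = ez[e] + R;
      aa[e] = ux * cx + uz * cz;       // projection onto the scanline
      bb[e] = cx * cx + cz * cz;       // squared distance from the center
    }
    for (int d = 0; d < nd; ++d) {
      const double dep = depths[d];
      const double r = R + dep;
      const double pxx = r * ux, pzz = r * uz - R;
      double dxs = pxx - sx, dzs = pzz - sz;
      const double dtx = std::sqrt(dxs * dxs + dzs * dzs);
      const double base = (dtx * inv_c - t0_us) * fs_mhz;
      const double q_scale = (dep > 1e-6) ? four_f2 / (dep * dep) : 0.0;
      double acc = 0.0;
      for (int e = 0; e < ne; ++e) {
        double drx2 = r * r - 2.0 * r * aa[e] + bb[e];
        double off2 = drx2 - dep * dep;
        double q = off2 > 0.0 ? off2 * q_scale : 0.0;
        if (q > 1.0 || q_scale == 0.0) continue;
        double drx = std::sqrt(drx2);
        double spos = base + drx * inv_c * fs_mhz;
        int i0 = (int)spos;
        if (spos < 0.0 || i0 >= n_samp - 1) { ++oor; continue; }
        double fr = spos - i0;
        const double *cole = prf + (size_t)e * n_samp;
        double qt = q * NQ;
        int qi = (int)qt;
        double w = qtab[qi] + (qtab[qi + 1] - qtab[qi]) * (qt - qi);
        acc += w * (cole[i0] + (cole[i0 + 1] - cole[i0]) * fr);
      }
      pimg[(size_t)l * nd + d] = acc;
    }
  }
  return List::create(_["image"] = img, _["out_of_range"] = (double)oor);
}

// Normalized cross-correlation of a reference window against a (possibly
// longer) search segment over integer lags -max_lag..+max_lag.  Lag 0 aligns
// the reference with the center of the search segment.  Each lag uses the
// overlapping samples only; per-lag mean removal and unit-energy
// normalization keep the coefficient in [-1, 1].  Zero-variance overlap or
// overlap shorter than min_overlap yields NA.
// [[Rcpp::export]]
NumericVector cpp_ncc(NumericVector ref, NumericVector cur, int max_lag,
                      int min_overlap) {
  const int n = ref.size(), m = cur.size();
  const int offset = (m - n) / 2; // center alignment
  NumericVector out(2 * max_lag + 1, NA_REAL);
  for (int l = -max_lag; l <= max_lag; ++l) {
    int start = offset + l;               // cur index aligned with ref[0]
    int i0 = start < 0 ? -start : 0;      // first ref index in overlap
    int i1 = (start + n > m) ? (m - start) : n; // one-past-last ref index
    int len = i1 - i0;
    if (len < min_overlap) continue;
    double sr = 0, sc = 0;
    for (int i = i0; i < i1; ++i) { sr += ref[i]; sc += cur[start + i]; }
    double mr = sr / len, mc = sc / len;
    double num = 0, dr = 0, dc = 0;
    for (int i = i0; i < i1; ++i) {
      double a = ref[i] - mr, b = cur[start + i] - mc;
      num += a * b; dr += a * a; dc += b * b;
    }
    out[l + max_lag] = (dr <= 0.0 || dc <= 0.0) ? 0.0 : num / std::sqrt(dr * dc);
  }
  return out;
}

// Synthesize one speckle A-line sequence directly on a beamformed depth grid:
// each scatterer contributes a Gaussian envelope with a two-way carrier
// (phase 4*pi*z/lambda), rigidly advected by disp_mm per frame.
// Returns matrix (n_z x n_frames).
// [[Rcpp::export]]
NumericMatrix cpp_speckle_line(NumericVector zgrid, NumericVector zi,
                               NumericVector ai, NumericVector disp_mm,
                               double lambda_mm, double sigma_mm) {
  const int nz = zgrid.size(), ns = zi.size(), nf = disp_mm.size();
  const double z0 = zgrid[0];
  const double dz = nz > 1 ? (zgrid[1] - zgrid[0]) : 1.0;
  const double k2 = 4.0 * M_PI / lambda_mm;
  const double hw = 4.0 * sigma_mm;
  NumericMatrix out(nz, nf);
  for (int f = 0; f < nf; ++f) {
    double d = disp_mm[f];
    for (int s = 0; s < ns; ++s) {
      double zc = zi[s] + d;
      int j0 = (int)std::ceil((zc - hw - z0) / dz);
      int j1 = (int)std::floor((zc + hw - z0) / dz);
      if (j0 < 0) j0 = 0;
      if (j1 > nz - 1) j1 = nz - 1;
      for (int j = j0; j <= j1; ++j) {
        double u = zgrid[j] - zc;
        out(j, f) += ai[s] *
          std::exp(-0.5 * u * u / (sigma_mm * sigma_mm)) * std::cos(k2 * u);
      }
    }
  }
  return out;
}
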
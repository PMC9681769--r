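#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Direct-form II transposed IIR filter, single causal pass (zero initial state).
// [[Rcpp::export(name = ".iirFilterCpp")]]
NumericVector iir_filter_cpp(NumericVector x, NumericVector b, NumericVector a) {
  int n = x.size();
  int nb = b.size(), na = a.size();
  int nw = std::max(nb, na);
  std::vector<double> bb(nw, 0.0), aa(nw, 0.0), w(nw, 0.0);
  double a0 = a[0];
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a0;
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a0;
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double yi = bb[0] * x[i] + w[0];
    for (int j = 0; j < nw - 1; ++j)
      w[j] = bb[j + 1] * x[i] + w[j + 1] - aa[j + 1] * yi;
    w[nw - 1] = 0.0;
    if (nw >= 2) w[nw - 2] = bb[nw - 1] * x[i] - aa[nw - 1] * yi;
    y[i] = yi;
  }
  return y;
}

struct PeakRec {
  int idx;
  double height;
  double prominence;
  int left_base;
  int right_base;
};

// Local maxima with plateau handling; classical topographic prominence:
// walk outwards until a strictly higher sample (or the signal edge), the
// minimum over each walk is the side base; prominence = height - max(side
// minima). Base width = distance between the two base positions.
static std::vector<PeakRec> find_peaks_core(const double* x, int n) {
  std::vector<PeakRec> peaks;
  int i = 1;
  while (i < n - 1) {
    if (x[i - 1] < x[i]) {
      int j = i;
      while (j + 1 < n && x[j + 1] == x[i]) ++j;
      if (j + 1 < n && x[j + 1] < x[i]) {
        PeakRec p;
        p.idx = (i + j) / 2;
        p.height = x[i];
        double lmin = x[i]; int lpos = p.idx;
        for (int k = i - 1; k >= 0; --k) {
          if (x[k] > p.height) break;
          if (x[k] < lmin) { lmin = x[k]; lpos = k; }
        }
        double rmin = x[i]; int rpos = p.idx;
        for (int k = j + 1; k < n; ++k) {
          if (x[k] > p.height) break;
          if (x[k] < rmin) { rmin = x[k]; rpos = k; }
        }
        p.prominence = p.height - std::max(lmin, rmin);
        p.left_base = lpos;
        p.right_base = rpos;
        peaks.push_back(p);
        i = j + 1;
        continue;
      }
      i = j + 1;
      continue;
    }
    ++i;
  }
  return peaks;
}

// apply the four criteria: height, prominence, base width, then the
// minimum-separation rule (taller peaks win; lower peaks closer than
// min_distance to a kept peak are suppressed). Result sorted by position.
static std::vector<PeakRec> filter_peaks(const std::vector<PeakRec>& all,
                                         const double* wl,
                                         double min_height,
                                         double min_prominence,
                                         double min_base_width,
                                         double min_distance) {
  std::vector<PeakRec> ok;
  for (size_t k = 0; k < all.size(); ++k) {
    const PeakRec& p = all[k];
    double bw = wl[p.right_base] - wl[p.left_base];
    if (p.height >= min_height && p.prominence >= min_prominence &&
        bw >= min_base_width)
      ok.push_back(p);
  }
  std::vector<int> ord(ok.size());
  for (size_t k = 0; k < ok.size(); ++k) ord[k] = (int)k;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return ok[a].height > ok[b].height;
  });
  std::vector<bool> keep(ok.size(), false);
  std::vector<double> kept_wl;
  for (size_t k = 0; k < ord.size(); ++k) {
    double w = wl[ok[ord[k]].idx];
    bool clash = false;
    for (size_t m = 0; m < kept_wl.size(); ++m)
      if (std::fabs(kept_wl[m] - w) < min_distance) { clash = true; break; }
    if (!clash) { keep[ord[k]] = true; kept_wl.push_back(w); }
  }
  std::vector<PeakRec> out;
  for (size_t k = 0; k < ok.size(); ++k) if (keep[k]) out.push_back(ok[k]);
  return out;
}

// [[Rcpp::export(name = ".findPeaksCpp")]]
DataFrame find_peaks_cpp(NumericVector x, NumericVector wavelength,
                         double min_height, double min_prominence,
                         double min_base_width, double min_distance) {
  std::vector<PeakRec> all = find_peaks_core(REAL(x), x.size());
  std::vector<PeakRec> ok = filter_peaks(all, REAL(wavelength), min_height,
                                         min_prominence, min_base_width,
                                         min_distance);
  int m = ok.size();
  IntegerVector out_idx(m);
  NumericVector out_wl(m), out_h(m), out_prom(m), out_bw(m);
  for (int k = 0; k < m; ++k) {
    const PeakRec& p = ok[k];
    out_idx[k] = p.idx + 1;  // 1-based for R
    out_wl[k] = wavelength[p.idx];
    out_h[k] = p.height;
    out_prom[k] = p.prominence;
    out_bw[k] = wavelength[p.right_base] - wavelength[p.left_base];
  }
  return DataFrame::create(_["index"] = out_idx, _["wavelength"] = out_wl,
                           _["intensity"] = out_h, _["prominence"] = out_prom,
                           _["base_width"] = out_bw);
}

// Full per-frame chain over a spectral stream stored as a wavelengths x
// frames matrix: plain background subtraction |I - dark|, causal Butterworth
// along the wavelength axis, peak detection with the four criteria. Frames
// whose raw background-subtracted maximum is below `prescreen` are skipped
// (they cannot contain a peak passing min_height). Returns one row per
// retained peak.
// [[Rcpp::export(name = ".processStreamCpp")]]
DataFrame process_stream_cpp(NumericMatrix intensity, NumericVector dark,
                             NumericVector times, NumericVector wavelength,
                             NumericVector b, NumericVector a,
                             double min_height, double min_prominence,
                             double min_base_width, double min_distance,
                             double prescreen) {
  int W = intensity.nrow(), T = intensity.ncol();
  std::vector<int> frame_out;
  std::vector<double> t_out, wl_out, h_out, prom_out, bw_out;
  int nb = b.size(), na = a.size();
  int nw = std::max(nb, na);
  std::vector<double> bb(nw, 0.0), aa(nw, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a[0];
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a[0];
  std::vector<double> sub(W), filt(W), w(nw);
  const double* wl = REAL(wavelength);
  for (int t = 0; t < T; ++t) {
    const double* col = &intensity(0, t);
    double mx = 0.0;
    for (int i = 0; i < W; ++i) {
      double v = std::fabs(col[i] - dark[i]);
      sub[i] = v;
      if (v > mx) mx = v;
    }
    if (mx < prescreen) continue;
    std::fill(w.begin(), w.end(), 0.0);
    for (int i = 0; i < W; ++i) {
      double yi = bb[0] * sub[i] + w[0];
      for (int j = 0; j < nw - 1; ++j)
        w[j] = bb[j + 1] * sub[i] + w[j + 1] - aa[j + 1] * yi;
      w[nw - 1] = 0.0;
      if (nw >= 2) w[nw - 2] = bb[nw - 1] * sub[i] - aa[nw - 1] * yi;
      filt[i] = yi;
    }
    std::vector<PeakRec> all = find_peaks_core(filt.data(), W);
    std::vector<PeakRec> ok = filter_peaks(all, wl, min_height,
                                           min_prominence, min_base_width,
                                           min_distance);
    for (size_t k = 0; k < ok.size(); ++k) {
      const PeakRec& p = ok[k];
      frame_out.push_back(t + 1);
      t_out.push_back(times[t]);
      wl_out.push_back(wl[p.idx]);
      h_out.push_back(p.height);
      prom_out.push_back(p.prominence);
      bw_out.push_back(wl[p.right_base] - wl[p.left_base]);
    }
  }
  return DataFrame::create(_["frame"] = wrap(frame_out), _["time"] = wrap(t_out),
                           _["wavelength"] = wrap(wl_out),
                           _["intensity"] = wrap(h_out),
                           _["prominence"] = wrap(prom_out),
                           _["base_width"] = wrap(bw_out));
}

// Add a scaled template band to a set of column ranges of a matrix, in
// place: the droplet-transit emission writer used by the stream simulator.
// [[Rcpp::export(name = ".addTransitsCpp")]]
void add_transits_cpp(NumericMatrix mat, NumericVector band,
                      IntegerVector col_from, IntegerVector col_to,
                      NumericVector amplitude) {
  int W = mat.nrow(), T = mat.ncol();
  for (int d = 0; d < col_from.size(); ++d) {
    int c0 = std::max(col_from[d] - 1, 0);
    int c1 = std::min(col_to[d] - 1, T - 1);
    double amp = amplitude[d];
    for (int c = c0; c <= c1; ++c) {
      double* colp = &mat(0, c);
      for (int i = 0; i < W; ++i) colp[i] += amp * band[i];
    }
  }
}
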
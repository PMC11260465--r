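#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Descending watershed sweep computing, for every local maximum (8-conn),
// its topographic prominence: summit value minus the level at which the
// summit's catchment first touches a catchment with a strictly higher
// summit. Plateaus (connected equal-value summits) are coalesced and
// reported once at their integer centroid. The image border contributes no
// saddle; summits never reaching higher terrain close against the image
// minimum.
//
// Invariant used throughout: every open peak of a component sits exactly at
// the component's summit value (lower peaks are closed the moment their
// component merges into higher terrain), so equal-summit merges at the
// summit level itself mean "same plateau" and coalesce coordinate sums.

struct Peak {
  double sumx, sumy;  // 0-based coordinate sums over plateau pixels
  int npix;
  int next;           // linked list over the peaks vector, -1 terminates
};

static inline int find_root(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// [[Rcpp::export(name = ".find_maxima_core")]]
DataFrame find_maxima_core(NumericMatrix img) {
  const int ny = img.nrow(), nx = img.ncol(), n = ny * nx;
  double vmin = img[0], vmax = img[0];
  for (int i = 1; i < n; ++i) {
    if (img[i] < vmin) vmin = img[i];
    if (img[i] > vmax) vmax = img[i];
  }
  std::vector<double> out_val, out_prom;
  std::vector<int> out_ix, out_iy;
  if (vmax == vmin) {  // constant image: single plateau, prominence 0
    return DataFrame::create(_["ix"] = IntegerVector(0),
                             _["iy"] = IntegerVector(0),
                             _["value"] = NumericVector(0),
                             _["prominence"] = NumericVector(0));
  }

  // pixels sorted by decreasing value (ties by linear index); the minimum
  // level is skipped: it can only merge components, which the final
  // closing at vmin reproduces
  std::vector<int> ord;
  ord.reserve(n);
  for (int i = 0; i < n; ++i)
    if (img[i] > vmin) ord.push_back(i);
  std::stable_sort(ord.begin(), ord.end(),
                   [&img](int a, int b) { return img[a] > img[b]; });

  std::vector<int> comp(n, -1);        // component id per processed pixel
  std::vector<int> parent;             // union-find
  std::vector<double> summit;          // summit value per component
  std::vector<int> head, tail;         // open-peak list per component
  std::vector<Peak> peaks;

  const int dy8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  int roots[8];

  auto close_list = [&](int r, double saddle) {
    for (int p = head[r]; p != -1; p = peaks[p].next) {
      out_ix.push_back((int)std::floor(peaks[p].sumx / peaks[p].npix + 0.5));
      out_iy.push_back((int)std::floor(peaks[p].sumy / peaks[p].npix + 0.5));
      out_val.push_back(summit[r]);
      out_prom.push_back(summit[r] - saddle);
    }
    head[r] = tail[r] = -1;
  };

  for (size_t k = 0; k < ord.size(); ++k) {
    const int p = ord[k];
    const double v = img[p];
    const int y = p % ny, x = p / ny;
    int nroots = 0;
    for (int t = 0; t < 8; ++t) {
      const int yy = y + dy8[t], xx = x + dx8[t];
      if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      const int q = xx * ny + yy;
      if (comp[q] < 0) continue;
      const int r = find_root(parent, comp[q]);
      bool seen = false;
      for (int s = 0; s < nroots; ++s) if (roots[s] == r) { seen = true; break; }
      if (!seen) roots[nroots++] = r;
    }
    if (nroots == 0) {  // new summit
      const int cid = (int)parent.size();
      parent.push_back(cid);
      summit.push_back(v);
      peaks.push_back({(double)x, (double)y, 1, -1});
      head.push_back((int)peaks.size() - 1);
      tail.push_back((int)peaks.size() - 1);
      comp[p] = cid;
      continue;
    }
    double smax = summit[roots[0]];
    int win = roots[0];
    for (int s = 1; s < nroots; ++s)
      if (summit[roots[s]] > smax) { smax = summit[roots[s]]; win = roots[s]; }
    for (int s = 0; s < nroots; ++s) {
      const int r = roots[s];
      if (r == win) continue;
      if (summit[r] < smax) {
        close_list(r, v);  // v is the first level joining r to higher terrain
      } else {             // equal summits: keep open, concatenate
        if (head[win] == -1) { head[win] = head[r]; tail[win] = tail[r]; }
        else if (head[r] != -1) {
          peaks[tail[win]].next = head[r];
          tail[win] = tail[r];
        }
        head[r] = tail[r] = -1;
      }
      parent[r] = win;
    }
    if (v == smax) {
      // p extends the summit plateau: coalesce all open peaks plus p
      double sx = (double)x, sy = (double)y;
      int np = 1;
      for (int q = head[win]; q != -1; q = peaks[q].next) {
        sx += peaks[q].sumx; sy += peaks[q].sumy; np += peaks[q].npix;
      }
      peaks.push_back({sx, sy, np, -1});
      head[win] = tail[win] = (int)peaks.size() - 1;
    }
    comp[p] = win;
  }
  // summits never joined to higher terrain
  for (size_t r = 0; r < parent.size(); ++r)
    if (parent[r] == (int)r) close_list((int)r, vmin);

  return DataFrame::create(_["ix"] = wrap(out_ix), _["iy"] = wrap(out_iy),
                           _["value"] = wrap(out_val),
                           _["prominence"] = wrap(out_prom));
}
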
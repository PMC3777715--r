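#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Synchronization-likelihood kernel for all channel pairs.
//
// data: R array with dim (n_epochs, n_channels, n_samples), band-filtered
// epochs of one subject. Embedding vectors are built within epochs only;
// candidate pairs are constrained by a Theiler window w1 and an outer
// window w2 on the concatenated sample index, so temporally adjacent
// (autocorrelated) vectors are never compared while vectors from other
// epochs remain admissible.
//
// For each reference time a, each channel's critical distance is the k-th
// smallest candidate distance with k = max(1, floor(p_ref * n_cand + 0.5));
// the hit set includes ties at that distance. The instantaneous SL of a
// channel pair is |H_x(a) & H_y(a)| / max(|H_x(a)|, |H_y(a)|) and the
// reported SL is its average over reference times and epochs.

static inline double sqdist(const double *ea, const double *eb, int m) {
  double s = 0.0;
  for (int t = 0; t < m; ++t) {
    double d = ea[t] - eb[t];
    s += d * d;
  }
  return s;
}

static inline double chebdist(const double *ea, const double *eb, int m) {
  double s = 0.0;
  for (int t = 0; t < m; ++t) {
    double d = std::fabs(ea[t] - eb[t]);
    if (d > s) s = d;
  }
  return s;
}

// [[Rcpp::export(name = ".sl_kernel")]]
NumericMatrix sl_kernel(NumericVector data, int lag, int m, int w1, int w2,
                        double p_ref, int chebyshev) {
  IntegerVector dims = data.attr("dim");
  if (dims.size() != 3) stop("data must be a 3-d array (epochs x channels x samples)");
  const int E = dims[0], C = dims[1], S = dims[2];
  const int Ne = S - (m - 1) * lag;
  if (Ne < 1)
    stop("epoch too short for embedding: need more than %d samples", (m - 1) * lag);
  const int M = E * Ne;

  // global (concatenated) sample index of each embedding vector
  std::vector<int> g(M);
  for (int e = 0; e < E; ++e)
    for (int i = 0; i < Ne; ++i) g[e * Ne + i] = e * S + i;

  // candidate ranges per reference vector: indices b with w1 < |g_a-g_b| < w2
  std::vector<int> lo1(M), hi1(M), lo2(M), hi2(M), ncand(M), kk(M);
  bool any_cand = false;
  for (int a = 0; a < M; ++a) {
    int ga = g[a];
    // left: g_b in (ga - w2, ga - w1)  -> strictly inside the open window
    lo1[a] = (int)(std::upper_bound(g.begin(), g.end(), ga - w2) - g.begin());
    hi1[a] = (int)(std::lower_bound(g.begin(), g.end(), ga - w1) - g.begin());
    lo2[a] = (int)(std::upper_bound(g.begin(), g.end(), ga + w1) - g.begin());
    hi2[a] = (int)(std::lower_bound(g.begin(), g.end(), ga + w2) - g.begin());
    ncand[a] = (hi1[a] - lo1[a]) + (hi2[a] - lo2[a]);
    if (ncand[a] > 0) {
      any_cand = true;
      int k = (int)std::floor(p_ref * ncand[a] + 0.5);
      kk[a] = k < 1 ? 1 : k;
    } else kk[a] = 0;
  }
  if (!any_cand)
    stop("no admissible candidate vectors: w1 = %d excludes every pair; "
         "provide more epochs or a longer recording", w1);

  // per channel: embed, then hit sets per reference vector (sorted by index)
  std::vector<std::vector<int>> hits(C);          // flat hit indices
  std::vector<std::vector<int>> hoff(C);          // offsets, length M+1
  std::vector<double> emb((size_t)m * M);
  std::vector<double> dist;
  std::vector<double> dsel;
  for (int c = 0; c < C; ++c) {
    for (int e = 0; e < E; ++e)
      for (int i = 0; i < Ne; ++i)
        for (int t = 0; t < m; ++t)
          emb[(size_t)(e * Ne + i) * m + t] =
            data[e + (size_t)E * (c + (size_t)C * (i + t * lag))];
    hoff[c].assign(M + 1, 0);
    std::vector<int> &hv = hits[c];
    hv.clear();
    for (int a = 0; a < M; ++a) {
      hoff[c][a] = (int)hv.size();
      int nc = ncand[a];
      if (nc == 0) continue;
      dist.resize(nc);
      const double *ea = emb.data() + (size_t)a * m;
      int p = 0;
      if (chebyshev) {
        for (int b = lo1[a]; b < hi1[a]; ++b)
          dist[p++] = chebdist(ea, emb.data() + (size_t)b * m, m);
        for (int b = lo2[a]; b < hi2[a]; ++b)
          dist[p++] = chebdist(ea, emb.data() + (size_t)b * m, m);
      } else {
        for (int b = lo1[a]; b < hi1[a]; ++b)
          dist[p++] = sqdist(ea, emb.data() + (size_t)b * m, m);
        for (int b = lo2[a]; b < hi2[a]; ++b)
          dist[p++] = sqdist(ea, emb.data() + (size_t)b * m, m);
      }
      int k = kk[a];
      dsel.assign(dist.begin(), dist.end());
      std::nth_element(dsel.begin(), dsel.begin() + (k - 1), dsel.end());
      double eps = dsel[k - 1];
      p = 0;
      for (int b = lo1[a]; b < hi1[a]; ++b, ++p)
        if (dist[p] <= eps) hv.push_back(b);
      for (int b = lo2[a]; b < hi2[a]; ++b, ++p)
        if (dist[p] <= eps) hv.push_back(b);
    }
    hoff[c][M] = (int)hv.size();
  }

  NumericMatrix out(C, C);
  for (int c1 = 0; c1 < C; ++c1) {
    out(c1, c1) = 1.0;
    for (int c2 = c1 + 1; c2 < C; ++c2) {
      double acc = 0.0;
      int nref = 0;
      for (int a = 0; a < M; ++a) {
        if (ncand[a] == 0) continue;
        int s1 = hoff[c1][a], e1 = hoff[c1][a + 1];
        int s2 = hoff[c2][a], e2 = hoff[c2][a + 1];
        int n1 = e1 - s1, n2 = e2 - s2;
        int joint = 0;
        int i = s1, j = s2;
        while (i < e1 && j < e2) {
          int bi = hits[c1][i], bj = hits[c2][j];
          if (bi == bj) { ++joint; ++i; ++j; }
          else if (bi < bj) ++i;
          else ++j;
        }
        int denom = n1 > n2 ? n1 : n2;
        if (denom > 0) acc += (double)joint / denom;
        ++nref;
      }
      double v = nref > 0 ? acc / nref : NA_REAL;
      out(c1, c2) = v;
      out(c2, c1) = v;
    }
  }
  return out;
}
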
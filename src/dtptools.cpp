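#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Hamming distance with early exit once `limit` is exceeded.
static inline int hd_capped(const char *a, const char *b, int L, int limit) {
  int d = 0;
  for (int k = 0; k < L; ++k) {
    if (a[k] != b[k] && ++d > limit) return d;
  }
  return d;
}

// For each barcode (given in rank order), the 1-based rank of its nearest
// other barcode lying within Hamming distance <= fp_hd, or 0 if none.
// Drives both the against-higher-ranked and the all-pairs FDR variants.
// [[Rcpp::export(name = ".hamming_neighbor_rank")]]
IntegerVector hamming_neighbor_rank(CharacterVector barcodes, int fp_hd) {
  const int n = barcodes.size();
  if (n == 0) return IntegerVector(0);
  const int L = LENGTH(STRING_ELT(barcodes, 0));
  std::vector<const char *> s(n);
  for (int i = 0; i < n; ++i) {
    if (LENGTH(STRING_ELT(barcodes, i)) != L)
      stop("all barcodes must have equal length");
    s[i] = CHAR(STRING_ELT(barcodes, i));
  }
  IntegerVector m(n, 0);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (hd_capped(s[i], s[j], L, fp_hd) <= fp_hd) {
        if (m[j] == 0) m[j] = i + 1;  // i ascends, so the first hit is minimal
        if (m[i] == 0 || m[i] > j + 1) m[i] = j + 1;
      }
    }
  }
  return m;
}

// Per-read nearest-whitelist lookup: for each read, the number of whitelist
// entries within max_hd, the index (1-based) of the closest one, and its
// distance. Ties in distance keep the lowest index but still count matches.
// [[Rcpp::export(name = ".assign_nearest")]]
List assign_nearest(CharacterVector reads, CharacterVector whitelist, int max_hd) {
  const int n = reads.size(), w = whitelist.size();
  if (w == 0) stop("empty whitelist");
  const int L = LENGTH(STRING_ELT(whitelist, 0));
  std::vector<const char *> wl(w);
  for (int j = 0; j < w; ++j) wl[j] = CHAR(STRING_ELT(whitelist, j));
  IntegerVector n_hits(n), best(n), dist(n);
  for (int i = 0; i < n; ++i) {
    if (LENGTH(STRING_ELT(reads, i)) != L) {
      n_hits[i] = 0; best[i] = NA_INTEGER; dist[i] = NA_INTEGER;
      continue;
    }
    const char *r = CHAR(STRING_ELT(reads, i));
    int hits = 0, bi = NA_INTEGER, bd = max_hd + 1;
    for (int j = 0; j < w; ++j) {
      int d = hd_capped(r, wl[j], L, max_hd);
      if (d <= max_hd) {
        ++hits;
        if (d < bd) { bd = d; bi = j + 1; }
      }
    }
    n_hits[i] = hits; best[i] = bi;
    dist[i] = hits > 0 ? bd : NA_INTEGER;
  }
  return List::create(_["n_hits"] = n_hits, _["best"] = best, _["dist"] = dist);
}

// 8-connected labeling of a binary mask (column-major matrix).
// [[Rcpp::export(name = ".label_components8")]]
IntegerMatrix label_components8(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      lab(r, c) = ++next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            int rr = p.first + dr, cc = p.second + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              q.push(std::make_pair(rr, cc));
            }
          }
        }
      }
    }
  }
  return lab;
}
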
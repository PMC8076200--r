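// Compiled kernels: k-mer multiplicity, unique-anchor matching, longest
// co-linear chains, banded affine-gap global alignment, and the
// mismatch-tolerant primer binding-site scan. Sequences arrive as plain
// upper-case character strings; positions returned are 1-based.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

// Open-addressing hash for 2-bit encoded k-mers (k <= 31).
struct KmerHash {
  std::vector<uint64_t> keys;
  std::vector<int32_t>  vals;
  uint64_t mask;
  static constexpr uint64_t EMPTY = ~0ULL;
  explicit KmerHash(size_t n) {
    size_t cap = 64;
    while (cap < n * 2 + 1) cap <<= 1;
    keys.assign(cap, EMPTY);
    vals.assign(cap, -1);
    mask = cap - 1;
  }
  static inline uint64_t mix(uint64_t x) {
    x ^= x >> 33; x *= 0xff51afd7ed558ccdULL;
    x ^= x >> 33; x *= 0xc4ceb9fe1a85ec53ULL;
    x ^= x >> 33;
    return x;
  }
  inline int32_t find(uint64_t k) const {
    uint64_t i = mix(k) & mask;
    for (;;) {
      if (keys[i] == EMPTY) return -1;
      if (keys[i] == k) return vals[i];
      i = (i + 1) & mask;
    }
  }
  // returns slot value; inserts with val if absent
  inline int32_t insert_or_get(uint64_t k, int32_t val) {
    uint64_t i = mix(k) & mask;
    for (;;) {
      if (keys[i] == EMPTY) { keys[i] = k; vals[i] = val; return val; }
      if (keys[i] == k) return vals[i];
      i = (i + 1) & mask;
    }
  }
};

// Genome-wide (forward strand) multiplicity of every k-mer of `window`.
// Returns an integer vector of length nchar(window) - k + 1; entries are the
// total count of that k-mer across all chromosomes of `genome`, or NA for
// window k-mers containing a non-ACGT character.
// [[Rcpp::export(name = ".cpp_kmer_multiplicity")]]
IntegerVector cpp_kmer_multiplicity(std::string window, CharacterVector genome, int k) {
  int n = (int)window.size();
  if (n < k) stop("window shorter than k");
  int nk = n - k + 1;
  // map window k-mers -> slot id
  KmerHash h((size_t)nk);
  std::vector<int32_t> slot_of(nk, -1);
  std::vector<int32_t> counts;
  uint64_t code = 0, kmask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int run = 0;
  for (int i = 0; i < n; i++) {
    int b = base_code(window[i]);
    if (b < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)b) & kmask;
    run++;
    if (run >= k) {
      int start = i - k + 1;
      int32_t s = h.insert_or_get(code, (int32_t)counts.size());
      if (s == (int32_t)counts.size()) counts.push_back(0);
      slot_of[start] = s;
    }
  }
  // scan genome forward strand
  for (int ci = 0; ci < genome.size(); ci++) {
    std::string chr = as<std::string>(genome[ci]);
    uint64_t c2 = 0; int r2 = 0;
    for (size_t i = 0; i < chr.size(); i++) {
      int b = base_code(chr[i]);
      if (b < 0) { r2 = 0; c2 = 0; continue; }
      c2 = ((c2 << 2) | (uint64_t)b) & kmask;
      r2++;
      if (r2 >= k) {
        int32_t s = h.find(c2);
        if (s >= 0) counts[s]++;
      }
    }
  }
  IntegerVector out(nk);
  for (int i = 0; i < nk; i++)
    out[i] = (slot_of[i] < 0) ? NA_INTEGER : counts[slot_of[i]];
  return out;
}

// For a set of bait sequences and one target genome, find k-mers that are
// unique within their bait (forward strand, and not shared between baits)
// and occur exactly once in the target genome (counting both strands).
// Returns a list (one element per bait) of data.frames with columns
// bait_pos, chrom, tpos, strand (all 1-based; strand +1/-1; tpos is the
// leftmost genome coordinate of the matching window).
// [[Rcpp::export(name = ".cpp_find_anchors_multi")]]
List cpp_find_anchors_multi(CharacterVector baits, CharacterVector genome, int k) {
  if (k < 4 || k > 31) stop("k must be in [4, 31]");
  if (k % 2 == 0) stop("k must be odd (avoids palindromic k-mers)");
  uint64_t kmask = (1ULL << (2 * k)) - 1;
  struct Rec {
    int32_t bait_id, bait_pos;  // 0-based bait index, 1-based position
    int32_t count;
    int32_t chrom, tpos, strand;
    bool dup;
  };
  std::vector<Rec> recs;
  size_t total = 0;
  for (int bi = 0; bi < baits.size(); bi++) total += LENGTH(STRING_ELT(baits, bi));
  KmerHash h(total);
  for (int bi = 0; bi < baits.size(); bi++) {
    std::string b = as<std::string>(baits[bi]);
    uint64_t code = 0; int run = 0;
    for (size_t i = 0; i < b.size(); i++) {
      int bc = base_code(b[i]);
      if (bc < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)bc) & kmask;
      run++;
      if (run >= k) {
        int32_t id = (int32_t)recs.size();
        int32_t got = h.insert_or_get(code, id);
        if (got == id) {
          Rec r; r.bait_id = bi; r.bait_pos = (int32_t)(i - k + 2);
          r.count = 0; r.chrom = 0; r.tpos = 0; r.strand = 0; r.dup = false;
          recs.push_back(r);
        } else {
          recs[got].dup = true;  // repeated within/between baits: not usable
        }
      }
    }
  }
  const uint64_t shift_rc = 2 * (uint64_t)(k - 1);
  for (int ci = 0; ci < genome.size(); ci++) {
    std::string chr = as<std::string>(genome[ci]);
    uint64_t f = 0, rc = 0; int run = 0;
    for (size_t i = 0; i < chr.size(); i++) {
      int bc = base_code(chr[i]);
      if (bc < 0) { run = 0; f = 0; rc = 0; continue; }
      f  = ((f << 2) | (uint64_t)bc) & kmask;
      rc = (rc >> 2) | (((uint64_t)(3 - bc)) << shift_rc);
      run++;
      if (run >= k) {
        int32_t pos = (int32_t)(i - k + 2);
        int32_t id = h.find(f);
        if (id >= 0) {
          Rec &r = recs[id];
          if (++r.count == 1) { r.chrom = ci + 1; r.tpos = pos; r.strand = 1; }
        }
        id = h.find(rc);
        if (id >= 0) {
          Rec &r = recs[id];
          if (++r.count == 1) { r.chrom = ci + 1; r.tpos = pos; r.strand = -1; }
        }
      }
    }
  }
  // bucket by bait
  int nb = baits.size();
  std::vector<std::vector<const Rec*> > per_bait(nb);
  for (size_t i = 0; i < recs.size(); i++) {
    const Rec &r = recs[i];
    if (!r.dup && r.count == 1) per_bait[r.bait_id].push_back(&r);
  }
  List out(nb);
  for (int bi = 0; bi < nb; bi++) {
    std::vector<const Rec*> &v = per_bait[bi];
    std::sort(v.begin(), v.end(), [](const Rec* a, const Rec* b) {
      return a->bait_pos < b->bait_pos;
    });
    int m = (int)v.size();
    IntegerVector bp(m), ch(m), tp(m), st(m);
    for (int i = 0; i < m; i++) {
      bp[i] = v[i]->bait_pos; ch[i] = v[i]->chrom;
      tp[i] = v[i]->tpos;     st[i] = v[i]->strand;
    }
    out[bi] = DataFrame::create(_["bait_pos"] = bp, _["chrom"] = ch,
                                _["tpos"] = tp, _["strand"] = st);
  }
  return out;
}

// Longest strictly increasing subsequence (patience algorithm); input values
// must be distinct. Returns 1-based indices of one longest subsequence
// (deterministic: among equals the lexicographically smallest tail chain).
// [[Rcpp::export(name = ".cpp_lis")]]
IntegerVector cpp_lis(IntegerVector x) {
  int n = x.size();
  if (n == 0) return IntegerVector(0);
  std::vector<int> tails;        // index of smallest tail of each length
  std::vector<int> tailvals;
  std::vector<int> parent(n, -1);
  tails.reserve(n); tailvals.reserve(n);
  for (int i = 0; i < n; i++) {
    int v = x[i];
    int lo = (int)(std::lower_bound(tailvals.begin(), tailvals.end(), v)
                   - tailvals.begin());
    if (lo == (int)tails.size()) { tails.push_back(i); tailvals.push_back(v); }
    else { tails[lo] = i; tailvals[lo] = v; }
    parent[i] = (lo > 0) ? tails[lo - 1] : -1;
  }
  int len = (int)tails.size();
  IntegerVector out(len);
  int cur = tails[len - 1];
  for (int j = len - 1; j >= 0; j--) { out[j] = cur + 1; cur = parent[cur]; }
  return out;
}

// Banded global alignment with affine gaps (gap of length g costs
// gap_open + g * gap_extend). Rows follow `a` (the bait), columns `b`.
// `center` gives, for every row i = 0..n, the 0-based column the band is
// centred on; the band half-width is `halfw`. With free_query_ends the
// alignment may start at any column of row 0 and end at any column of row
// n at no cost (`a` fully consumed, overhangs of `b` unaligned); the
// emitted strings then cover only b[qstart..qend]. Traceback ties prefer
// diagonal, then gap-in-b (vertical), then gap-in-a (horizontal). Returns
// score, gapped strings, the 1-based aligned span of b, and whether the
// optimal path touched the band edge.
// [[Rcpp::export(name = ".cpp_banded_affine")]]
List cpp_banded_affine(std::string a, std::string b,
                       double match, double mismatch,
                       double gap_open, double gap_extend,
                       IntegerVector center, int halfw,
                       bool free_query_ends) {
  const double NEG = -1e30;
  int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  if (center.size() != n + 1) stop("center must have length nchar(a) + 1");
  int W = 2 * halfw + 1;
  // band bounds per row
  std::vector<int> lo(n + 1), hi(n + 1);
  for (int i = 0; i <= n; i++) {
    int c = center[i];
    lo[i] = std::max(0, c - halfw);
    hi[i] = std::min(m, c + halfw);
    if (lo[i] > hi[i]) stop("band does not intersect columns at row %d", i);
  }
  if (!free_query_ends) {
    if (lo[0] > 0) stop("band does not reach column 0");
    if (hi[n] < m) stop("band does not reach the final column");
  }
  std::vector<double> M(W), X(W), Y(W), pM(W), pX(W), pY(W);
  // traceback: 2 bits per state (0=from M, 1=from X, 2=from Y, 3=invalid)
  // value 0xFF marks an uninitialised cell.
  std::vector<uint8_t> tb((size_t)(n + 1) * W, 0xFF);
  auto off = [&](int i, int j) { return j - lo[i]; };
  // row 0: M[0][0] = 0; free starts give Y[0][j>0] = 0 (an implicit
  // cost-free skip of b[1..j], not a traversed path).
  for (int j = lo[0]; j <= hi[0]; j++) {
    int o = off(0, j);
    M[o] = (j == 0) ? 0.0 : NEG;
    X[o] = NEG;
    if (j == 0) Y[o] = NEG;
    else        Y[o] = free_query_ends ? 0.0 : gap_open + gap_extend * j;
    tb[(size_t)0 * W + o] = (uint8_t)((2 << 4) | 0x0F);  // Y from Y
  }
  for (int i = 1; i <= n; i++) {
    std::swap(pM, M); std::swap(pX, X); std::swap(pY, Y);
    char ac = a[i - 1];
    for (int j = lo[i]; j <= hi[i]; j++) {
      int o = off(i, j);
      double dM = NEG, dX = NEG, dY = NEG;
      int pdiag = (j - 1 >= lo[i - 1] && j - 1 <= hi[i - 1]) ? off(i - 1, j - 1) : -1;
      int pvert = (j >= lo[i - 1] && j <= hi[i - 1]) ? off(i - 1, j) : -1;
      uint8_t tM = 3, tX = 3, tY = 3;
      // M: diagonal
      if (j >= 1 && pdiag >= 0) {
        double s = (ac == b[j - 1] && base_code(ac) >= 0) ? match : mismatch;
        double v0 = pM[pdiag], v1 = pX[pdiag], v2 = pY[pdiag];
        double best = v0; uint8_t t = 0;
        if (v1 > best) { best = v1; t = 1; }
        if (v2 > best) { best = v2; t = 2; }
        if (best > NEG / 2) { dM = best + s; tM = t; }
      }
      // X: vertical, consume a (gap in b)
      if (pvert >= 0) {
        double v0 = pM[pvert] + gap_open + gap_extend;
        double v1 = pX[pvert] + gap_extend;
        double v2 = pY[pvert] + gap_open + gap_extend;
        double best = v0; uint8_t t = 0;
        if (v1 > best) { best = v1; t = 1; }
        if (v2 > best) { best = v2; t = 2; }
        if (best > NEG / 2) { dX = best; tX = t; }
      }
      // Y: horizontal, consume b (gap in a)
      if (j - 1 >= lo[i]) {
        int po = off(i, j - 1);
        double v0 = M[po] + gap_open + gap_extend;
        double v1 = X[po] + gap_open + gap_extend;
        double v2 = Y[po] + gap_extend;
        double best = v0; uint8_t t = 0;
        if (v1 > best) { best = v1; t = 1; }
        if (v2 > best) { best = v2; t = 2; }
        if (best > NEG / 2) { dY = best; tY = t; }
      }
      M[o] = dM; X[o] = dX; Y[o] = dY;
      tb[(size_t)i * W + o] = (uint8_t)((tY << 4) | (tX << 2) | tM);
    }
  }
  // terminal cell
  double score = NEG;
  int state = 0, jend = m;
  bool edge = false;
  if (free_query_ends) {
    for (int j = lo[n]; j <= hi[n]; j++) {
      int o = off(n, j);
      double v[3] = { M[o], X[o], Y[o] };
      for (int s = 0; s < 3; s++) {
        if (v[s] > score || (v[s] == score && j > jend)) {
          // prefer larger j (align as much of b as possible), then M>X>Y
          if (v[s] > score || j > jend) { score = v[s]; state = s; jend = j; }
        }
      }
    }
    if (jend == hi[n] && jend < m) edge = true;
  } else {
    int oend = off(n, m);
    double v[3] = { M[oend], X[oend], Y[oend] };
    score = v[0]; state = 0;
    if (v[1] > score) { score = v[1]; state = 1; }
    if (v[2] > score) { score = v[2]; state = 2; }
    jend = m;
  }
  if (score < NEG / 2) stop("no alignment within band");
  // traceback
  std::string ra, rb;
  ra.reserve(n + 64); rb.reserve(m + 64);
  int i = n, j = jend;
  int qstart = 1, qend = jend;
  while (!(i == 0 && j == 0)) {
    if (i == 0) {
      if (free_query_ends && state == 2) { qstart = j + 1; break; }
      // plain global: leading gap in a traversed along row 0
      ra.push_back('-'); rb.push_back(b[j - 1]);
      j--; state = 2;
      continue;
    }
    if (i < n && (j == lo[i] || j == hi[i]) && j > 0 && j < m) edge = true;
    uint8_t t = tb[(size_t)i * W + off(i, j)];
    if (t == 0xFF) stop("traceback fell out of band");
    int from;
    if (state == 0) {
      from = t & 0x3;
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      i--; j--;
    } else if (state == 1) {
      from = (t >> 2) & 0x3;
      ra.push_back(a[i - 1]); rb.push_back('-');
      i--;
    } else {
      from = (t >> 4) & 0x3;
      ra.push_back('-'); rb.push_back(b[j - 1]);
      j--;
    }
    if (from == 3) stop("invalid traceback state");
    if (i == 0 && j == 0) break;
    state = from;
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = score,
                      _["aligned_a"] = ra,
                      _["aligned_b"] = rb,
                      _["qstart"] = qstart,
                      _["qend"] = qend,
                      _["edge_hit"] = edge);
}

// Multi-pattern binding-site scan. Each pattern is matched against `seq`
// with at most `max_mm` mismatches overall and zero mismatches in its
// `tpe` "exact" bases, which sit at the right end of the window when
// right_exact[i] is TRUE and at the left end otherwise. Non-ACGT characters
// in seq never match. Returns, per pattern, the 1-based window starts.
// [[Rcpp::export(name = ".cpp_scan_sites_multi")]]
List cpp_scan_sites_multi(std::string seq, CharacterVector patterns,
                          LogicalVector right_exact, int max_mm, int tpe) {
  int np = patterns.size();
  if (right_exact.size() != np) stop("right_exact length mismatch");
  if (tpe < 1 || tpe > 8) stop("three_prime_exact_len must be in [1, 8]");
  int tsize = 1 << (2 * tpe);
  std::vector<std::vector<int> > bucket(tsize);
  std::vector<std::string> pats(np);
  std::vector<bool> rex(np);
  for (int p = 0; p < np; p++) {
    pats[p] = as<std::string>(patterns[p]);
    rex[p] = right_exact[p];
    const std::string &s = pats[p];
    if ((int)s.size() < tpe) stop("pattern shorter than exact length");
    int code = 0; bool ok = true;
    for (int i = 0; i < tpe; i++) {
      char c = rex[p] ? s[s.size() - tpe + i] : s[i];
      int b = base_code(c);
      if (b < 0) { ok = false; break; }
      code = (code << 2) | b;
    }
    if (ok) bucket[code].push_back(p);
  }
  std::vector<std::vector<int> > hits(np);
  int n = (int)seq.size();
  int code = 0, run = 0, mask = tsize - 1;
  for (int i = 0; i < n; i++) {
    int b = base_code(seq[i]);
    if (b < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | b) & mask;
    run++;
    if (run < tpe) continue;
    int tstart = i - tpe + 1;  // 0-based start of the exact tpe-mer window
    const std::vector<int> &cand = bucket[code];
    for (size_t c = 0; c < cand.size(); c++) {
      int p = cand[c];
      const std::string &pat = pats[p];
      int L = (int)pat.size();
      int wstart = rex[p] ? (tstart - (L - tpe)) : tstart;
      if (wstart < 0 || wstart + L > n) continue;
      int mm = 0;
      // exact part already matched; check the remainder
      int from = rex[p] ? 0 : tpe;
      int to   = rex[p] ? (L - tpe) : L;
      for (int q = from; q < to; q++) {
        char sc = seq[wstart + q];
        if (sc != pat[q] || base_code(sc) < 0) {
          if (++mm > max_mm) break;
        }
      }
      if (mm <= max_mm) hits[p].push_back(wstart + 1);
    }
  }
  List out(np);
  for (int p = 0; p < np; p++) out[p] = wrap(hits[p]);
  return out;
}
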
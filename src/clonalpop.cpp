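// Low-level sequence machinery for near-identical genome comparison:
//  - unique-k-mer anchoring (MUM-style) with collinear chaining
//  - exact/near-exact read placement for coverage profiling
//  - k-mer-seeded tandem repeat (CRISPR array) detection
//  - word-seeded ungapped local extension (BLASTN-like, no gaps)
// All coordinates are 0-based half-open on the forward strand.

#include <Rcpp.h>
#include <unordered_map>
#include <set>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Map each k-mer to its position, or -2 when it occurs more than once.
static void index_unique_kmers(const std::string& s, int k,
                               std::unordered_map<uint64_t, int64_t>& map) {
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t cur = 0;
  int run = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; cur = 0; continue; }
    cur = ((cur << 2) | (uint64_t)c) & mask;
    if (++run >= k) {
      int64_t pos = (int64_t)i - k + 1;
      auto it = map.find(cur);
      if (it == map.end()) map.emplace(cur, pos); else it->second = -2;
    }
  }
}

struct Anchor { int64_t r, q, len; };

// Maximal exact matches seeded by k-mers unique in both sequences, chained
// into the highest-total-length collinear subset (weighted LIS on ref order,
// ties broken toward smaller reference start), overlaps trimmed so the chain
// is strictly increasing and non-overlapping on both coordinate systems.
// [[Rcpp::export]]
DataFrame cpp_anchor_chain(std::string ref, std::string query, int k) {
  std::unordered_map<uint64_t, int64_t> rmap, qmap;
  index_unique_kmers(ref, k, rmap);
  index_unique_kmers(query, k, qmap);

  // seeds: (ref_pos, query_pos) where the k-mer is unique in both
  std::vector<std::pair<int64_t, int64_t> > seeds;
  {
    const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    uint64_t cur = 0; int run = 0;
    for (size_t i = 0; i < query.size(); ++i) {
      int c = base_code(query[i]);
      if (c < 0) { run = 0; cur = 0; continue; }
      cur = ((cur << 2) | (uint64_t)c) & mask;
      if (++run >= k) {
        int64_t qpos = (int64_t)i - k + 1;
        auto qi = qmap.find(cur);
        if (qi == qmap.end() || qi->second < 0) continue;
        auto ri = rmap.find(cur);
        if (ri == rmap.end() || ri->second < 0) continue;
        seeds.push_back(std::make_pair(ri->second, qpos));
      }
    }
  }
  std::sort(seeds.begin(), seeds.end());

  // merge runs of diagonal-consecutive seeds, then extend maximally
  std::vector<Anchor> anchors;
  size_t i = 0;
  while (i < seeds.size()) {
    size_t j = i;
    while (j + 1 < seeds.size() &&
           seeds[j + 1].first == seeds[j].first + 1 &&
           seeds[j + 1].second == seeds[j].second + 1) ++j;
    int64_t r0 = seeds[i].first, q0 = seeds[i].second;
    int64_t len = (seeds[j].first - r0) + k;
    while (r0 > 0 && q0 > 0 && ref[r0 - 1] == query[q0 - 1] &&
           base_code(ref[r0 - 1]) >= 0) { --r0; --q0; ++len; }
    while (r0 + len < (int64_t)ref.size() && q0 + len < (int64_t)query.size() &&
           ref[r0 + len] == query[q0 + len] &&
           base_code(ref[r0 + len]) >= 0) ++len;
    Anchor a; a.r = r0; a.q = q0; a.len = len;
    anchors.push_back(a);
    i = j + 1;
  }
  // dedupe extended anchors (seed runs inside one maximal match converge)
  std::sort(anchors.begin(), anchors.end(),
            [](const Anchor& a, const Anchor& b) {
              if (a.r != b.r) return a.r < b.r;
              if (a.q != b.q) return a.q < b.q;
              return a.len > b.len;
            });
  anchors.erase(std::unique(anchors.begin(), anchors.end(),
                            [](const Anchor& a, const Anchor& b) {
                              return a.r == b.r && a.q == b.q && a.len == b.len;
                            }), anchors.end());

  // weighted LIS: strictly increasing starts on both coordinates
  int n = (int)anchors.size();
  std::vector<int64_t> best(n, 0);
  std::vector<int> prev(n, -1);
  int end_i = -1; int64_t end_score = -1;
  for (int a = 0; a < n; ++a) {
    best[a] = anchors[a].len;
    for (int b = 0; b < a; ++b) {
      if (anchors[b].r < anchors[a].r && anchors[b].q < anchors[a].q) {
        int64_t cand = best[b] + anchors[a].len;
        if (cand > best[a]) { best[a] = cand; prev[a] = b; }
      }
    }
    if (best[a] > end_score) { end_score = best[a]; end_i = a; }
  }
  std::vector<int> chain;
  for (int a = end_i; a >= 0; a = prev[a]) chain.push_back(a);
  std::reverse(chain.begin(), chain.end());

  // trim overlaps (exact-match substrings stay exact matches)
  std::vector<Anchor> out;
  for (size_t c = 0; c < chain.size(); ++c) {
    Anchor a = anchors[chain[c]];
    if (!out.empty()) {
      const Anchor& p = out.back();
      int64_t trim = std::max((int64_t)0,
        std::max(p.r + p.len - a.r, p.q + p.len - a.q));
      a.r += trim; a.q += trim; a.len -= trim;
      if (a.len <= 0) continue;
    }
    out.push_back(a);
  }

  int m = (int)out.size();
  IntegerVector rs(m), re(m), qs(m), qe(m);
  for (int a = 0; a < m; ++a) {
    rs[a] = (int)out[a].r; re[a] = (int)(out[a].r + out[a].len);
    qs[a] = (int)out[a].q; qe[a] = (int)(out[a].q + out[a].len);
  }
  return DataFrame::create(_["ref_start"] = rs, _["ref_end"] = re,
                           _["query_start"] = qs, _["query_end"] = qe);
}

// Place reads on a reference by exact k-mer seeding at a few fixed offsets,
// verifying with at most `max_mismatch` substitutions over the full read.
// Best placement = fewest mismatches, ties to the leftmost coordinate.
// Returns (pos, mismatches), pos = -1 for unplaced reads.
// [[Rcpp::export]]
IntegerMatrix cpp_place_reads(CharacterVector reads, std::string ref,
                              int k, int max_mismatch) {
  std::unordered_map<uint64_t, std::vector<int> > idx;
  {
    const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    uint64_t cur = 0; int run = 0;
    for (size_t i = 0; i < ref.size(); ++i) {
      int c = base_code(ref[i]);
      if (c < 0) { run = 0; cur = 0; continue; }
      cur = ((cur << 2) | (uint64_t)c) & mask;
      if (++run >= k) idx[cur].push_back((int)i - k + 1);
    }
  }
  int n = reads.size();
  IntegerMatrix out(n, 2);
  const int64_t rlen = (int64_t)ref.size();
  for (int r = 0; r < n; ++r) {
    const char* rd = CHAR(STRING_ELT(reads, r));
    int L = (int)LENGTH(STRING_ELT(reads, r));
    int best_pos = -1, best_mm = max_mismatch + 1;
    std::set<int> tried;
    for (int off = 0; off + k <= L; off += k) {
      uint64_t cur = 0; bool ok = true;
      for (int t = 0; t < k; ++t) {
        int c = base_code(rd[off + t]);
        if (c < 0) { ok = false; break; }
        cur = (cur << 2) | (uint64_t)c;
      }
      if (!ok) continue;
      auto it = idx.find(cur);
      if (it == idx.end()) continue;
      for (size_t h = 0; h < it->second.size(); ++h) {
        int pos = it->second[h] - off;
        if (pos < 0 || (int64_t)pos + L > rlen) continue;
        if (!tried.insert(pos).second) continue;
        int mm = 0;
        for (int t = 0; t < L && mm <= max_mismatch; ++t)
          if (ref[pos + t] != rd[t]) ++mm;
        if (mm < best_mm || (mm == best_mm && pos < best_pos)) {
          best_mm = mm; best_pos = pos;
        }
      }
    }
    if (best_mm > max_mismatch) { out(r, 0) = -1; out(r, 1) = NA_INTEGER; }
    else { out(r, 0) = best_pos; out(r, 1) = best_mm; }
  }
  return out;
}

static std::vector<int> find_all(const std::string& hay, const std::string& pat) {
  std::vector<int> hits;
  size_t p = hay.find(pat, 0);
  while (p != std::string::npos) {
    hits.push_back((int)p);
    p = hay.find(pat, p + 1);
  }
  return hits;
}

// CRT-like tandem repeat finder: exact seed k-mers recurring at CRISPR-like
// periods nominate a repeat unit (maximal common substring around the pair,
// refined by end-trimming); arrays are chains of >= min_copies exact repeat
// occurrences separated by spacers within [min_spacer, max_spacer].
// [[Rcpp::export]]
List cpp_detect_arrays(std::string seq, int seed_k, int min_rep, int max_rep,
                       int min_spacer, int max_spacer, int min_copies) {
  const int min_period = min_rep + min_spacer;
  const int max_period = max_rep + max_spacer;
  const int nbuck = 1 << (2 * seed_k);
  std::vector<std::vector<int> > buck(nbuck);
  {
    uint64_t cur = 0; int run = 0;
    const uint64_t mask = (1ULL << (2 * seed_k)) - 1;
    for (size_t i = 0; i < seq.size(); ++i) {
      int c = base_code(seq[i]);
      if (c < 0) { run = 0; cur = 0; continue; }
      cur = ((cur << 2) | (uint64_t)c) & mask;
      if (++run >= seed_k) buck[cur].push_back((int)i - seed_k + 1);
    }
  }
  std::vector<std::pair<int, int> > cand; // (pos, period)
  for (int b = 0; b < nbuck; ++b) {
    const std::vector<int>& v = buck[b];
    for (size_t a = 0; a + 1 < v.size(); ++a)
      for (size_t c = a + 1; c < v.size(); ++c) {
        int d = v[c] - v[a];
        if (d > max_period) break;
        if (d >= min_period) cand.push_back(std::make_pair(v[a], d));
      }
  }
  std::sort(cand.begin(), cand.end());

  std::vector<char> covered(seq.size(), 0);
  std::set<std::string> tried;
  List arrays;
  for (size_t ci = 0; ci < cand.size(); ++ci) {
    int p = cand[ci].first, d = cand[ci].second;
    if (covered[p]) continue;
    // maximal common substring around the two occurrences
    int l = 0, len = seed_k;
    int q = p + d;
    while (p - l > 0 && seq[p - l - 1] == seq[q - l - 1] &&
           len < max_rep + 6) { ++l; ++len; }
    while (p + len - l < q && q + len - l < (int)seq.size() &&
           seq[p - l + len] == seq[q - l + len] &&
           len < max_rep + 6) ++len;
    if (len < min_rep || len > max_rep + 5) continue;
    int start0 = p - l;
    // refine: trim chance extensions into flanking spacers, keep the
    // trim giving the most chained copies (then the longest repeat)
    std::string base = seq.substr(start0, len);
    if (!tried.insert(base).second) continue;
    // choose the end-trim whose occurrence chain through this candidate has
    // the most copies (then the longest repeat)
    int best_copies = 0;
    std::string best_rep;
    for (int tl = 0; tl <= 3; ++tl) {
      for (int tr = 0; tr <= 3; ++tr) {
        int rl = len - tl - tr;
        if (rl < min_rep || rl > max_rep) continue;
        std::string rep = base.substr(tl, rl);
        std::vector<int> occ = find_all(seq, rep);
        if ((int)occ.size() < min_copies) continue;
        size_t a = 0;
        while (a < occ.size()) {
          size_t b = a;
          while (b + 1 < occ.size()) {
            int sp = occ[b + 1] - (occ[b] + rl);
            if (sp < min_spacer || sp > max_spacer) break;
            ++b;
          }
          int copies = (int)(b - a + 1);
          bool contains = occ[a] <= start0 + tl && start0 + tl <= occ[b];
          if (contains && copies >= min_copies &&
              (copies > best_copies ||
               (copies == best_copies && rl > (int)best_rep.size()))) {
            best_copies = copies;
            best_rep = rep;
          }
          a = b + 1;
        }
      }
    }
    if (best_copies >= min_copies) {
      // the same repeat may form several arrays genome-wide; accept every
      // qualifying chain not already covered
      int rl = (int)best_rep.size();
      std::vector<int> occ = find_all(seq, best_rep);
      size_t a = 0;
      while (a < occ.size()) {
        size_t b = a;
        while (b + 1 < occ.size()) {
          int sp = occ[b + 1] - (occ[b] + rl);
          if (sp < min_spacer || sp > max_spacer) break;
          ++b;
        }
        int copies = (int)(b - a + 1);
        if (copies >= min_copies && !covered[occ[a]]) {
          int first = occ[a], last = occ[b] + rl;
          for (int t = first; t < last; ++t) covered[t] = 1;
          std::vector<int> starts(occ.begin() + a, occ.begin() + b + 1);
          arrays.push_back(List::create(
            _["start"] = first, _["end"] = last,
            _["repeat"] = best_rep,
            _["repeat_starts"] = IntegerVector(starts.begin(),
                                               starts.end())));
        }
        a = b + 1;
      }
    }
  }
  return arrays;
}

// Word-seeded ungapped local alignment (fixed match/mismatch scores).
// Every seeded diagonal is extended to its maximal-scoring segment with an
// X-drop bound; segments scoring >= min_score are returned (deduplicated).
// [[Rcpp::export]]
DataFrame cpp_seed_extend(std::string query, std::string subject, int word,
                          int match, int mismatch, int min_score) {
  const int xdrop = 20;
  const int nbuck = 1 << (2 * word);
  std::vector<std::vector<int> > buck(nbuck);
  {
    uint64_t cur = 0; int run = 0;
    const uint64_t mask = (1ULL << (2 * word)) - 1;
    for (size_t i = 0; i < subject.size(); ++i) {
      int c = base_code(subject[i]);
      if (c < 0) { run = 0; cur = 0; continue; }
      cur = ((cur << 2) | (uint64_t)c) & mask;
      if (++run >= word) buck[cur].push_back((int)i - word + 1);
    }
  }
  std::set<std::tuple<int, int, int> > seen; // (diag, q_start, q_end)
  std::vector<int> qs_v, qe_v, ss_v, sc_v, id_v;
  const int qlen = (int)query.size(), slen = (int)subject.size();
  uint64_t cur = 0; int run = 0;
  const uint64_t mask = (1ULL << (2 * word)) - 1;
  for (int i = 0; i < qlen; ++i) {
    int c = base_code(query[i]);
    if (c < 0) { run = 0; cur = 0; continue; }
    cur = ((cur << 2) | (uint64_t)c) & mask;
    if (++run < word) continue;
    int qpos = i - word + 1;
    const std::vector<int>& v = buck[cur];
    for (size_t h = 0; h < v.size(); ++h) {
      int spos = v[h];
      int diag = spos - qpos;
      int sc = word * match;
      // extend left from (qpos-1, spos-1), keeping the best-scoring extent
      int bl = 0, blo = 0;
      { int cl = 0, off = 1;
        while (qpos - off >= 0 && spos - off >= 0) {
          cl += (query[qpos - off] == subject[spos - off]) ? match : mismatch;
          if (cl > bl) { bl = cl; blo = off; }
          if (cl < bl - xdrop) break;
          ++off;
        }
      }
      // extend right from (qpos+word, spos+word)
      int br = 0, cr = 0, bro = 0, off = 0;
      while (qpos + word + off < qlen && spos + word + off < slen) {
        cr += (query[qpos + word + off] == subject[spos + word + off])
          ? match : mismatch;
        if (cr > br) { br = cr; bro = off + 1; }
        if (cr < br - xdrop) break;
        ++off;
      }
      int total = sc + bl + br;
      if (total < min_score) continue;
      int q_start = qpos - blo, q_end = qpos + word + bro;
      if (!seen.insert(std::make_tuple(diag, q_start, q_end)).second) continue;
      int s_start = q_start + diag;
      int nid = 0;
      for (int t = 0; t < q_end - q_start; ++t)
        if (query[q_start + t] == subject[s_start + t]) ++nid;
      qs_v.push_back(q_start); qe_v.push_back(q_end);
      ss_v.push_back(s_start); sc_v.push_back(total); id_v.push_back(nid);
    }
  }
  return DataFrame::create(
    _["q_start"] = IntegerVector(qs_v.begin(), qs_v.end()),
    _["q_end"] = IntegerVector(qe_v.begin(), qe_v.end()),
    _["s_start"] = IntegerVector(ss_v.begin(), ss_v.end()),
    _["score"] = IntegerVector(sc_v.begin(), sc_v.end()),
    _["n_ident"] = IntegerVector(id_v.begin(), id_v.end()));
}
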
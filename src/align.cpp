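// Anchor-chaining local aligner used for placing gap flanks on a donor
// assembly: exact k-mer anchors (2-bit rolling hash; N never anchors),
// greedy colinear chaining with a diagonal-drift tolerance, and a banded
// global alignment (match +1, mismatch -1, gap -2; N matches nothing) of
// each kept cluster's spanned substrings.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <climits>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

struct KmerIndex {
  int k;
  std::vector<std::string> seqs;   // uppercased copies
  std::unordered_map<uint64_t, std::vector<std::pair<int32_t,int32_t>>> map;
};

static std::string upper_copy(const std::string& s) {
  std::string u(s);
  for (auto& c : u) if (c >= 'a' && c <= 'z') c -= 32;
  return u;
}

static std::string revcomp_upper(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'C': c = 'G'; break;
      case 'G': c = 'C'; break; case 'T': c = 'A'; break;
      default: c = 'N';
    }
  }
  return r;
}

// [[Rcpp::export]]
SEXP cpp_kmer_index(CharacterVector seqs, int k) {
  if (k < 2 || k > 31) stop("k must be in [2, 31]");
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  for (int s = 0; s < seqs.size(); ++s) {
    idx->seqs.push_back(upper_copy(as<std::string>(seqs[s])));
    const std::string& S = idx->seqs.back();
    uint64_t h = 0; int run = 0;
    for (int32_t i = 0; i < (int32_t)S.size(); ++i) {
      int b = base_code(S[i]);
      if (b < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)b) & mask;
      if (++run >= k) idx->map[h].push_back({(int32_t)s, i - k + 1});
    }
  }
  return XPtr<KmerIndex>(idx, true);
}

struct AlnCell { int score, matches, cols; };

// banded global alignment of a vs b (uppercase, may contain N).
// Returns matches and aligned columns on the optimal path.
static void banded_global(const std::string& a, const std::string& b,
                          int band, int& matches_out, int& cols_out) {
  const int la = (int)a.size(), lb = (int)b.size();
  if (la == 0 || lb == 0) { matches_out = 0; cols_out = la + lb; return; }
  if (a == b && a.find('N') == std::string::npos) {
    matches_out = la; cols_out = la; return;   // provably optimal
  }
  const int dmin = std::min(0, lb - la) - band;
  const int dmax = std::max(0, lb - la) + band;
  const int NEG = INT_MIN / 4;
  std::vector<AlnCell> prev(lb + 2), cur(lb + 2);
  for (int j = 0; j <= lb + 1; ++j) { prev[j] = {NEG, 0, 0}; cur[j] = {NEG, 0, 0}; }
  for (int j = 0; j <= std::min(lb, dmax); ++j) prev[j] = {-2 * j, 0, j};
  for (int i = 1; i <= la; ++i) {
    const int jlo = std::max(0, i + dmin), jhi = std::min(lb, i + dmax);
    if (jlo >= 1) cur[jlo - 1].score = NEG;   // left band boundary
    const char qc = a[i - 1];
    for (int j = jlo; j <= jhi; ++j) {
      int best = NEG, bm = 0, bc = 0;
      if (j >= 1 && prev[j - 1].score > NEG) {
        const char dc = b[j - 1];
        const bool m = (qc == dc) && qc != 'N' && dc != 'N';
        const int sc = prev[j - 1].score + (m ? 1 : -1);
        if (sc > best) { best = sc; bm = prev[j - 1].matches + (m ? 1 : 0);
                         bc = prev[j - 1].cols + 1; }
      }
      if (prev[j].score > NEG) {                 // gap in b (query consumed)
        const int sc = prev[j].score - 2;
        if (sc > best) { best = sc; bm = prev[j].matches; bc = prev[j].cols + 1; }
      }
      if (j >= 1 && cur[j - 1].score > NEG) {    // gap in a (donor consumed)
        const int sc = cur[j - 1].score - 2;
        if (sc > best) { best = sc; bm = cur[j - 1].matches; bc = cur[j - 1].cols + 1; }
      }
      cur[j] = {best, bm, bc};
    }
    cur[jhi + 1].score = NEG;   // right band boundary for the next row
    std::swap(prev, cur);
  }
  matches_out = prev[lb].matches;
  cols_out = prev[lb].cols;
}

// [[Rcpp::export]]
List cpp_banded_global(std::string a, std::string b, int band) {
  int m, c;
  banded_global(upper_copy(a), upper_copy(b), band, m, c);
  return List::create(_["matches"] = m, _["columns"] = c);
}

struct Chain {
  int32_t first_q, first_d, last_q, last_d, q_end, d_end;
  int32_t seq;
};

struct Hit { int32_t q, d; };

// chain anchors of one (donor sequence, strand) group; anchors arrive
// sorted by (q, d)
static void chain_hits(const std::vector<Hit>& hits, int k, int max_gap,
                       int diag_tol, int32_t seq, std::vector<Chain>& out) {
  std::vector<Chain> chains;
  std::vector<int> active;
  for (const Hit& h : hits) {
    // retire chains that can no longer accept anchors (q is monotone)
    size_t w = 0;
    for (size_t t = 0; t < active.size(); ++t) {
      if (h.q - chains[active[t]].q_end <= max_gap) active[w++] = active[t];
      else out.push_back(chains[active[t]]);
    }
    active.resize(w);
    int best = -1; long bestdiff = LONG_MAX;
    for (int idx : active) {
      const Chain& c = chains[idx];
      if (h.q < c.last_q || h.d < c.last_d) continue;
      if (h.d - c.d_end > max_gap) continue;
      long diff = std::labs((long)(h.d - h.q) - (long)(c.last_d - c.last_q));
      if (diff > diag_tol) continue;
      if (diff < bestdiff) { bestdiff = diff; best = idx; }
    }
    if (best >= 0) {
      Chain& c = chains[best];
      c.last_q = h.q; c.last_d = h.d;
      c.q_end = h.q + k; c.d_end = h.d + k;
    } else {
      chains.push_back({h.q, h.d, h.q, h.d, h.q + k, h.d + k, seq});
      active.push_back((int)chains.size() - 1);
    }
  }
  for (int idx : active) out.push_back(chains[idx]);
}

// collect anchors of `query` (already oriented + uppercased) against the
// index, grouped per donor sequence (anchors stay (q, d)-sorted)
static void collect_hits(const KmerIndex& idx, const std::string& query,
                         std::unordered_map<int32_t, std::vector<Hit>>& per_seq) {
  const int k = idx.k;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  uint64_t h = 0; int run = 0;
  for (int32_t i = 0; i < (int32_t)query.size(); ++i) {
    int b = base_code(query[i]);
    if (b < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)b) & mask;
    if (++run >= k) {
      auto it = idx.map.find(h);
      if (it != idx.map.end()) {
        for (const auto& pr : it->second) {
          per_seq[pr.first].push_back({i - k + 1, pr.second});
        }
      }
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_align_flank(SEXP index_ptr, std::string flank, int min_cluster,
                          int max_anchor_gap, double band_frac, int diag_tol,
                          int min_band) {
  XPtr<KmerIndex> idx(index_ptr);
  const int k = idx->k;
  const int L = (int)flank.size();
  std::vector<int> o_seq, o_ds, o_de, o_qs, o_qe, o_match, o_cols;
  std::vector<std::string> o_strand;
  for (int strand = 0; strand < 2; ++strand) {
    std::string q = (strand == 0) ? upper_copy(flank) : revcomp_upper(flank);
    std::unordered_map<int32_t, std::vector<Hit>> per_seq;
    collect_hits(*idx, q, per_seq);
    std::vector<int32_t> seq_ids;
    for (auto& kv : per_seq) seq_ids.push_back(kv.first);
    std::sort(seq_ids.begin(), seq_ids.end());
    for (int32_t s : seq_ids) {
      std::vector<Chain> chains;
      chain_hits(per_seq[s], k, max_anchor_gap, diag_tol, s, chains);
      for (const Chain& c : chains) {
        if (c.q_end - c.first_q < min_cluster) continue;
        const std::string qsub = q.substr(c.first_q, c.q_end - c.first_q);
        const std::string dsub = idx->seqs[s].substr(c.first_d, c.d_end - c.first_d);
        const int band = std::max(min_band,
            (int)std::ceil(band_frac * std::max(qsub.size(), dsub.size())));
        int m, cols;
        banded_global(qsub, dsub, band, m, cols);
        int fqs, fqe;   // query interval in forward flank frame
        if (strand == 0) { fqs = c.first_q; fqe = c.q_end; }
        else { fqs = L - c.q_end; fqe = L - c.first_q; }
        o_seq.push_back(s + 1);
        o_ds.push_back(c.first_d); o_de.push_back(c.d_end);
        o_qs.push_back(fqs); o_qe.push_back(fqe);
        o_match.push_back(m); o_cols.push_back(cols);
        o_strand.push_back(strand == 0 ? "+" : "-");
      }
    }
  }
  return DataFrame::create(
    _["donor_idx"] = o_seq, _["donor_start"] = o_ds, _["donor_end"] = o_de,
    _["strand"] = o_strand, _["query_start"] = o_qs, _["query_end"] = o_qe,
    _["matches"] = o_match, _["aligned_cols"] = o_cols,
    _["stringsAsFactors"] = false);
}
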
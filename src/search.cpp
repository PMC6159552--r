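#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <unordered_map>
#include <unordered_set>
#include <string>

using namespace Rcpp;

// Ungapped seed-and-extend local search: exact seed-word anchoring on shared
// diagonals followed by a maximal-scoring-segment (Kadane) scan of each
// anchored diagonal. Scoring uses blastn ungapped defaults
// (reward +2, penalty -3; lambda = 0.625, K = 0.41) so bit scores are on the
// familiar blastn scale.

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

static inline char comp(char c) {
  switch (c) {
  case 'A': case 'a': return 'T';
  case 'C': case 'c': return 'G';
  case 'G': case 'g': return 'C';
  case 'T': case 't': return 'A';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) r[s.size() - 1 - i] = comp(s[i]);
  return r;
}

struct Hit {
  int query, subject;
  int qstart, qend, sstart, send; // 0-based half-open, forward strand coords
  int length, matches;
  double raw;
  char strand;
};

// Scan one diagonal of (query, subject), emit the maximal-scoring segment.
static void scan_diagonal(const std::string& q, const std::string& s,
                          long diag, double reward, double penalty,
                          double min_raw, std::vector<Hit>& out,
                          int qi, int si, char strand, int slen_orig) {
  int q0 = (int) std::max(0L, diag);
  int s0 = (int) std::max(0L, -diag);
  int len = std::min((int) q.size() - q0, (int) s.size() - s0);
  if (len <= 0) return;

  double best = 0, cur = 0;
  int cur_start = 0, best_start = 0, best_end = -1;
  for (int i = 0; i < len; ++i) {
    int a = base_code(q[q0 + i]), b = base_code(s[s0 + i]);
    double sc = (a != 4 && a == b) ? reward : -penalty;
    cur += sc;
    if (cur <= 0) { cur = 0; cur_start = i + 1; continue; }
    if (cur > best) { best = cur; best_start = cur_start; best_end = i + 1; }
  }
  if (best < min_raw || best_end < 0) return;

  int m = 0;
  for (int i = best_start; i < best_end; ++i) {
    int a = base_code(q[q0 + i]), b = base_code(s[s0 + i]);
    if (a != 4 && a == b) ++m;
  }
  Hit h;
  h.query = qi; h.subject = si;
  h.qstart = q0 + best_start; h.qend = q0 + best_end;
  int sa = s0 + best_start, sb = s0 + best_end;
  if (strand == '+') { h.sstart = sa; h.send = sb; }
  else { h.sstart = slen_orig - sb; h.send = slen_orig - sa; }
  h.length = best_end - best_start;
  h.matches = m;
  h.raw = best;
  h.strand = strand;
  out.push_back(h);
}

// [[Rcpp::export(name = ".seed_search_cpp")]]
DataFrame seed_search_cpp(CharacterVector query_ids, CharacterVector query_seqs,
                          CharacterVector subject_ids, CharacterVector subject_seqs,
                          int seed_len, double reward, double penalty,
                          double min_raw, double lambda, double K) {
  if (seed_len < 4 || seed_len > 31) stop("seed_len must be in [4, 31]");
  const uint64_t mask = (1ULL << (2 * seed_len)) - 1;
  std::vector<Hit> hits;

  for (int qi = 0; qi < query_seqs.size(); ++qi) {
    std::string q = as<std::string>(query_seqs[qi]);
    if ((int) q.size() < seed_len) continue;

    // index seed words of the query
    std::unordered_map<uint64_t, std::vector<int> > index;
    index.reserve(q.size());
    uint64_t w = 0; int valid = 0;
    for (int i = 0; i < (int) q.size(); ++i) {
      int c = base_code(q[i]);
      if (c == 4) { valid = 0; w = 0; continue; }
      w = ((w << 2) | (uint64_t) c) & mask;
      if (++valid >= seed_len) index[w].push_back(i - seed_len + 1);
    }

    for (int si = 0; si < subject_seqs.size(); ++si) {
      std::string s_fwd = as<std::string>(subject_seqs[si]);
      if ((int) s_fwd.size() < seed_len) continue;
      int slen = (int) s_fwd.size();
      for (int strand = 0; strand < 2; ++strand) {
        std::string s = strand == 0 ? s_fwd : revcomp(s_fwd);
        std::unordered_set<long> diags;
        uint64_t v = 0; int ok = 0;
        for (int j = 0; j < (int) s.size(); ++j) {
          int c = base_code(s[j]);
          if (c == 4) { ok = 0; v = 0; continue; }
          v = ((v << 2) | (uint64_t) c) & mask;
          if (++ok >= seed_len) {
            auto it = index.find(v);
            if (it == index.end()) continue;
            int spos = j - seed_len + 1;
            for (int qpos : it->second) diags.insert((long) qpos - spos);
          }
        }
        for (long d : diags)
          scan_diagonal(q, s, d, reward, penalty, min_raw, hits,
                        qi, si, strand == 0 ? '+' : '-', slen);
      }
    }
  }

  int n = (int) hits.size();
  CharacterVector qid(n), sid(n), strand(n);
  IntegerVector qs(n), qe(n), ss(n), se(n), len(n), mat(n);
  NumericVector pid(n), bits(n), raw(n);
  for (int i = 0; i < n; ++i) {
    const Hit& h = hits[i];
    qid[i] = query_ids[h.query];
    sid[i] = subject_ids[h.subject];
    qs[i] = h.qstart; qe[i] = h.qend; ss[i] = h.sstart; se[i] = h.send;
    len[i] = h.length; mat[i] = h.matches;
    pid[i] = 100.0 * h.matches / h.length;
    raw[i] = h.raw;
    bits[i] = (lambda * h.raw - std::log(K)) / std::log(2.0);
    strand[i] = h.strand == '+' ? "+" : "-";
  }
  return DataFrame::create(
    _["contig_id"] = qid, _["subject_id"] = sid,
    _["pct_identity"] = pid, _["length"] = len, _["matches"] = mat,
    _["bit_score"] = bits, _["raw_score"] = raw,
    _["start"] = qs, _["end"] = qe,
    _["subject_start"] = ss, _["subject_end"] = se,
    _["strand"] = strand,
    _["stringsAsFactors"] = false);
}
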
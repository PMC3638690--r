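#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static inline int base_digit(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

// clean_run[p] = number of consecutive A/C/G/T characters starting at p;
// a window of length L at p is clean iff clean_run[p] >= L
static std::vector<int> clean_run_of(const std::string& s) {
  const int n = (int)s.size();
  std::vector<int> run(n + 1, 0);
  for (int p = n - 1; p >= 0; --p)
    run[p] = (base_digit(s[p]) >= 0) ? run[p + 1] + 1 : 0;
  run.pop_back();
  return run;
}

// 0-based starts of clean length-l windows, per sequence
// [[Rcpp::export]]
List cpp_clean_windows(CharacterVector seqs, int l) {
  const int ns = seqs.size();
  List out(ns);
  for (int i = 0; i < ns; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::vector<int> run = clean_run_of(s);
    std::vector<int> starts;
    const int nw = (int)s.size() - l + 1;
    for (int p = 0; p < nw; ++p)
      if (run[p] >= l) starts.push_back(p);
    out[i] = wrap(starts);
  }
  return out;
}

typedef std::pair<int, int> Occ;  // (seq index, start), both 0-based

struct Engine {
  std::vector<std::string> seq;
  std::vector<std::vector<int>> run;
  std::vector<int> est;             // EST identity of each sequence slot
  int l, d;
  bool within_est;
  std::vector<std::vector<uint8_t>> marks;

  Engine(const CharacterVector& seqs, const IntegerVector& est_ids,
         int l_, int d_, bool within_est_)
      : l(l_), d(d_), within_est(within_est_) {
    const int ns = seqs.size();
    seq.resize(ns);
    run.resize(ns);
    est.assign(est_ids.begin(), est_ids.end());
    marks.resize(ns);
    for (int i = 0; i < ns; ++i) {
      seq[i] = as<std::string>(seqs[i]);
      run[i] = clean_run_of(seq[i]);
      int nw = (int)seq[i].size() - l + 1;
      marks[i].assign(nw > 0 ? nw : 0, 0);
    }
  }

  inline bool clean(int s, int p, int len) const {
    return p >= 0 && p + len <= (int)seq[s].size() && run[s][p] >= len;
  }

  inline void mark_pair_if_close(int s1, int a, int s2, int b) {
    const char* x = seq[s1].data() + a;
    const char* y = seq[s2].data() + b;
    int mm = 0;
    for (int t = 0; t < l; ++t) {
      mm += (x[t] != y[t]);
      if (mm > d) return;
    }
    marks[s1][a] = 1;
    marks[s2][b] = 1;
  }

  List marked_starts() const {
    List out(marks.size());
    for (size_t i = 0; i < marks.size(); ++i) {
      std::vector<int> v;
      for (size_t p = 0; p < marks[i].size(); ++p)
        if (marks[i][p]) v.push_back((int)p);
      out[i] = wrap(v);
    }
    return out;
  }
};

// Filtration engine: index length-q seeds, pair occurrences within a bucket
// and (for m >= 1) across m-mutant buckets, extend each pair at every
// block-aligned offset, verify HD <= d, mark both l-mer windows.
// owned_keys restricts phase two to a subset of seed codes (parallel mode):
// a bucket's within-bucket pairs and all its mutant pairs with HIGHER codes
// are owned by that bucket's key.
// [[Rcpp::export]]
List cpp_find_nonunique(CharacterVector seqs, IntegerVector est_ids,
                        int l, int d, int q, int k, int m,
                        bool within_est,
                        Nullable<NumericVector> owned_keys = R_NilValue) {
  if (q < 1 || q > 25) stop("q must be in [1, 25]");
  if (m < 0 || m > 2) stop("per-block mismatch budget m must be 0, 1 or 2");
  Engine eng(seqs, est_ids, l, d, within_est);
  const int ns = eng.seq.size();

  // phase one: file every clean q-window under its 2-bit code
  std::unordered_map<uint64_t, std::vector<Occ>> table;
  for (int i = 0; i < ns; ++i) {
    const std::string& s = eng.seq[i];
    const int nw = (int)s.size() - q + 1;
    for (int p = 0; p < nw; ++p) {
      if (eng.run[i][p] < q) continue;
      uint64_t code = 0;
      for (int t = 0; t < q; ++t) code = code * 4 + base_digit(s[p + t]);
      table[code].push_back(Occ(i, p));
    }
  }

  bool restrict_keys = owned_keys.isNotNull();
  std::unordered_set<uint64_t> owned;
  if (restrict_keys) {
    NumericVector ks(owned_keys);
    for (double kk : ks) owned.insert((uint64_t)kk);
  }

  // extension: candidate l-mer starts are block-aligned (seed at offset j*q)
  auto extend_pair = [&](int s1, int p1, int s2, int p2) {
    if (s1 == s2 && p1 == p2) return;
    if (!within_est && eng.est[s1] == eng.est[s2]) return;
    for (int j = 0; j < k; ++j) {
      const int a = p1 - j * q, b = p2 - j * q;
      if (!eng.clean(s1, a, l) || !eng.clean(s2, b, l)) continue;
      if (s1 == s2 && a == b) continue;
      eng.mark_pair_if_close(s1, a, s2, b);
    }
  };

  std::vector<int> dig(q);
  for (const auto& kv : table) {
    const uint64_t c = kv.first;
    if (restrict_keys && !owned.count(c)) continue;
    const std::vector<Occ>& bucket = kv.second;

    // same-bucket pass: all unordered occurrence pairs
    for (size_t i = 0; i + 1 < bucket.size(); ++i)
      for (size_t j = i + 1; j < bucket.size(); ++j)
        extend_pair(bucket[i].first, bucket[i].second,
                    bucket[j].first, bucket[j].second);

    if (m == 0) continue;

    // mutant cross pass: each unordered bucket pair (c, c') visited once,
    // from the lower code
    uint64_t cc = c;
    for (int t = q - 1; t >= 0; --t) { dig[t] = (int)(cc & 3); cc >>= 2; }
    std::vector<uint64_t> pw(q);
    for (int t = 0; t < q; ++t) pw[t] = (uint64_t)1 << (2 * (q - 1 - t));

    auto cross = [&](uint64_t c2) {
      if (c2 <= c) return;
      auto it = table.find(c2);
      if (it == table.end()) return;
      for (const Occ& o1 : bucket)
        for (const Occ& o2 : it->second)
          extend_pair(o1.first, o1.second, o2.first, o2.second);
    };

    for (int i = 0; i < q; ++i)
      for (int a = 0; a < 4; ++a) {
        if (a == dig[i]) continue;
        cross(c + ((int64_t)a - dig[i]) * pw[i]);
      }
    if (m == 2) {
      for (int i = 0; i + 1 < q; ++i)
        for (int j = i + 1; j < q; ++j)
          for (int a = 0; a < 4; ++a) {
            if (a == dig[i]) continue;
            for (int b = 0; b < 4; ++b) {
              if (b == dig[j]) continue;
              cross(c + ((int64_t)a - dig[i]) * pw[i]
                      + ((int64_t)b - dig[j]) * pw[j]);
            }
          }
    }
  }
  return eng.marked_starts();
}

// Brute-force reference solver: direct Hamming comparison of every pair of
// clean l-windows. Shares only the clean-window scan and the Hamming
// primitive with the filtration engine.
// [[Rcpp::export]]
List cpp_brute_force(CharacterVector seqs, IntegerVector est_ids,
                     int l, int d, bool within_est) {
  Engine eng(seqs, est_ids, l, d, within_est);
  const int ns = eng.seq.size();

  std::vector<Occ> wins;
  for (int i = 0; i < ns; ++i) {
    const int nw = (int)eng.seq[i].size() - l + 1;
    for (int p = 0; p < nw; ++p)
      if (eng.run[i][p] >= l) wins.push_back(Occ(i, p));
  }
  for (size_t i = 0; i + 1 < wins.size(); ++i) {
    for (size_t j = i + 1; j < wins.size(); ++j) {
      const int s1 = wins[i].first, s2 = wins[j].first;
      if (!within_est && eng.est[s1] == eng.est[s2]) continue;
      eng.mark_pair_if_close(s1, wins[i].second, s2, wins[j].second);
    }
  }
  return eng.marked_starts();
}
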
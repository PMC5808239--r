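#include <Rcpp.h>
#include <cstring>
#include <unordered_map>
#include <unordered_set>
#include <cmath>
using namespace Rcpp;

// Unit-cost Levenshtein distance with optional cutoff. When kmax >= 0 the
// computation is banded and returns kmax + 1 as soon as the distance is known
// to exceed kmax.
static int lv_dist(const char *a, int la, const char *b, int lb, int kmax) {
  if (la > lb) { std::swap(a, b); std::swap(la, lb); }
  if (kmax >= 0 && lb - la > kmax) return kmax + 1;
  if (la == 0) return lb;
  std::vector<int> prev(la + 2), cur(la + 2);
  const int BIG = la + lb + 1;
  for (int i = 0; i <= la + 1; ++i) prev[i] = i;
  for (int j = 1; j <= lb; ++j) {
    int lo = 1, hi = la;
    if (kmax >= 0) {
      lo = std::max(1, j - kmax);
      hi = std::min(la, j + kmax);
    }
    cur[0] = j;
    if (lo > 1) cur[lo - 1] = BIG;
    int rowmin = (lo == 1) ? cur[0] : BIG;
    for (int i = lo; i <= hi; ++i) {
      int sub = prev[i - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = cur[i - 1] + 1;
      int ins = prev[i] + 1;
      int v = sub;
      if (del < v) v = del;
      if (ins < v) v = ins;
      cur[i] = v;
      if (v < rowmin) rowmin = v;
    }
    if (hi < la) cur[hi + 1] = BIG;  // guard stale band edge for next column
    if (kmax >= 0 && rowmin > kmax) return kmax + 1;
    std::swap(prev, cur);
  }
  int d = prev[la];
  if (kmax >= 0 && d > kmax) return kmax + 1;
  return d;
}

// Hamming distance with early exit; -1 if lengths differ.
static int ham_dist(const char *a, int la, const char *b, int lb, int kmax) {
  if (la != lb) return -1;
  int d = 0;
  for (int i = 0; i < la; ++i) {
    if (a[i] != b[i]) {
      if (kmax >= 0 && ++d > kmax) return kmax + 1;
      else if (kmax < 0) ++d;
    }
  }
  return d;
}

//' @noRd
// [[Rcpp::export(name = ".lv_dist_cpp")]]
IntegerVector lv_dist_cpp(CharacterVector a, CharacterVector b,
                          int max_dist = -1) {
  R_xlen_t n = std::max(a.size(), b.size());
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *sa = CHAR(STRING_ELT(a, i % a.size()));
    const char *sb = CHAR(STRING_ELT(b, i % b.size()));
    out[i] = lv_dist(sa, std::strlen(sa), sb, std::strlen(sb), max_dist);
  }
  return out;
}

// true when the read is within `thr` edits of the seed, trying the cheap
// Hamming bound first (Levenshtein <= Hamming for equal lengths).
static bool within_threshold(const char *a, int la, const char *b, int lb,
                             int thr) {
  if (std::abs(la - lb) > thr) return false;
  if (la == lb) {
    int h = ham_dist(a, la, b, lb, thr);
    if (h <= thr) return true;
  }
  return lv_dist(a, la, b, lb, thr) <= thr;
}

static const int PHRED_OFFSET = 33;

// Quality-weighted consensus over members of the modal length (ties broken
// towards the shorter length). At each position the base with the largest
// summed Phred quality wins; ties break in the fixed order A < C < G < T.
// 'N' bases contribute zero weight.
static std::string consensus_of(const std::vector<const char *> &seqs,
                                const std::vector<const char *> &quals,
                                const std::vector<int> &lens) {
  size_t n = seqs.size();
  std::unordered_map<int, int> lenfreq;
  for (size_t i = 0; i < n; ++i) lenfreq[lens[i]]++;
  int modal = -1, best = -1;
  for (auto &kv : lenfreq) {
    if (kv.second > best || (kv.second == best && kv.first < modal)) {
      best = kv.second;
      modal = kv.first;
    }
  }
  std::vector<double> w(4 * modal, 0.0);
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  for (size_t i = 0; i < n; ++i) {
    if (lens[i] != modal) continue;
    const char *s = seqs[i];
    const char *q = quals[i];
    for (int p = 0; p < modal; ++p) {
      int bi;
      switch (s[p]) {
        case 'A': bi = 0; break;
        case 'C': bi = 1; break;
        case 'G': bi = 2; break;
        case 'T': bi = 3; break;
        default: continue;
      }
      w[4 * p + bi] += (double)(q[p] - PHRED_OFFSET);
    }
  }
  std::string cons(modal, 'N');
  for (int p = 0; p < modal; ++p) {
    double mx = 0.0;
    int arg = -1;
    for (int bi = 0; bi < 4; ++bi) {
      if (w[4 * p + bi] > mx) {
        mx = w[4 * p + bi];
        arg = bi;
      }
    }
    if (arg >= 0) cons[p] = bases[arg];
  }
  return cons;
}

//' @noRd
// [[Rcpp::export(name = ".consensus_cpp")]]
String consensus_cpp(CharacterVector seqs, CharacterVector quals) {
  size_t n = seqs.size();
  std::vector<const char *> s(n), q(n);
  std::vector<int> l(n);
  for (size_t i = 0; i < n; ++i) {
    s[i] = CHAR(STRING_ELT(seqs, i));
    q[i] = CHAR(STRING_ELT(quals, i));
    l[i] = std::strlen(s[i]);
  }
  return consensus_of(s, q, l);
}

// Greedy seeded quality-threshold clustering of reads grouped by MID.
// Inputs are parallel vectors sorted so that each MID group is contiguous
// (group boundaries given by `group` codes, non-decreasing). Within a group,
// reads are expected sorted by id so ties in summed quality resolve to the
// lexicographically smallest id.
//
// Returns per-read sub-cluster assignment (0 = discarded) and a table of
// retained sub-clusters (group row index, read count, consensus).
//' @noRd
// [[Rcpp::export(name = ".cluster_groups_cpp")]]
List cluster_groups_cpp(CharacterVector payload, CharacterVector qual,
                        IntegerVector group, double distance_fraction,
                        int min_reads) {
  R_xlen_t n = payload.size();
  IntegerVector assign(n, 0);
  std::vector<int> cl_group, cl_count;
  std::vector<std::string> cl_cons;
  std::vector<const char *> seqs(n), quals(n);
  std::vector<int> lens(n);
  std::vector<double> qsum(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    seqs[i] = CHAR(STRING_ELT(payload, i));
    quals[i] = CHAR(STRING_ELT(qual, i));
    lens[i] = std::strlen(seqs[i]);
    double s = 0;
    for (int p = 0; p < lens[i]; ++p)
      if (seqs[i][p] != 'N') s += (double)(quals[i][p] - PHRED_OFFSET);
    qsum[i] = s;
  }
  int next_id = 0;
  R_xlen_t gstart = 0;
  while (gstart < n) {
    R_xlen_t gend = gstart;
    while (gend < n && group[gend] == group[gstart]) ++gend;
    // indices of still-unassigned reads in this group
    std::vector<R_xlen_t> un;
    for (R_xlen_t i = gstart; i < gend; ++i) un.push_back(i);
    while (!un.empty()) {
      // seed: highest summed quality; ties -> earliest (id-sorted) read
      size_t si = 0;
      for (size_t k = 1; k < un.size(); ++k)
        if (qsum[un[k]] > qsum[un[si]]) si = k;
      R_xlen_t seed = un[si];
      int thr = (int)std::nearbyint(distance_fraction * lens[seed]);
      std::vector<R_xlen_t> members;
      std::vector<R_xlen_t> rest;
      for (size_t k = 0; k < un.size(); ++k) {
        R_xlen_t i = un[k];
        if (i == seed ||
            within_threshold(seqs[i], lens[i], seqs[seed], lens[seed], thr))
          members.push_back(i);
        else
          rest.push_back(i);
      }
      bool keep = (int)members.size() >= min_reads;
      if (keep && members.size() == 2) {
        // two-read rule: both reads must be identical strings
        keep = lens[members[0]] == lens[members[1]] &&
               std::memcmp(seqs[members[0]], seqs[members[1]],
                           lens[members[0]]) == 0;
      }
      if (keep) {
        ++next_id;
        std::vector<const char *> ms, mq;
        std::vector<int> ml;
        for (R_xlen_t i : members) {
          assign[i] = next_id;
          ms.push_back(seqs[i]);
          mq.push_back(quals[i]);
          ml.push_back(lens[i]);
        }
        cl_group.push_back(group[gstart]);
        cl_count.push_back((int)members.size());
        cl_cons.push_back(consensus_of(ms, mq, ml));
      }
      // members of failed clusters are discarded (assign stays 0)
      un.swap(rest);
    }
    gstart = gend;
  }
  return List::create(
      _["assign"] = assign,
      _["cluster_group"] = IntegerVector(cl_group.begin(), cl_group.end()),
      _["read_count"] = IntegerVector(cl_count.begin(), cl_count.end()),
      _["consensus"] = wrap(cl_cons));
}

// All unordered pairs (1-based indices) of sequences at Levenshtein distance
// exactly 1. Candidate pairs are generated by hashing half-length prefixes
// and suffixes (two strings at distance 1 must share one or the other), then
// verified exactly.
//' @noRd
// [[Rcpp::export(name = ".neighbor_pairs_cpp")]]
IntegerMatrix neighbor_pairs_cpp(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  std::vector<const char *> s(n);
  std::vector<int> l(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    s[i] = CHAR(STRING_ELT(seqs, i));
    l[i] = std::strlen(s[i]);
  }
  std::unordered_map<std::string, std::vector<int>> buckets;
  for (R_xlen_t i = 0; i < n; ++i) {
    for (int cmin = l[i] - 1; cmin <= l[i]; ++cmin) {
      if (cmin < 1) continue;
      int h = (cmin - 1) / 2;
      std::string kp = "P" + std::to_string(cmin) + ":";
      kp.append(s[i], h);
      buckets[kp].push_back((int)i);
      std::string ks = "S" + std::to_string(cmin) + ":";
      ks.append(s[i] + l[i] - h, h);
      buckets[ks].push_back((int)i);
    }
  }
  std::unordered_set<uint64_t> seen;
  std::vector<int> pi, pj;
  for (auto &kv : buckets) {
    std::vector<int> &v = kv.second;
    if (v.size() < 2) continue;
    for (size_t a = 0; a + 1 < v.size(); ++a) {
      for (size_t b = a + 1; b < v.size(); ++b) {
        int i = v[a], j = v[b];
        if (i == j) continue;
        int lo = std::min(i, j), hi = std::max(i, j);
        uint64_t key = (uint64_t)lo * (uint64_t)n + (uint64_t)hi;
        if (seen.count(key)) continue;
        seen.insert(key);
        if (std::abs(l[i] - l[j]) > 1) continue;
        if (lv_dist(s[i], l[i], s[j], l[j], 1) == 1) {
          pi.push_back(lo + 1);
          pj.push_back(hi + 1);
        }
      }
    }
  }
  IntegerMatrix out(pi.size(), 2);
  for (size_t k = 0; k < pi.size(); ++k) {
    out(k, 0) = pi[k];
    out(k, 1) = pj[k];
  }
  return out;
}

// Apply single-base substitutions to a copy of `seqs`: for each k,
// seqs[idx[k]][pos[k]] <- base[k] (1-based idx/pos).
//' @noRd
// [[Rcpp::export(name = ".apply_substitutions_cpp")]]
CharacterVector apply_substitutions_cpp(CharacterVector seqs,
                                        IntegerVector idx, IntegerVector pos,
                                        CharacterVector base) {
  std::vector<std::string> out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    out[i] = std::string(CHAR(STRING_ELT(seqs, i)));
  for (R_xlen_t k = 0; k < idx.size(); ++k) {
    int i = idx[k] - 1;
    int p = pos[k] - 1;
    if (i < 0 || i >= (int)out.size()) stop("substitution index out of range");
    if (p < 0 || p >= (int)out[i].size()) continue;  // beyond read end: no-op
    out[i][p] = CHAR(STRING_ELT(base, k))[0];
  }
  return wrap(out);
}

// Mean Phred quality of each Phred+33 string.
//' @noRd
// [[Rcpp::export(name = ".mean_phred_cpp")]]
NumericVector mean_phred_cpp(CharacterVector qual) {
  R_xlen_t n = qual.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *q = CHAR(STRING_ELT(qual, i));
    int L = std::strlen(q);
    double s = 0;
    for (int p = 0; p < L; ++p) s += (double)(q[p] - PHRED_OFFSET);
    out[i] = L > 0 ? s / L : NA_REAL;
  }
  return out;
}

// Encode an integer quality matrix (reads in rows) as Phred+33 strings.
//' @noRd
// [[Rcpp::export(name = ".phred_strings_cpp")]]
CharacterVector phred_strings_cpp(IntegerMatrix q) {
  int n = q.nrow(), L = q.ncol();
  CharacterVector out(n);
  std::string buf(L, '!');
  for (int i = 0; i < n; ++i) {
    for (int p = 0; p < L; ++p) buf[p] = (char)(q(i, p) + PHRED_OFFSET);
    out[i] = buf;
  }
  return out;
}

// Paste rows of a character matrix into strings (cells may hold one or more
// characters, e.g. single bases or whole codons).
//' @noRd
// [[Rcpp::export(name = ".collapse_rows_cpp")]]
CharacterVector collapse_rows_cpp(CharacterMatrix m) {
  int n = m.nrow(), L = m.ncol();
  CharacterVector out(n);
  std::string buf;
  for (int i = 0; i < n; ++i) {
    buf.clear();
    for (int p = 0; p < L; ++p) buf.append(CHAR(STRING_ELT(m, i + (R_xlen_t)p * n)));
    out[i] = buf;
  }
  return out;
}
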
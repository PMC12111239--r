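#include <Rcpp.h>
using namespace Rcpp;

// Smallest period p in [min_period, floor(L/2)] such that the fraction of
// offsets i in [0, L-p) with s[i] == s[i+p] is >= 1 - tau. 'N' never agrees.
static int period_one(const std::string& s, int min_period, double tau) {
  const int L = (int) s.size();
  const int pmax = L / 2;
  for (int p = min_period; p <= pmax; ++p) {
    const int ncmp = L - p;
    int agree = 0;
    for (int i = 0; i < ncmp; ++i) {
      if (s[i] == s[i + p] && s[i] != 'N') ++agree;
    }
    if ((double) agree / (double) ncmp >= 1.0 - tau) return p;
  }
  return NA_INTEGER;
}

// [[Rcpp::export(name = ".detect_period_batch")]]
IntegerVector detect_period_batch(CharacterVector reads, int min_period, double tau) {
  const int n = reads.size();
  IntegerVector out(n);
  for (int j = 0; j < n; ++j) {
    std::string s = as<std::string>(reads[j]);
    if ((int) s.size() < 2 * min_period) { out[j] = NA_INTEGER; continue; }
    out[j] = period_one(s, min_period, tau);
  }
  return out;
}

// Booth's least-rotation algorithm: index of the lexicographically smallest
// rotation of s.
static int least_rotation_index(const std::string& s) {
  const int n = (int) s.size();
  std::string t = s + s;
  std::vector<int> f(2 * n, -1);
  int k = 0;
  for (int j = 1; j < 2 * n; ++j) {
    char sj = t[j];
    int i = f[j - k - 1];
    while (i != -1 && sj != t[k + i + 1]) {
      if (sj < t[k + i + 1]) k = j - i - 1;
      i = f[i];
    }
    if (sj != t[k + i + 1]) {
      if (sj < t[k]) k = j;
      f[j - k] = -1;
    } else {
      f[j - k] = i + 1;
    }
  }
  return k;
}

// [[Rcpp::export(name = ".least_rotation_batch")]]
CharacterVector least_rotation_batch(CharacterVector x) {
  const int n = x.size();
  CharacterVector out(n);
  for (int j = 0; j < n; ++j) {
    std::string s = as<std::string>(x[j]);
    int k = least_rotation_index(s);
    std::string r = s.substr(k) + s.substr(0, k);
    out[j] = r;
  }
  return out;
}

// Best ungapped match count of each query (length <= ref length) against a
// reference monomer over all cyclic shifts and both strands, normalised by
// the LONGER length. For equal-length, indel-free copies this equals the
// rotation/strand-invariant alignment identity; unlike gapped alignment it
// keeps the chance similarity of unrelated monomers well below 50%.
// [[Rcpp::export(name = ".cyclic_identity_batch")]]
NumericVector cyclic_identity_batch(CharacterVector queries, std::string ref) {
  const int L = (int) ref.size();
  std::string fwd = ref + ref;
  std::string rc(ref.rbegin(), ref.rend());
  for (size_t i = 0; i < rc.size(); ++i) {
    switch (rc[i]) {
      case 'A': rc[i] = 'T'; break;
      case 'C': rc[i] = 'G'; break;
      case 'G': rc[i] = 'C'; break;
      case 'T': rc[i] = 'A'; break;
      default: break;
    }
  }
  std::string rev2 = rc + rc;
  const int n = queries.size();
  NumericVector out(n);
  for (int j = 0; j < n; ++j) {
    std::string q = as<std::string>(queries[j]);
    const int Lq = (int) q.size();
    if (Lq > L) { out[j] = NA_REAL; continue; }
    int best = 0;
    for (int s = 0; s < L; ++s) {
      int m1 = 0, m2 = 0;
      for (int i = 0; i < Lq; ++i) {
        if (q[i] == fwd[s + i]) ++m1;
        if (q[i] == rev2[s + i]) ++m2;
      }
      int m = m1 > m2 ? m1 : m2;
      if (m > best) best = m;
      if (best == Lq) break;
    }
    out[j] = (double) best / (double) L;
  }
  return out;
}

static inline bool is_transition(char a, char b) {
  return (a == 'A' && b == 'G') || (a == 'G' && b == 'A') ||
         (a == 'C' && b == 'T') || (a == 'T' && b == 'C');
}

// Column accounting over pairs of gapped aligned strings (equal lengths).
// Columns: matches, transitions, transversions, gap_columns, aligned_columns,
// sites (ungapped, N-free; the K2P denominator), pattern_bp (non-gap pattern
// characters). An N in an ungapped column counts as a transversion for the
// identity bookkeeping but is excluded from 'sites'.
// [[Rcpp::export(name = ".aln_tally")]]
IntegerMatrix aln_tally(CharacterVector pat, CharacterVector sub) {
  const int n = pat.size();
  IntegerMatrix out(n, 7);
  colnames(out) = CharacterVector::create("matches", "transitions",
    "transversions", "gap_columns", "aligned_columns", "sites", "pattern_bp");
  for (int j = 0; j < n; ++j) {
    std::string a = as<std::string>(pat[j]);
    std::string b = as<std::string>(sub[j]);
    const int L = (int) a.size();
    int match = 0, ts = 0, tv = 0, gap = 0, sites = 0, pbp = 0;
    for (int i = 0; i < L; ++i) {
      char x = a[i], y = b[i];
      if (x != '-') ++pbp;
      if (x == '-' || y == '-') { ++gap; continue; }
      if (x == 'N' || y == 'N') { ++tv; continue; }
      ++sites;
      if (x == y) ++match;
      else if (is_transition(x, y)) ++ts;
      else ++tv;
    }
    out(j, 0) = match; out(j, 1) = ts; out(j, 2) = tv; out(j, 3) = gap;
    out(j, 4) = L; out(j, 5) = sites; out(j, 6) = pbp;
  }
  return out;
}
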
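// Canonical k-mer database and LCA read classifier.
// k-mers are 2-bit packed (A=0,C=1,G=2,T=3) so k<=31 fits one uint64_t;
// the canonical form is the numeric minimum of a k-mer and its reverse
// complement, which equals the lexicographic minimum under this encoding.
#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <cstdint>
using namespace Rcpp;

typedef std::unordered_map<uint64_t, int> KmerMap;

static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1; // N or anything else breaks k-mer extraction
  }
}

// Enumerate canonical k-mers; any non-ACGT base resets the window so no
// k-mer spans an ambiguous base.
template <class F>
static void for_each_canonical(const char* s, size_t n, int k, F fn) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rev = 0;
  int valid = 0;
  for (size_t i = 0; i < n; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
    if (++valid >= k) fn(fwd < rev ? fwd : rev);
  }
}

static std::string decode_kmer(uint64_t code, int k) {
  static const char bases[] = "ACGT";
  std::string out(k, 'A');
  for (int i = k - 1; i >= 0; --i) { out[i] = bases[code & 3ULL]; code >>= 2; }
  return out;
}

// parent: 1-based parent id per node, 0 for the root.
static std::vector<int> node_depths(const IntegerVector& parent) {
  int n = parent.size();
  std::vector<int> dep(n + 1, -1);
  for (int v = 1; v <= n; ++v) {
    int d = 0, u = v;
    while (parent[u - 1] != 0) { u = parent[u - 1]; ++d; }
    dep[v] = d;
  }
  return dep;
}

static int lca(int a, int b, const IntegerVector& parent, const std::vector<int>& dep) {
  while (a != b) {
    if (dep[a] > dep[b]) a = parent[a - 1];
    else if (dep[b] > dep[a]) b = parent[b - 1];
    else { a = parent[a - 1]; b = parent[b - 1]; }
  }
  return a;
}

// [[Rcpp::export]]
SEXP cpp_kmerdb_build(CharacterVector seqs, IntegerVector node_ids,
                      IntegerVector parent, int k) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  std::vector<int> dep = node_depths(parent);
  KmerMap* m = new KmerMap();
  for (int i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    size_t n = LENGTH(STRING_ELT(seqs, i));
    int node = node_ids[i];
    for_each_canonical(s, n, k, [&](uint64_t code) {
      auto it = m->find(code);
      if (it == m->end()) (*m)[code] = node;
      else if (it->second != node) it->second = lca(it->second, node, parent, dep);
    });
  }
  XPtr<KmerMap> p(m, true);
  return p;
}

// [[Rcpp::export]]
double cpp_kmerdb_size(SEXP dbptr) {
  XPtr<KmerMap> p(dbptr);
  return (double)p->size();
}

// [[Rcpp::export]]
DataFrame cpp_kmerdb_entries(SEXP dbptr, int k) {
  XPtr<KmerMap> p(dbptr);
  std::vector<std::string> kmers;
  std::vector<int> nodes;
  kmers.reserve(p->size()); nodes.reserve(p->size());
  for (auto& kv : *p) { kmers.push_back(decode_kmer(kv.first, k)); nodes.push_back(kv.second); }
  return DataFrame::create(Named("kmer") = kmers, Named("node_id") = nodes,
                           Named("stringsAsFactors") = false);
}

// Kraken-style scoring: each root-to-leaf path is scored by the sum of hit
// counts on its nodes; the read gets the LCA of the maximum-scoring leaves
// (a unique winner yields that leaf, hits confined to an internal node yield
// that node, no hits yield 0 = unclassified).
// [[Rcpp::export]]
IntegerVector cpp_classify(SEXP dbptr, CharacterVector reads,
                           IntegerVector parent, int k) {
  XPtr<KmerMap> p(dbptr);
  int n_nodes = parent.size();
  std::vector<int> dep = node_depths(parent);
  std::vector<bool> is_leaf(n_nodes + 1, true);
  for (int v = 1; v <= n_nodes; ++v)
    if (parent[v - 1] != 0) is_leaf[parent[v - 1]] = false;
  std::vector<int> leaves;
  for (int v = 1; v <= n_nodes; ++v) if (is_leaf[v]) leaves.push_back(v);

  IntegerVector out(reads.size());
  std::vector<int> hits(n_nodes + 1, 0);
  std::vector<int> touched;
  for (int r = 0; r < reads.size(); ++r) {
    const char* s = CHAR(STRING_ELT(reads, r));
    size_t n = LENGTH(STRING_ELT(reads, r));
    touched.clear();
    for_each_canonical(s, n, k, [&](uint64_t code) {
      auto it = p->find(code);
      if (it != p->end()) {
        if (hits[it->second] == 0) touched.push_back(it->second);
        ++hits[it->second];
      }
    });
    if (touched.empty()) { out[r] = NA_INTEGER; continue; }
    int best_score = -1, winner = 0;
    for (int leaf : leaves) {
      int score = 0;
      for (int u = leaf; u != 0; u = parent[u - 1]) score += hits[u];
      if (score > best_score) { best_score = score; winner = leaf; }
      else if (score == best_score) winner = lca(winner, leaf, parent, dep);
    }
    out[r] = winner;
    for (int t : touched) hits[t] = 0;
  }
  return out;
}

// [[Rcpp::export]]
int cpp_hamming(std::string a, std::string b) {
  if (a.size() != b.size()) stop("hamming distance requires equal-length sequences");
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i) if (a[i] != b[i]) ++d;
  return d;
}

// ---- shared k-mer candidate index used by clustering / search ------------

static void unique_kmers(const char* s, size_t n, int k, std::vector<uint64_t>& out) {
  std::unordered_set<uint64_t> seen;
  for_each_canonical(s, n, k, [&](uint64_t code) { seen.insert(code); });
  out.assign(seen.begin(), seen.end());
}

struct AlignStats { int matches; int columns; int score; };

// Banded global (Needleman-Wunsch) alignment, linear gap penalty.
// Identity is matches / alignment columns over the full global alignment.
static bool banded_align(const char* a, int la, const char* b, int lb,
                         int extra, int match, int mismatch, int gap,
                         AlignStats& st) {
  if (la == 0 || lb == 0) { st = {0, la + lb, gap * (la + lb)}; return true; }
  const int NEG = INT_MIN / 4;
  int dl = std::max(0, la - lb) + extra;
  int du = std::max(0, lb - la) + extra;
  int W = dl + du + 1;
  std::vector<int> S((size_t)(la + 1) * W, NEG);
  std::vector<unsigned char> T((size_t)(la + 1) * W, 3);
  auto idx = [&](int i, int j) { return (size_t)i * W + (j - i + dl); };
  S[idx(0, 0)] = 0;
  for (int j = 1; j <= std::min(lb, du); ++j) { S[idx(0, j)] = gap * j; T[idx(0, j)] = 2; }
  for (int i = 1; i <= la; ++i) {
    int jlo = std::max(0, i - dl), jhi = std::min(lb, i + du);
    for (int j = jlo; j <= jhi; ++j) {
      if (j == 0) { S[idx(i, 0)] = gap * i; T[idx(i, 0)] = 1; continue; }
      int best = S[idx(i - 1, j - 1)] + (a[i - 1] == b[j - 1] ? match : mismatch);
      unsigned char t = 0;
      if (j - 1 >= i - dl) { int u = S[idx(i, j - 1)] + gap; if (u > best) { best = u; t = 2; } }
      if (j <= i - 1 + du) { int v = S[idx(i - 1, j)] + gap; if (v > best) { best = v; t = 1; } }
      S[idx(i, j)] = best; T[idx(i, j)] = t;
    }
  }
  if (S[idx(la, lb)] <= NEG) return false;
  int i = la, j = lb, mt = 0, cols = 0;
  while (i > 0 || j > 0) {
    unsigned char t = T[idx(i, j)];
    if (t == 0 && i > 0 && j > 0) { if (a[i - 1] == b[j - 1]) ++mt; ++cols; --i; --j; }
    else if (t == 2 && j > 0) { ++cols; --j; }
    else { ++cols; --i; }
  }
  st.matches = mt; st.columns = cols; st.score = S[idx(la, lb)];
  return true;
}

// [[Rcpp::export]]
List cpp_align_counts(std::string a, std::string b, int extra = 32,
                      int match = 1, int mismatch = -1, int gap = -2) {
  AlignStats st;
  if (!banded_align(a.c_str(), a.size(), b.c_str(), b.size(),
                    extra, match, mismatch, gap, st))
    stop("banded alignment failed; increase band width");
  return List::create(Named("matches") = st.matches,
                      Named("columns") = st.columns,
                      Named("score") = st.score,
                      Named("identity") = st.columns > 0 ? (double)st.matches / st.columns : 1.0);
}

// Global-alignment coverage of both sequences reduces to the length ratio:
// the shorter sequence must be >= min_cov of the longer one.
static inline bool cov_ok(int la, int lb, double min_cov) {
  return (double)std::min(la, lb) >= min_cov * (double)std::max(la, lb);
}

// Greedy incremental clustering. seqs must be pre-sorted (length desc, then
// id); each sequence joins the FIRST (creation-order) representative it
// matches at >= min_id identity with both-way coverage >= min_cov, else it
// founds a new cluster. Candidate representatives must share at least one
// canonical prek-mer with the query (exact-k-mer prefilter).
// [[Rcpp::export]]
IntegerVector cpp_cluster_greedy(CharacterVector seqs, double min_id,
                                 double min_cov, int prek = 15, int extra = 32) {
  int n = seqs.size();
  IntegerVector assign(n);
  std::vector<int> reps;                 // indices into seqs, creation order
  std::unordered_map<uint64_t, std::vector<int>> index; // kmer -> rep ordinal
  std::vector<uint64_t> kms;
  std::vector<int> cand_count;
  std::vector<int> cand_list;
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    int ls = LENGTH(STRING_ELT(seqs, i));
    unique_kmers(s, ls, prek, kms);
    cand_count.assign(reps.size(), 0);
    cand_list.clear();
    for (uint64_t km : kms) {
      auto it = index.find(km);
      if (it == index.end()) continue;
      for (int rid : it->second) {
        if (cand_count[rid] == 0) cand_list.push_back(rid);
        ++cand_count[rid];
      }
    }
    std::sort(cand_list.begin(), cand_list.end()); // creation order
    int joined = 0;
    AlignStats st;
    for (int rid : cand_list) {
      const char* r = CHAR(STRING_ELT(seqs, reps[rid]));
      int lr = LENGTH(STRING_ELT(seqs, reps[rid]));
      if (!cov_ok(ls, lr, min_cov)) continue;
      if (!banded_align(s, ls, r, lr, extra, 1, -1, -2, st)) continue;
      double id = st.columns > 0 ? (double)st.matches / st.columns : 1.0;
      if (id >= min_id) { joined = rid + 1; break; }
    }
    if (joined) { assign[i] = joined; continue; }
    int rid = (int)reps.size();
    reps.push_back(i);
    assign[i] = rid + 1;
    for (uint64_t km : kms) index[km].push_back(rid);
  }
  return assign;
}

// Best hit of each query among targets: candidates share >= 1 canonical
// prek-mer, are screened by length-ratio coverage, and the top max_cand by
// shared-k-mer count are aligned; the best identity >= min_id wins (ties to
// the earlier target). index 0 / identity NA means no hit.
// [[Rcpp::export]]
List cpp_best_hit(CharacterVector queries, CharacterVector targets,
                  double min_id, double min_cov, int prek = 15,
                  int extra = 32, int max_cand = 50) {
  int nt = targets.size();
  std::unordered_map<uint64_t, std::vector<int>> index;
  std::vector<uint64_t> kms;
  for (int t = 0; t < nt; ++t) {
    unique_kmers(CHAR(STRING_ELT(targets, t)), LENGTH(STRING_ELT(targets, t)), prek, kms);
    for (uint64_t km : kms) index[km].push_back(t);
  }
  int nq = queries.size();
  IntegerVector hit(nq);
  NumericVector ident(nq);
  std::vector<int> cand_count(nt, 0);
  std::vector<int> cand_list;
  for (int q = 0; q < nq; ++q) {
    const char* s = CHAR(STRING_ELT(queries, q));
    int ls = LENGTH(STRING_ELT(queries, q));
    unique_kmers(s, ls, prek, kms);
    cand_list.clear();
    for (uint64_t km : kms) {
      auto it = index.find(km);
      if (it == index.end()) continue;
      for (int t : it->second) {
        if (cand_count[t] == 0) cand_list.push_back(t);
        ++cand_count[t];
      }
    }
    std::sort(cand_list.begin(), cand_list.end(), [&](int a, int b) {
      if (cand_count[a] != cand_count[b]) return cand_count[a] > cand_count[b];
      return a < b;
    });
    int best = 0; double best_id = -1.0;
    int tried = 0;
    AlignStats st;
    for (int t : cand_list) {
      if (tried >= max_cand) break;
      const char* r = CHAR(STRING_ELT(targets, t));
      int lr = LENGTH(STRING_ELT(targets, t));
      if (min_cov > 0 && !cov_ok(ls, lr, min_cov)) continue;
      ++tried;
      if (!banded_align(s, ls, r, lr, extra, 1, -1, -2, st)) continue;
      double id = st.columns > 0 ? (double)st.matches / st.columns : 1.0;
      if (id >= min_id && (id > best_id || (id == best_id && (best == 0 || t + 1 < best)))) {
        best = t + 1; best_id = id;
      }
    }
    hit[q] = best;
    ident[q] = best > 0 ? best_id : NA_REAL;
    for (int t : cand_list) cand_count[t] = 0;
  }
  return List::create(Named("index") = hit, Named("identity") = ident);
}
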
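#include <Rcpp.h>
#include <array>
#include <cstring>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// Core holds the graph in index space plus the seed dictionary.
// Node indices are 0-based positions into ids/fwd/rev; ids are the
// user-visible node identifiers (strictly increasing by construction).
struct Core {
  int n = 0;
  std::vector<int> ids;
  std::vector<std::string> fwd;  // node sequence, forward strand
  std::vector<std::string> rev;  // reverse complement
  std::vector<std::vector<int>> succ_f;  // forward successors, ascending id
  std::vector<std::vector<int>> succ_r;  // predecessors, descending id
  std::vector<char> snp_node;            // 1 if ref- or alt-allele node
  std::unordered_map<int, int> id2idx;
  // 2-mer buckets per strand (0 = forward, 1 = reverse): (node_idx, offset)
  std::array<std::array<std::vector<std::pair<int, int>>, 16>, 2> k2;
  // node indices whose oriented sequence ends in base b (for boundary seeds)
  std::array<std::array<std::vector<int>, 4>, 2> last_base;
};

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    case 'N': return 'N';
    default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (auto& c : out) c = comp_base(c);
  return out;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return revcomp(s); }

// ids must be strictly increasing; edges reference existing ids.
// [[Rcpp::export]]
SEXP core_build(IntegerVector ids, CharacterVector seqs, IntegerVector efrom,
                IntegerVector eto, LogicalVector snp_node) {
  Core* C = new Core();
  C->n = ids.size();
  C->ids.assign(ids.begin(), ids.end());
  C->fwd.resize(C->n);
  C->rev.resize(C->n);
  C->snp_node.resize(C->n, 0);
  C->succ_f.resize(C->n);
  C->succ_r.resize(C->n);
  for (int i = 0; i < C->n; ++i) {
    C->fwd[i] = as<std::string>(seqs[i]);
    C->rev[i] = revcomp(C->fwd[i]);
    C->snp_node[i] = snp_node[i] ? 1 : 0;
    C->id2idx[C->ids[i]] = i;
  }
  for (int e = 0; e < efrom.size(); ++e) {
    auto u = C->id2idx.find(efrom[e]);
    auto v = C->id2idx.find(eto[e]);
    if (u == C->id2idx.end() || v == C->id2idx.end()) {
      delete C;
      stop("edge endpoint not present in node table");
    }
    C->succ_f[u->second].push_back(v->second);
    C->succ_r[v->second].push_back(u->second);
  }
  for (int i = 0; i < C->n; ++i) {
    auto by_id_asc = [&](int a, int b) { return C->ids[a] < C->ids[b]; };
    auto by_id_desc = [&](int a, int b) { return C->ids[a] > C->ids[b]; };
    std::sort(C->succ_f[i].begin(), C->succ_f[i].end(), by_id_asc);
    C->succ_f[i].erase(std::unique(C->succ_f[i].begin(), C->succ_f[i].end()),
                       C->succ_f[i].end());
    std::sort(C->succ_r[i].begin(), C->succ_r[i].end(), by_id_desc);
    C->succ_r[i].erase(std::unique(C->succ_r[i].begin(), C->succ_r[i].end()),
                       C->succ_r[i].end());
  }
  // seed dictionary: every within-node 2-mer on both strands, plus the
  // oriented final base of every node (anchors that continue across an edge)
  for (int s = 0; s < 2; ++s) {
    for (int i = 0; i < C->n; ++i) {
      const std::string& S = (s == 0) ? C->fwd[i] : C->rev[i];
      int L = (int)S.size();
      for (int o = 0; o + 2 <= L; ++o) {
        int a = base_code(S[o]), b = base_code(S[o + 1]);
        if (a >= 0 && b >= 0) C->k2[s][a * 4 + b].push_back({i, o});
      }
      int last = base_code(S[L - 1]);
      if (last >= 0) C->last_base[s][last].push_back(i);
    }
  }
  XPtr<Core> p(C, true);
  return p;
}

// [[Rcpp::export]]
bool core_alive(SEXP xp) {
  if (TYPEOF(xp) != EXTPTRSXP) return false;
  return R_ExternalPtrAddr(xp) != NULL;
}

static inline const std::string& oriented(const Core& C, int i, int strand) {
  return strand == 0 ? C.fwd[i] : C.rev[i];
}

// length of the longest common prefix of read[pos..] and S[o..]
static inline int lcp(const std::string& read, int pos, const std::string& S,
                      int o) {
  int m = std::min((int)read.size() - pos, (int)S.size() - o);
  int k = 0;
  while (k < m && read[pos + k] == S[o + k]) ++k;
  return k;
}

struct Hit {
  int idx, offset, strand, len;
};

static void locate_one(const Core& C, const std::string& pat,
                       std::vector<Hit>& out) {
  int L = (int)pat.size();
  if (L < 2) return;
  int a = base_code(pat[0]), b = base_code(pat[1]);
  if (a < 0 || b < 0) return;  // patterns with N never match
  for (char ch : pat)
    if (base_code(ch) < 0) return;
  for (int s = 0; s < 2; ++s) {
    for (const auto& po : C.k2[s][a * 4 + b]) {
      const std::string& S = oriented(C, po.first, s);
      if (po.second + L > (int)S.size()) continue;
      if (std::memcmp(S.data() + po.second, pat.data(), L) == 0)
        out.push_back({po.first, po.second, s, L});
    }
  }
  std::sort(out.begin(), out.end(), [&](const Hit& x, const Hit& y) {
    if (C.ids[x.idx] != C.ids[y.idx]) return C.ids[x.idx] < C.ids[y.idx];
    if (x.strand != y.strand) return x.strand < y.strand;
    return x.offset < y.offset;
  });
}

// [[Rcpp::export]]
DataFrame core_locate(SEXP xp, CharacterVector patterns) {
  XPtr<Core> p(xp);
  const Core& C = *p;
  std::vector<int> pi, nid, off, mlen;
  std::vector<int> isrev;
  for (int q = 0; q < patterns.size(); ++q) {
    std::vector<Hit> hits;
    locate_one(C, as<std::string>(patterns[q]), hits);
    for (const auto& h : hits) {
      pi.push_back(q + 1);
      nid.push_back(C.ids[h.idx]);
      off.push_back(h.offset);
      isrev.push_back(h.strand);
      mlen.push_back(h.len);
    }
  }
  return DataFrame::create(_["pattern"] = pi, _["node_id"] = nid,
                           _["offset"] = off, _["is_reverse"] = isrev,
                           _["match_length"] = mlen);
}

// All terminal anchors of `read`: maximal prefix matches (in each
// orientation) of length >= 2 within one node, plus node-final single-base
// anchors whose continuation into an oriented successor matches read[1]
// (the two shared characters then straddle an edge).
static void find_seeds(const Core& C, const std::string& read,
                       std::vector<Hit>& seeds) {
  int N = (int)read.size();
  if (N < 2) return;
  for (char ch : read)
    if (base_code(ch) < 0) return;  // reads containing N are rejected
  int a = base_code(read[0]), b = base_code(read[1]);
  for (int s = 0; s < 2; ++s) {
    for (const auto& po : C.k2[s][a * 4 + b]) {
      const std::string& S = oriented(C, po.first, s);
      int len = 2 + lcp(read, 2, S, po.second + 2);
      seeds.push_back({po.first, po.second, s, len});
    }
    for (int i : C.last_base[s][a]) {
      const std::string& S = oriented(C, i, s);
      int o = (int)S.size() - 1;
      const auto& succ = (s == 0) ? C.succ_f[i] : C.succ_r[i];
      bool cont = false;
      for (int w : succ)
        if (oriented(C, w, s)[0] == read[1]) {
          cont = true;
          break;
        }
      if (cont) seeds.push_back({i, o, s, 1});
    }
  }
  std::sort(seeds.begin(), seeds.end(), [&](const Hit& x, const Hit& y) {
    if (x.len != y.len) return x.len > y.len;  // longest anchor first
    if (C.ids[x.idx] != C.ids[y.idx]) return C.ids[x.idx] < C.ids[y.idx];
    if (x.strand != y.strand) return x.strand < y.strand;  // fwd before rev
    return x.offset < y.offset;
  });
}

// [[Rcpp::export]]
DataFrame core_find_seeds(SEXP xp, std::string read) {
  XPtr<Core> p(xp);
  std::vector<Hit> seeds;
  find_seeds(*p, read, seeds);
  int n = (int)seeds.size();
  IntegerVector nid(n), off(n), mlen(n);
  LogicalVector isrev(n);
  for (int i = 0; i < n; ++i) {
    nid[i] = p->ids[seeds[i].idx];
    off[i] = seeds[i].offset;
    isrev[i] = seeds[i].strand == 1;
    mlen[i] = seeds[i].len;
  }
  return DataFrame::create(_["node_id"] = nid, _["offset"] = off,
                           _["is_reverse"] = isrev, _["match_length"] = mlen);
}

struct Search {
  const Core* C;
  const std::string* read;
  int strand;
  int budget;       // global: at most node_budget_factor * N probes
  int visited = 0;  // probes performed (diagnostic)
  int cap;          // neighbour probes per node
  bool backtrack;
  bool aborted = false;
  std::vector<std::array<int, 2>> steps;  // (node_idx, matched_len); offsets
                                          // are 0 beyond the anchor
};

static bool dfs(Search& s, int u, int pos) {
  const auto& succ = (s.strand == 0) ? s.C->succ_f[u] : s.C->succ_r[u];
  int probes = 0;
  for (int w : succ) {
    if (probes >= s.cap) break;
    if (s.budget <= 0) {
      s.aborted = true;
      return false;
    }
    ++probes;
    --s.budget;
    ++s.visited;
    const std::string& S = oriented(*s.C, w, s.strand);
    int m = std::min((int)S.size(), (int)s.read->size() - pos);
    if (std::memcmp(S.data(), s.read->data() + pos, m) == 0) {
      s.steps.push_back({w, m});
      if (pos + m == (int)s.read->size()) return true;
      if (dfs(s, w, pos + m)) return true;
      s.steps.pop_back();
      if (s.aborted || !s.backtrack) return false;
    }
    // mismatching probe: try the next neighbour (counts toward both caps)
  }
  return false;
}

// Extend an anchor to a full-read exact alignment (Algorithm-1 style).
// Returns an R list or NULL. Anchor offsets/lengths are in the anchor's
// orientation.
static SEXP extend_from(const Core& C, const std::string& read, const Hit& h,
                        int budget_factor, int cap, bool backtrack) {
  int N = (int)read.size();
  const std::string& S = oriented(C, h.idx, h.strand);
  Search s;
  s.C = &C;
  s.read = &read;
  s.strand = h.strand;
  s.budget = budget_factor * N;
  s.cap = cap;
  s.backtrack = backtrack;
  bool complete = false;
  if (h.len == N) {
    complete = true;
  } else if (h.offset + h.len == (int)S.size()) {
    complete = dfs(s, h.idx, h.len);
  }  // else: the anchor mismatched before the node end; no exact completion
  if (!complete) return R_NilValue;
  int k = 1 + (int)s.steps.size();
  IntegerVector nid(k), off(k), len(k);
  LogicalVector rev(k);
  bool covers = C.snp_node[h.idx] != 0;
  nid[0] = C.ids[h.idx];
  off[0] = h.offset;
  len[0] = h.len;
  rev[0] = h.strand == 1;
  for (int i = 0; i < (int)s.steps.size(); ++i) {
    int w = s.steps[i][0];
    nid[i + 1] = C.ids[w];
    off[i + 1] = 0;
    len[i + 1] = s.steps[i][1];
    rev[i + 1] = h.strand == 1;
    covers = covers || C.snp_node[w];
  }
  return List::create(_["node_id"] = nid, _["offset"] = off, _["length"] = len,
                      _["is_reverse"] = rev, _["covers_snp"] = covers,
                      _["visited_nodes"] = s.visited,
                      _["strand_reverse"] = (h.strand == 1));
}

// [[Rcpp::export]]
SEXP core_extend(SEXP xp, std::string read, int node_id, int offset,
                 bool is_reverse, int match_length, int budget_factor, int cap,
                 bool backtrack) {
  XPtr<Core> p(xp);
  auto it = p->id2idx.find(node_id);
  if (it == p->id2idx.end()) stop("unknown node id: %d", node_id);
  Hit h{it->second, offset, is_reverse ? 1 : 0, match_length};
  const std::string& S = oriented(*p, h.idx, h.strand);
  if (h.offset < 0 || h.len < 1 || h.offset + h.len > (int)S.size())
    stop("seed hit out of node bounds");
  if (std::memcmp(S.data() + h.offset, read.data(),
                  std::min(h.len, (int)read.size())) != 0 ||
      h.len > (int)read.size())
    stop("seed hit does not anchor a prefix of the read in its orientation");
  return extend_from(*p, read, h, budget_factor, cap, backtrack);
}

static SEXP map_one(const Core& C, const std::string& read, int budget_factor,
                    int cap, int min_seed, bool backtrack) {
  std::vector<Hit> seeds;
  find_seeds(C, read, seeds);
  RObject best(R_NilValue);
  for (const auto& h : seeds) {
    // boundary anchors (len 1) share their 2nd character across an edge
    int shared = h.len == 1 ? 2 : h.len;
    if (shared < min_seed) continue;
    RObject al(extend_from(C, read, h, budget_factor, cap, backtrack));
    if (al.isNULL()) continue;
    bool covers = as<bool>(as<List>(al)["covers_snp"]);
    if (covers) return al;  // SNP-covering alignment: best choice, stop
    if (best.isNULL()) best = al;
  }
  return best;
}

// [[Rcpp::export]]
SEXP core_map_read(SEXP xp, std::string read, int budget_factor, int cap,
                   int min_seed, bool backtrack) {
  XPtr<Core> p(xp);
  return map_one(*p, read, budget_factor, cap, min_seed, backtrack);
}

// [[Rcpp::export]]
List core_map_reads(SEXP xp, CharacterVector reads, int budget_factor, int cap,
                    int min_seed, bool backtrack) {
  XPtr<Core> p(xp);
  List out(reads.size());
  for (int i = 0; i < reads.size(); ++i) {
    out[i] = map_one(*p, as<std::string>(reads[i]), budget_factor, cap,
                     min_seed, backtrack);
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
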
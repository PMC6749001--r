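// Unique k-mer anchor machinery.
//
// k-mers are packed 2 bits/base into a 64-bit word (so k <= 31) and counted
// in canonical form (min of forward and reverse-complement encoding). An
// anchor is a k-mer occurring exactly once in each of two sequence sets; its
// orientation is + when both occurrences have the same strand relative to the
// canonical form, - otherwise.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Occ {
  uint32_t chrom;   // 0-based index into the sequence set
  uint32_t pos;     // 0-based position of k-mer start on the forward strand
  uint8_t  strand;  // 0 = forward occurrence equals canonical, 1 = revcomp
  uint8_t  count;   // saturating at 2
};

typedef std::unordered_map<uint64_t, Occ> KmerMap;

struct KmerIndex {
  int k;
  KmerMap map;
};

inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Scan one sequence set into a canonical k-mer occurrence map.
void count_kmers(const std::vector<std::string>& seqs, int k, KmerMap& map) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  for (size_t ci = 0; ci < seqs.size(); ++ci) {
    const std::string& s = seqs[ci];
    uint64_t fwd = 0, rev = 0;
    int run = 0;  // consecutive valid bases ending here
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base_code(s[i]);
      if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
      if (++run < k) continue;
      uint64_t canon = fwd <= rev ? fwd : rev;
      uint8_t strand = fwd <= rev ? 0 : 1;
      KmerMap::iterator it = map.find(canon);
      if (it == map.end()) {
        Occ o; o.chrom = (uint32_t)ci; o.pos = (uint32_t)(i + 1 - k);
        o.strand = strand; o.count = 1;
        map.emplace(canon, o);
      } else if (it->second.count < 2) {
        it->second.count = 2;
      }
    }
  }
}

std::vector<std::string> as_std(const CharacterVector& x) {
  std::vector<std::string> out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = as<std::string>(x[i]);
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".kmer_index_build")]]
SEXP kmer_index_build(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  std::vector<std::string> ss = as_std(seqs);
  count_kmers(ss, k, idx->map);
  XPtr<KmerIndex> ptr(idx, true);
  return ptr;
}

// Anchors between the indexed set (role: ref) and `seqs` (role: query).
// Returns parallel vectors of 0-based coordinates.
// [[Rcpp::export(name = ".kmer_index_anchors")]]
List kmer_index_anchors(SEXP index, CharacterVector seqs) {
  XPtr<KmerIndex> idx(index);
  const int k = idx->k;
  KmerMap qmap;
  std::vector<std::string> ss = as_std(seqs);
  count_kmers(ss, k, qmap);

  std::vector<int> rc, rp, qc, qp;
  std::vector<int> orient;  // 1 = '+', -1 = '-'
  for (KmerMap::const_iterator it = qmap.begin(); it != qmap.end(); ++it) {
    if (it->second.count != 1) continue;
    KmerMap::const_iterator rit = idx->map.find(it->first);
    if (rit == idx->map.end() || rit->second.count != 1) continue;
    rc.push_back((int)rit->second.chrom);
    rp.push_back((int)rit->second.pos);
    qc.push_back((int)it->second.chrom);
    qp.push_back((int)it->second.pos);
    orient.push_back(rit->second.strand == it->second.strand ? 1 : -1);
  }
  return List::create(_["ref_chrom"] = wrap(rc), _["ref_pos"] = wrap(rp),
                      _["query_chrom"] = wrap(qc), _["query_pos"] = wrap(qp),
                      _["orient"] = wrap(orient));
}

// 0-based start positions of query k-mers that occur anywhere (count >= 1)
// in the indexed set. Used as an alignment-identity proxy: footprint
// coverage by present k-mers, with no uniqueness requirement.
// [[Rcpp::export(name = ".kmer_index_present")]]
IntegerVector kmer_index_present(SEXP index, std::string seq) {
  XPtr<KmerIndex> idx(index);
  const int k = idx->k;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  std::vector<int> out;
  uint64_t fwd = 0, rev = 0;
  int run = 0;
  for (size_t i = 0; i < seq.size(); ++i) {
    int b = base_code(seq[i]);
    if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
    if (++run < k) continue;
    uint64_t canon = fwd <= rev ? fwd : rev;
    if (idx->map.find(canon) != idx->map.end())
      out.push_back((int)(i + 1 - k));
  }
  return wrap(out);
}

// Longest strictly increasing subsequence (maximum cardinality); returns
// 1-based indices of one optimal subsequence, in increasing order.
// [[Rcpp::export(name = ".lis_indices")]]
IntegerVector lis_indices(NumericVector x) {
  int n = x.size();
  if (n == 0) return IntegerVector(0);
  std::vector<int> tail_idx;           // index of smallest tail per length
  std::vector<int> prev(n, -1);
  for (int i = 0; i < n; ++i) {
    // binary search: first tail with value >= x[i]
    int lo = 0, hi = (int)tail_idx.size();
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (x[tail_idx[mid]] < x[i]) lo = mid + 1; else hi = mid;
    }
    if (lo > 0) prev[i] = tail_idx[lo - 1];
    if (lo == (int)tail_idx.size()) tail_idx.push_back(i);
    else tail_idx[lo] = i;
  }
  int len = (int)tail_idx.size();
  IntegerVector out(len);
  int cur = tail_idx[len - 1];
  for (int j = len - 1; j >= 0; --j) { out[j] = cur + 1; cur = prev[cur]; }
  return out;
}
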
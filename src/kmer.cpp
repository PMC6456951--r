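#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// 2-bit base encoding; order-preserving (A<C<G<T) so that min(fwd, rc) on the
// packed integers matches lexicographic canonicalization. Returns -1 for N
// (window skipped), -2 for anything else (hard error upstream).
static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    case 'N': case 'n': return -1;
    default: return -2;
  }
}

typedef std::unordered_map<uint64_t, uint32_t> kmer_map;
typedef std::unordered_set<uint64_t> kmer_set;

// Stream all valid k-length windows of one sequence into a callback.
// Windows containing N are skipped entirely; any non-ACGTN symbol aborts
// with the offending character reported through *bad_char.
template <typename F>
static bool scan_kmers(const char* s, size_t n, int k, bool canonical,
                       F emit, char* bad_char) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift_rc = 2 * (k - 1);
  uint64_t fwd = 0, rc = 0;
  int run = 0;  // length of current valid run
  for (size_t i = 0; i < n; ++i) {
    int code = base2bits(s[i]);
    if (code == -2) { *bad_char = s[i]; return false; }
    if (code == -1) { run = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)code) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - code) << shift_rc);
    if (++run >= k) {
      uint64_t key = canonical ? std::min(fwd, rc) : fwd;
      emit(key);
    }
  }
  return true;
}

static void check_k(int k) {
  if (k < 1 || k > 31)
    stop("k must be between 1 and 31 (2-bit packed counting)");
}

// Count k-mers across a set of sequences; returns the frequency spectrum
// (freq j, count n_j) plus TKC.
// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, CharacterVector ids, int k,
                     bool canonical) {
  check_k(k);
  kmer_map counts;
  double tkc = 0;
  char bad = 0;
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    const char* s = CHAR(STRING_ELT(seqs, r));
    size_t n = LENGTH(STRING_ELT(seqs, r));
    bool ok = scan_kmers(s, n, k, canonical,
                         [&](uint64_t key) { ++counts[key]; ++tkc; }, &bad);
    if (!ok) {
      std::string id = as<std::string>(ids[r]);
      stop("invalid character '%s' in record '%s' (only A, C, G, T, N allowed)",
           std::string(1, bad).c_str(), id.c_str());
    }
  }
  // histogram of multiplicities
  std::unordered_map<uint32_t, double> hist;
  for (kmer_map::const_iterator it = counts.begin(); it != counts.end(); ++it)
    hist[it->second] += 1;
  std::vector<uint32_t> js;
  js.reserve(hist.size());
  for (std::unordered_map<uint32_t, double>::const_iterator it = hist.begin();
       it != hist.end(); ++it)
    js.push_back(it->first);
  std::sort(js.begin(), js.end());
  IntegerVector freq(js.size());
  NumericVector cnt(js.size());
  for (size_t i = 0; i < js.size(); ++i) {
    freq[i] = (int)js[i];
    cnt[i] = hist[js[i]];
  }
  return List::create(_["freq"] = freq, _["count"] = cnt, _["tkc"] = tkc);
}

// Distinct-k-mer overlap between a sample and a genome set, used for the
// initial-coverage statistic: |distinct(sample) ∩ distinct(genomes)|.
// [[Rcpp::export]]
List cpp_kmer_overlap(CharacterVector sample_seqs, CharacterVector genome_seqs,
                      int k, bool canonical) {
  check_k(k);
  char bad = 0;
  kmer_set genome;
  for (R_xlen_t r = 0; r < genome_seqs.size(); ++r) {
    const char* s = CHAR(STRING_ELT(genome_seqs, r));
    size_t n = LENGTH(STRING_ELT(genome_seqs, r));
    if (!scan_kmers(s, n, k, canonical,
                    [&](uint64_t key) { genome.insert(key); }, &bad))
      stop("invalid character '%s' in genome sequence %d",
           std::string(1, bad).c_str(), (int)(r + 1));
  }
  kmer_set sample;
  for (R_xlen_t r = 0; r < sample_seqs.size(); ++r) {
    const char* s = CHAR(STRING_ELT(sample_seqs, r));
    size_t n = LENGTH(STRING_ELT(sample_seqs, r));
    if (!scan_kmers(s, n, k, canonical,
                    [&](uint64_t key) { sample.insert(key); }, &bad))
      stop("invalid character '%s' in sample sequence %d",
           std::string(1, bad).c_str(), (int)(r + 1));
  }
  double shared = 0;
  for (kmer_set::const_iterator it = sample.begin(); it != sample.end(); ++it)
    if (genome.count(*it)) shared += 1;
  return List::create(_["shared"] = shared,
                      _["sample_dkc"] = (double)sample.size(),
                      _["genome_dkc"] = (double)genome.size());
}
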
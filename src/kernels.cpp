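#include <Rcpp.h>
#include <unordered_map>
#include <set>
#include <tuple>
#include <cstdint>
using namespace Rcpp;

// 2-bit base codes; -1 for anything not ACGT (upper case expected)
static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

// SplitMix64 finalizer: seed-free, platform-stable 64-bit mix
static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// Hash values of all canonical k-mers of `seq` (k <= 31), in sequence order.
// Canonical k-mer = min(2-bit encoding of k-mer, encoding of its reverse
// complement). Windows containing non-ACGT symbols are skipped. Hashes are
// returned shifted to 53 bits so they are exactly representable as doubles.
// [[Rcpp::export(name = ".kmer_hashes_cpp")]]
NumericVector kmer_hashes_cpp(std::string seq, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  size_t n = seq.size();
  std::vector<double> out;
  if (n < (size_t)k) return NumericVector(0);
  out.reserve(n - k + 1);
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  uint64_t fwd = 0, rev = 0;
  int run = 0;
  int shift = 2 * (k - 1);
  for (size_t i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
    if (++run >= k) {
      uint64_t canon = fwd < rev ? fwd : rev;
      out.push_back((double)(mix64(canon) >> 11));
    }
  }
  return wrap(out);
}

// Generate `len` bases from an order-`order` Markov chain. `trans` has
// 4^order rows (contexts, most-recent base in the low 2 bits) and 4 columns
// of next-base probabilities (rows sum to 1). Uses R's RNG stream.
// [[Rcpp::export(name = ".markov_sequence_cpp")]]
std::string markov_sequence_cpp(NumericMatrix trans, int order, int len) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  int ncontext = 1;
  for (int i = 0; i < order; ++i) ncontext *= 4;
  if (trans.nrow() != ncontext || trans.ncol() != 4)
    stop("transition matrix must be 4^order x 4");
  std::string out(len, 'A');
  RNGScope scope;
  unsigned int state = 0, smask = ncontext - 1;
  // burn in the context with uniform draws
  for (int i = 0; i < order; ++i) {
    int b = (int)(unif_rand() * 4.0); if (b > 3) b = 3;
    state = ((state << 2) | b) & smask;
  }
  for (int i = 0; i < len; ++i) {
    double u = unif_rand(), acc = 0.0;
    int b = 3;
    for (int j = 0; j < 4; ++j) {
      acc += trans(state, j);
      if (u < acc) { b = j; break; }
    }
    out[i] = bases[b];
    state = ((state << 2) | b) & smask;
  }
  return out;
}

// Maximal exact repeats of length >= min_element shared between two distinct
// contigs (forward strand), found by anchoring on shared min_element-mers
// (polynomial rolling hash) and extending to maximal mismatch-bounded runs.
// Contigs shorter than min_contig are ignored. Coordinates are 0-based
// half-open; each maximal repeat is reported once per (contig pair, diagonal).
// [[Rcpp::export(name = ".exact_repeats_cpp")]]
DataFrame exact_repeats_cpp(CharacterVector seqs, CharacterVector ids,
                            int min_element, int min_contig) {
  int nseq = seqs.size();
  std::vector<std::string> S(nseq);
  std::vector<int> keep;
  for (int i = 0; i < nseq; ++i) {
    S[i] = as<std::string>(seqs[i]);
    if ((int)S[i].size() >= min_contig) keep.push_back(i);
  }
  // rolling hash of all min_element-mers, grouped by hash value
  const uint64_t B = 1099511628211ULL;
  uint64_t Bk = 1;  // B^(min_element-1)
  for (int i = 0; i < min_element - 1; ++i) Bk *= B;
  std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > anchors;
  for (size_t ki = 0; ki < keep.size(); ++ki) {
    int si = keep[ki];
    const std::string &s = S[si];
    int n = (int)s.size();
    if (n < min_element) continue;
    uint64_t h = 0;
    for (int j = 0; j < min_element; ++j) h = h * B + (uint8_t)s[j];
    anchors[h].push_back(std::make_pair(si, 0));
    for (int j = min_element; j < n; ++j) {
      h = (h - (uint8_t)s[j - min_element] * Bk) * B + (uint8_t)s[j];
      anchors[h].push_back(std::make_pair(si, j - min_element + 1));
    }
  }
  // extend anchor pairs; dedupe on (a, b, a_start, b_start)
  std::set<std::tuple<int, int, int, int> > seen;
  std::vector<int> ra, rb, ras, rae, rbs, rbe, rlen;
  for (std::unordered_map<uint64_t,
         std::vector<std::pair<int, int> > >::iterator it = anchors.begin();
       it != anchors.end(); ++it) {
    std::vector<std::pair<int, int> > &v = it->second;
    if (v.size() < 2) continue;
    for (size_t p = 0; p < v.size(); ++p) {
      for (size_t q = p + 1; q < v.size(); ++q) {
        int ai = v[p].first, bi = v[q].first;
        int ap = v[p].second, bp = v[q].second;
        if (ai == bi) continue;  // self-pairs excluded
        if (ai > bi) { std::swap(ai, bi); std::swap(ap, bp); }
        const std::string &A = S[ai], &Bs = S[bi];
        // verify the anchor (guards hash collisions)
        if (A.compare(ap, min_element, Bs, bp, min_element) != 0) continue;
        int la = ap, lb = bp;
        while (la > 0 && lb > 0 && A[la - 1] == Bs[lb - 1]) { --la; --lb; }
        int ea = ap + min_element, eb = bp + min_element;
        while (ea < (int)A.size() && eb < (int)Bs.size() && A[ea] == Bs[eb]) {
          ++ea; ++eb;
        }
        std::tuple<int, int, int, int> key(ai, bi, la, lb);
        if (seen.count(key)) continue;
        seen.insert(key);
        ra.push_back(ai); rb.push_back(bi);
        ras.push_back(la); rae.push_back(ea);
        rbs.push_back(lb); rbe.push_back(eb);
        rlen.push_back(ea - la);
      }
    }
  }
  CharacterVector ca(ra.size()), cb(ra.size());
  for (size_t i = 0; i < ra.size(); ++i) {
    ca[i] = ids[ra[i]];
    cb[i] = ids[rb[i]];
  }
  return DataFrame::create(
    _["contig_a"] = ca, _["a_start"] = ras, _["a_end"] = rae,
    _["contig_b"] = cb, _["b_start"] = rbs, _["b_end"] = rbe,
    _["length"] = rlen, _["stringsAsFactors"] = false);
}
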
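// Canonical k-mer core: 2-bit encoding, counting hashmap, seed scanning,
// and bounded de Bruijn traversal. Codes are uint64, so the full k <= 31
// range is supported here even though R numerics cannot hold 62-bit integers.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <set>
#include <map>
#include <string>
#include <vector>

using namespace Rcpp;

typedef std::unordered_map<uint64_t, uint32_t> KmerMap;

struct KmerTable {
  int k;
  KmerMap counts;
  explicit KmerTable(int k_) : k(k_) {}
};

typedef Rcpp::XPtr<KmerTable> KTPtr;

static inline int base2bits(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
  }
}

static inline char bits2base(int b) {
  static const char tab[5] = "ACGT";
  return tab[b & 3];
}

// reverse complement of a 2-bit code; complement of a base b is 3-b
static uint64_t revcomp_code_u64(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (code & 3ULL));
    code >>= 2;
  }
  return rc;
}

static inline uint64_t canon_u64(uint64_t code, int k) {
  uint64_t rc = revcomp_code_u64(code, k);
  return code < rc ? code : rc;
}

// returns false if seq contains a non-ACGT character
static bool encode_u64(const char* s, int k, uint64_t& out) {
  uint64_t code = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) return false;
    code = (code << 2) | (uint64_t)b;
  }
  out = code;
  return true;
}

static std::string decode_u64(uint64_t code, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = bits2base((int)(code & 3ULL));
    code >>= 2;
  }
  return s;
}

static void check_k(int k) {
  if (k < 3 || k > 31 || k % 2 == 0)
    stop("k must be an odd integer in [3, 31], got %d", k);
}

// [[Rcpp::export(name = ".kt_new")]]
SEXP kt_new(int k) {
  check_k(k);
  KmerTable* tab = new KmerTable(k);
  return KTPtr(tab, true);
}

// Count all length-k windows over {A,C,G,T} in each sequence into the table.
// Rolling 2-bit update; windows touching any other character are skipped.
// [[Rcpp::export(name = ".kt_insert")]]
void kt_insert(SEXP tab_, CharacterVector seqs) {
  KTPtr tab(tab_);
  const int k = tab->k;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    int len = (int)LENGTH(STRING_ELT(seqs, i));
    uint64_t code = 0;
    int run = 0;  // length of current stretch of valid bases
    for (int j = 0; j < len; ++j) {
      int b = base2bits(s[j]);
      if (b < 0) {
        run = 0;
        code = 0;
        continue;
      }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++run >= k) tab->counts[canon_u64(code, k)] += 1;
    }
  }
}

// [[Rcpp::export(name = ".kt_k")]]
int kt_k(SEXP tab_) { return KTPtr(tab_)->k; }

// [[Rcpp::export(name = ".kt_size")]]
double kt_size(SEXP tab_) { return (double)KTPtr(tab_)->counts.size(); }

// [[Rcpp::export(name = ".kt_total")]]
double kt_total(SEXP tab_) {
  KTPtr tab(tab_);
  double tot = 0;
  for (KmerMap::const_iterator it = tab->counts.begin(); it != tab->counts.end(); ++it)
    tot += it->second;
  return tot;
}

// Counts for the canonical forms of given k-mer strings; 0 if absent,
// NA for strings with ambiguous characters or wrong length.
// [[Rcpp::export(name = ".kt_lookup")]]
IntegerVector kt_lookup(SEXP tab_, CharacterVector kmers) {
  KTPtr tab(tab_);
  const int k = tab->k;
  IntegerVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const char* s = CHAR(STRING_ELT(kmers, i));
    uint64_t code;
    if ((int)LENGTH(STRING_ELT(kmers, i)) != k || !encode_u64(s, k, code)) {
      out[i] = NA_INTEGER;
      continue;
    }
    KmerMap::const_iterator it = tab->counts.find(canon_u64(code, k));
    out[i] = (it == tab->counts.end()) ? 0 : (int)it->second;
  }
  return out;
}

// All entries as decoded canonical k-mer strings plus counts.
// [[Rcpp::export(name = ".kt_entries")]]
List kt_entries(SEXP tab_) {
  KTPtr tab(tab_);
  const int k = tab->k;
  R_xlen_t n = (R_xlen_t)tab->counts.size();
  CharacterVector kmers(n);
  IntegerVector counts(n);
  R_xlen_t i = 0;
  for (KmerMap::const_iterator it = tab->counts.begin(); it != tab->counts.end(); ++it, ++i) {
    kmers[i] = decode_u64(it->first, k);
    counts[i] = (int)it->second;
  }
  return List::create(_["kmer"] = kmers, _["count"] = counts);
}

// Histogram of multiplicities; counts >= max_mult pool into the top bin.
// [[Rcpp::export(name = ".kt_spectrum")]]
List kt_spectrum(SEXP tab_, int max_mult) {
  if (max_mult < 1) stop("max_multiplicity must be >= 1");
  KTPtr tab(tab_);
  std::map<uint32_t, double> hist;
  for (KmerMap::const_iterator it = tab->counts.begin(); it != tab->counts.end(); ++it) {
    uint32_t m = it->second;
    if ((int)m > max_mult) m = (uint32_t)max_mult;
    hist[m] += 1;
  }
  R_xlen_t n = (R_xlen_t)hist.size();
  IntegerVector mult(n);
  NumericVector nk(n);
  R_xlen_t i = 0;
  for (std::map<uint32_t, double>::const_iterator it = hist.begin(); it != hist.end(); ++it, ++i) {
    mult[i] = (int)it->first;
    nk[i] = it->second;
  }
  return List::create(_["multiplicity"] = mult, _["n_kmers"] = nk);
}

// Scan table keys for oriented k-mers that begin with a forward variant
// (start k-mers) or end with a reverse-oriented variant (end k-mers).
// Both orientations of each canonical key are tested.
// [[Rcpp::export(name = ".kt_scan_seeds")]]
List kt_scan_seeds(SEXP tab_, CharacterVector fwd_variants, CharacterVector rev_variants) {
  KTPtr tab(tab_);
  const int k = tab->k;

  // all forward variants share one length; likewise reverse
  int lf = fwd_variants.size() ? (int)LENGTH(STRING_ELT(fwd_variants, 0)) : 0;
  int lr = rev_variants.size() ? (int)LENGTH(STRING_ELT(rev_variants, 0)) : 0;
  if (lf > k || lr > k) stop("searched primer longer than k");

  std::unordered_set<uint64_t> fwd_set, rev_set;
  for (R_xlen_t i = 0; i < fwd_variants.size(); ++i) {
    uint64_t c;
    if ((int)LENGTH(STRING_ELT(fwd_variants, i)) != lf)
      stop("forward variants differ in length");
    if (encode_u64(CHAR(STRING_ELT(fwd_variants, i)), lf, c)) fwd_set.insert(c);
  }
  for (R_xlen_t i = 0; i < rev_variants.size(); ++i) {
    uint64_t c;
    if ((int)LENGTH(STRING_ELT(rev_variants, i)) != lr)
      stop("reverse variants differ in length");
    if (encode_u64(CHAR(STRING_ELT(rev_variants, i)), lr, c)) rev_set.insert(c);
  }

  const int shift_f = 2 * (k - lf);
  const uint64_t mask_r = (lr == 32) ? ~0ULL : ((1ULL << (2 * lr)) - 1ULL);

  std::set<std::string> starts, ends;  // sorted for deterministic output
  for (KmerMap::const_iterator it = tab->counts.begin(); it != tab->counts.end(); ++it) {
    uint64_t orient[2];
    orient[0] = it->first;
    orient[1] = revcomp_code_u64(it->first, k);
    for (int o = 0; o < 2; ++o) {
      uint64_t code = orient[o];
      if (lf > 0 && fwd_set.count(code >> shift_f)) starts.insert(decode_u64(code, k));
      if (lr > 0 && rev_set.count(code & mask_r)) ends.insert(decode_u64(code, k));
    }
  }
  return List::create(
      _["start_kmers"] = CharacterVector(starts.begin(), starts.end()),
      _["end_kmers"] = CharacterVector(ends.begin(), ends.end()));
}

struct Path {
  std::string seq;
  uint64_t code;                         // oriented code of last k-mer
  std::unordered_set<uint64_t> visited;  // oriented codes on this path
};

// Breadth-first enumeration of all simple paths (no oriented-k-mer revisit)
// from each start k-mer, emitting the sequence whenever the current k-mer is
// an end k-mer and the length lies in [min_len, max_len]. Traversal continues
// past an end hit so nested, longer products remain discoverable. The live
// frontier per start k-mer is capped at max_paths (truncation flagged).
// [[Rcpp::export(name = ".kt_assemble")]]
List kt_assemble(SEXP tab_, CharacterVector start_kmers, CharacterVector end_kmers,
                 int min_count, double min_len, double max_len, int max_paths) {
  KTPtr tab(tab_);
  const int k = tab->k;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  if (min_count < 1) stop("min_count must be >= 1");
  if (max_paths < 1) stop("max_paths must be >= 1");

  std::unordered_set<uint64_t> end_set;
  for (R_xlen_t i = 0; i < end_kmers.size(); ++i) {
    uint64_t c;
    if ((int)LENGTH(STRING_ELT(end_kmers, i)) != k || !encode_u64(CHAR(STRING_ELT(end_kmers, i)), k, c))
      stop("invalid end k-mer");
    end_set.insert(c);
  }

  std::set<std::string> products;
  bool truncated = false;

  for (R_xlen_t s = 0; s < start_kmers.size(); ++s) {
    uint64_t c0;
    if ((int)LENGTH(STRING_ELT(start_kmers, s)) != k || !encode_u64(CHAR(STRING_ELT(start_kmers, s)), k, c0))
      stop("invalid start k-mer");
    KmerMap::const_iterator it0 = tab->counts.find(canon_u64(c0, k));
    if (it0 == tab->counts.end() || (int)it0->second < min_count) continue;

    std::vector<Path> frontier(1);
    frontier[0].seq = decode_u64(c0, k);
    frontier[0].code = c0;
    frontier[0].visited.insert(c0);
    if (end_set.count(c0) && (double)k >= min_len && (double)k <= max_len)
      products.insert(frontier[0].seq);

    while (!frontier.empty()) {
      std::vector<Path> next;
      for (size_t p = 0; p < frontier.size(); ++p) {
        Path& cur = frontier[p];
        if ((double)cur.seq.size() >= max_len) continue;  // cannot extend further
        for (int b = 0; b < 4; ++b) {  // fixed A,C,G,T successor order
          uint64_t nc = ((cur.code << 2) | (uint64_t)b) & mask;
          KmerMap::const_iterator it = tab->counts.find(canon_u64(nc, k));
          if (it == tab->counts.end() || (int)it->second < min_count) continue;
          if (cur.visited.count(nc)) continue;
          Path np;
          np.seq = cur.seq;
          np.seq.push_back(bits2base(b));
          np.code = nc;
          np.visited = cur.visited;
          np.visited.insert(nc);
          if (end_set.count(nc) && (double)np.seq.size() >= min_len &&
              (double)np.seq.size() <= max_len)
            products.insert(np.seq);
          next.push_back(std::move(np));
        }
      }
      if ((int)next.size() > max_paths) {
        truncated = true;
        next.resize((size_t)max_paths);
      }
      frontier.swap(next);
    }
  }

  return List::create(
      _["sequences"] = CharacterVector(products.begin(), products.end()),
      _["truncated"] = truncated);
}

// ---- small scalar helpers exposed for the R-level encoding API (k <= 26
// so codes stay exact in doubles) ----

static void check_k_small(int k) {
  check_k(k);
  if (k > 26) stop("numeric k-mer codes at the R level require k <= 26");
}

// [[Rcpp::export(name = ".encode_kmer")]]
double encode_kmer_cpp(std::string seq) {
  int k = (int)seq.size();
  check_k_small(k);
  uint64_t code;
  if (!encode_u64(seq.c_str(), k, code)) return NA_REAL;  // ambiguous base: caller skips
  return (double)code;
}

// [[Rcpp::export(name = ".decode_kmer")]]
std::string decode_kmer_cpp(double code, int k) {
  check_k_small(k);
  if (code < 0 || code >= std::ldexp(1.0, 2 * k)) stop("code out of range for k=%d", k);
  return decode_u64((uint64_t)code, k);
}

// [[Rcpp::export(name = ".revcomp_code")]]
double revcomp_code_cpp(double code, int k) {
  check_k_small(k);
  if (code < 0 || code >= std::ldexp(1.0, 2 * k)) stop("code out of range for k=%d", k);
  return (double)revcomp_code_u64((uint64_t)code, k);
}
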
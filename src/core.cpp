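// Core bit-level k-mer machinery, database writer and LIS.
//
// k-mers are packed big-endian into a 64-bit word, 2 bits per base
// (A=00, C=01, G=10, T=11), so the complement of a base is the bitwise
// NOT of its 2-bit code and a window slide is a shift-or-mask. Codes
// cross the R boundary either as doubles (exact for k <= 26) or as
// decimal strings (any k <= 32).

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <cstdio>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

static inline uint64_t mask_for(int k) {
  return (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
}

// Reverse complement of a packed k-mer: complement every 2-bit pair
// (bitwise NOT), reverse the pair order across the full word, then
// shift the result down into the low 2k bits.
static inline uint64_t rc_code(uint64_t code, int k) {
  uint64_t x = ~code;
  x = ((x & 0x3333333333333333ULL) << 2) | ((x >> 2) & 0x3333333333333333ULL);
  x = ((x & 0x0F0F0F0F0F0F0F0FULL) << 4) | ((x >> 4) & 0x0F0F0F0F0F0F0F0FULL);
  x = ((x & 0x00FF00FF00FF00FFULL) << 8) | ((x >> 8) & 0x00FF00FF00FF00FFULL);
  x = ((x & 0x0000FFFF0000FFFFULL) << 16) | ((x >> 16) & 0x0000FFFF0000FFFFULL);
  x = (x << 32) | (x >> 32);
  return x >> (64 - 2 * k);
}

static inline std::string code2string(uint64_t v) {
  char buf[24];
  std::snprintf(buf, sizeof(buf), "%llu", (unsigned long long)v);
  return std::string(buf);
}

static uint64_t parse_code(const char* s) {
  uint64_t v = 0;
  for (const char* p = s; *p; ++p) {
    if (*p < '0' || *p > '9') stop("invalid k-mer code string '%s'", s);
    v = v * 10ULL + (uint64_t)(*p - '0');
  }
  return v;
}

// ---- scalar helpers (double interface, exact for k <= 26) -----------------

// [[Rcpp::export]]
double cpp_encode(std::string seq, int k) {
  uint64_t code = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bits(seq[i]);
    if (b < 0) stop("non-ACGT base in k-mer");
    code = (code << 2) | (uint64_t)b;
  }
  return (double)code;
}

// [[Rcpp::export]]
std::string cpp_decode(double code, int k) {
  uint64_t v = (uint64_t)code;
  std::string out(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    out[i] = BITS2BASE[v & 3ULL];
    v >>= 2;
  }
  return out;
}

// [[Rcpp::export]]
double cpp_roll(double code, std::string next_base, int k) {
  int b = base2bits(next_base[0]);
  if (b < 0) stop("non-ACGT base");
  uint64_t v = (((uint64_t)code << 2) | (uint64_t)b) & mask_for(k);
  return (double)v;
}

// [[Rcpp::export]]
double cpp_revcomp(double code, int k) {
  return (double)rc_code((uint64_t)code, k);
}

// ---- k-mer counting --------------------------------------------------------

// Calls f(pos, fwd, rev) for every ACGT-only window; windows touching a
// non-ACGT base are skipped and the rolling state restarts after it.
template <class F>
static void for_each_window(const char* s, size_t n, int k, F f) {
  uint64_t fwd = 0, rev = 0;
  const uint64_t msk = mask_for(k);
  const int shift_rc = 2 * (k - 1);
  int run = 0;
  for (size_t i = 0; i < n; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & msk;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << shift_rc);
    if (++run >= k) f((long)i - k + 1, fwd, rev);
  }
}

static void count_into(const char* s, size_t n, int k,
                       std::unordered_map<uint64_t, int>& tab,
                       double* total) {
  for_each_window(s, n, k, [&](long, uint64_t fwd, uint64_t rev) {
    tab[std::min(fwd, rev)] += 1;
    *total += 1;
  });
}

// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k) {
  std::unordered_map<uint64_t, int> tab;
  double total = 0;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    count_into(s, LENGTH(STRING_ELT(seqs, i)), k, tab, &total);
  }
  std::vector<std::pair<uint64_t, int>> v(tab.begin(), tab.end());
  std::sort(v.begin(), v.end());
  CharacterVector codes(v.size());
  IntegerVector counts(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    codes[i] = code2string(v[i].first);
    counts[i] = v[i].second;
  }
  return List::create(_["code"] = codes, _["count"] = counts,
                      _["total_windows"] = total);
}

// ---- rare k-mer scanning ---------------------------------------------------

struct OccBuf {
  std::vector<long> pos;
  std::vector<uint64_t> code;
  std::vector<char> orient;
};

static void scan_into(const char* s, size_t n, int k,
                      const std::unordered_set<uint64_t>& rare, OccBuf& out) {
  for_each_window(s, n, k, [&](long p, uint64_t fwd, uint64_t rev) {
    uint64_t canon = std::min(fwd, rev);
    if (rare.count(canon)) {
      out.pos.push_back(p);
      out.code.push_back(canon);
      out.orient.push_back(fwd <= rev ? '+' : '-');
    }
  });
}

// [[Rcpp::export]]
List cpp_scan(std::string seq, CharacterVector rare_codes, int k) {
  std::unordered_set<uint64_t> rare;
  rare.reserve(rare_codes.size() * 2 + 8);
  for (R_xlen_t i = 0; i < rare_codes.size(); ++i)
    rare.insert(parse_code(CHAR(STRING_ELT(rare_codes, i))));
  OccBuf buf;
  scan_into(seq.c_str(), seq.size(), k, rare, buf);
  IntegerVector pos(buf.pos.size());
  CharacterVector code(buf.pos.size());
  CharacterVector orient(buf.pos.size());
  for (size_t i = 0; i < buf.pos.size(); ++i) {
    pos[i] = (int)buf.pos[i];
    code[i] = code2string(buf.code[i]);
    orient[i] = std::string(1, buf.orient[i]);
  }
  return List::create(_["pos"] = pos, _["code"] = code, _["orient"] = orient);
}

// ---- database writer -------------------------------------------------------

// FNV-1a over the bytes written after the header; recorded in the index
// header so rebuilds can be checked cheaply.
struct Fnv {
  uint64_t h = 1469598103934665603ULL;
  void update(const char* s, size_t n) {
    for (size_t i = 0; i < n; ++i) {
      h ^= (uint64_t)(unsigned char)s[i];
      h *= 1099511628211ULL;
    }
  }
};

static void append_plain_record(std::string& line, long pos, uint64_t code,
                                char orient) {
  char buf[48];
  int n = std::snprintf(buf, sizeof(buf), "%ld:%llu:%c", pos,
                        (unsigned long long)code, orient);
  line.append(buf, n);
}

// Fixed-width record for in-file binary search: 12-digit position,
// 20-digit code, 1-char orientation -> 35 bytes, 36 with the separator.
static void append_fixed_record(std::string& line, long pos, uint64_t code,
                                char orient) {
  char buf[48];
  int n = std::snprintf(buf, sizeof(buf), "%012ld:%020llu:%c", pos,
                        (unsigned long long)code, orient);
  line.append(buf, n);
}

// Scans each sequence against the rare set and writes one line per
// sequence: id TAB n TAB rec[,rec]* NL. Returns per-sequence byte
// offsets (doubles: files may exceed 2^31 bytes) and occurrence counts.
static List write_db_file(CharacterVector ids, CharacterVector seqs, int k,
                          const std::unordered_set<uint64_t>& rare,
                          const std::string& path, const std::string& header,
                          bool fixed_width) {
  FILE* fp = std::fopen(path.c_str(), "wb");
  if (!fp) stop("cannot open '%s' for writing", path.c_str());
  std::fwrite(header.data(), 1, header.size(), fp);
  double offset = (double)header.size();
  NumericVector offsets(ids.size());
  NumericVector n_occ(ids.size());
  double total = 0;
  Fnv hash;
  std::string line;
  OccBuf buf;
  for (R_xlen_t i = 0; i < ids.size(); ++i) {
    buf.pos.clear(); buf.code.clear(); buf.orient.clear();
    const char* s = CHAR(STRING_ELT(seqs, i));
    scan_into(s, LENGTH(STRING_ELT(seqs, i)), k, rare, buf);
    line.clear();
    line.append(CHAR(STRING_ELT(ids, i)));
    char nb[24];
    int nn = std::snprintf(nb, sizeof(nb), "\t%zu\t", buf.pos.size());
    line.append(nb, nn);
    for (size_t j = 0; j < buf.pos.size(); ++j) {
      if (j) line.push_back(',');
      if (fixed_width)
        append_fixed_record(line, buf.pos[j], buf.code[j], buf.orient[j]);
      else
        append_plain_record(line, buf.pos[j], buf.code[j], buf.orient[j]);
    }
    line.push_back('\n');
    std::fwrite(line.data(), 1, line.size(), fp);
    hash.update(line.data(), line.size());
    offsets[i] = offset;
    n_occ[i] = (double)buf.pos.size();
    total += (double)buf.pos.size();
    offset += (double)line.size();
  }
  std::fclose(fp);
  return List::create(_["offset"] = offsets, _["n_occ"] = n_occ,
                      _["total_occ"] = total,
                      _["hash"] = code2string(hash.h));
}

// One-pass builder: count reference k-mers, select the rare set, scan and
// write both database files. Keeping codes inside C++ avoids shipping
// millions of code strings through R on genome-scale inputs.
// [[Rcpp::export]]
List cpp_build_dbs(CharacterVector ref_ids, CharacterVector ref_seqs,
                   CharacterVector qry_ids, CharacterVector qry_seqs, int k,
                   int m, std::string ref_path, std::string qry_path,
                   std::string ref_header, std::string qry_header) {
  std::unordered_map<uint64_t, int> tab;
  double total_windows = 0;
  for (R_xlen_t i = 0; i < ref_seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(ref_seqs, i));
    count_into(s, LENGTH(STRING_ELT(ref_seqs, i)), k, tab, &total_windows);
  }
  std::unordered_set<uint64_t> rare;
  rare.reserve(tab.size());
  for (const auto& kv : tab)
    if (kv.second <= m) rare.insert(kv.first);
  double distinct = (double)tab.size();
  tab.clear();

  List ref_out = write_db_file(ref_ids, ref_seqs, k, rare, ref_path,
                               ref_header, false);
  List qry_out = write_db_file(qry_ids, qry_seqs, k, rare, qry_path,
                               qry_header, true);
  return List::create(
      _["ref"] = ref_out, _["qry"] = qry_out,
      _["total_windows"] = total_windows, _["distinct_kmers"] = distinct,
      _["rare_kmers"] = (double)rare.size());
}

// ---- record-block parsing --------------------------------------------------

// Parses "pos:code:orient[,pos:code:orient]*" (plain or fixed-width,
// trailing separators tolerated) into parallel vectors. Codes are
// re-emitted in plain decimal so both dialects compare equal.
// [[Rcpp::export]]
List cpp_parse_records(std::string block) {
  std::vector<long> pos;
  std::vector<uint64_t> code;
  std::vector<char> orient;
  const char* p = block.c_str();
  const char* end = p + block.size();
  while (p < end) {
    while (p < end && (*p == ',' || *p == '\n' || *p == '\r')) ++p;
    if (p >= end) break;
    long pv = 0;
    while (p < end && *p >= '0' && *p <= '9') pv = pv * 10 + (*p++ - '0');
    if (p >= end || *p != ':') stop("malformed occurrence record");
    ++p;
    uint64_t cv = 0;
    while (p < end && *p >= '0' && *p <= '9') cv = cv * 10ULL + (uint64_t)(*p++ - '0');
    if (p >= end || *p != ':') stop("malformed occurrence record");
    ++p;
    if (p >= end || (*p != '+' && *p != '-')) stop("malformed occurrence record");
    pos.push_back(pv);
    code.push_back(cv);
    orient.push_back(*p++);
  }
  IntegerVector rp(pos.size());
  CharacterVector rc(pos.size());
  CharacterVector ro(pos.size());
  for (size_t i = 0; i < pos.size(); ++i) {
    rp[i] = (int)pos[i];
    rc[i] = code2string(code[i]);
    ro[i] = std::string(1, orient[i]);
  }
  return List::create(_["pos"] = rp, _["code"] = rc, _["orient"] = ro);
}

// ---- longest strictly increasing subsequence -------------------------------

// Patience method: tails[j] holds the smallest possible tail of an
// increasing subsequence of length j+1; each element replaces the first
// tail >= itself (strict LIS), O(n log n).
// [[Rcpp::export]]
int cpp_lis(IntegerVector x) {
  std::vector<int> tails;
  tails.reserve(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    auto it = std::lower_bound(tails.begin(), tails.end(), x[i]);
    if (it == tails.end())
      tails.push_back(x[i]);
    else
      *it = x[i];
  }
  return (int)tails.size();
}

// ---- read error model ------------------------------------------------------

// Per-base errors at the given rate, substitution:insertion:deletion in
// ratio 1:1:1; substitutions change to one of the three other bases,
// insertions add a uniform random base before the current one. Uses R's
// RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
std::string cpp_apply_read_errors(std::string seq, double rate) {
  std::string out;
  out.reserve(seq.size() + (size_t)(seq.size() * rate / 2) + 16);
  for (size_t i = 0; i < seq.size(); ++i) {
    double u = unif_rand();
    if (u >= rate) { out.push_back(seq[i]); continue; }
    double v = unif_rand();
    if (v < 1.0 / 3.0) {
      int b = base2bits(seq[i]);
      int nb = (int)(unif_rand() * 3.0);
      if (nb >= b) ++nb;       // one of the three other bases
      out.push_back(BITS2BASE[nb & 3]);
    } else if (v < 2.0 / 3.0) {
      out.push_back(BITS2BASE[(int)(unif_rand() * 4.0) & 3]);
      out.push_back(seq[i]);
    }                           // else deletion: emit nothing
  }
  return out;
}

// [[Rcpp::export]]
std::string cpp_revcomp_string(std::string seq) {
  std::string out(seq.size(), 'N');
  for (size_t i = 0; i < seq.size(); ++i) {
    char c = seq[seq.size() - 1 - i];
    switch (c) {
    case 'A': case 'a': out[i] = 'T'; break;
    case 'C': case 'c': out[i] = 'G'; break;
    case 'G': case 'g': out[i] = 'C'; break;
    case 'T': case 't': out[i] = 'A'; break;
    default: out[i] = 'N';
    }
  }
  return out;
}

// ---- fast per-alignment scoring -------------------------------------------

// Parsed whole-sequence reference occurrence list held in C++ so interval
// scoring avoids round-tripping millions of code strings through R.
struct RefList {
  std::vector<long> pos;
  std::vector<uint64_t> code;
};

static void parse_block(const std::string& block, std::vector<long>& pos,
                        std::vector<uint64_t>& code) {
  const char* p = block.c_str();
  const char* end = p + block.size();
  while (p < end) {
    while (p < end && (*p == ',' || *p == '\n' || *p == '\r')) ++p;
    if (p >= end) break;
    long pv = 0;
    while (p < end && *p >= '0' && *p <= '9') pv = pv * 10 + (*p++ - '0');
    if (p >= end || *p != ':') stop("malformed occurrence record");
    ++p;
    uint64_t cv = 0;
    while (p < end && *p >= '0' && *p <= '9') cv = cv * 10ULL + (uint64_t)(*p++ - '0');
    if (p >= end || *p != ':') stop("malformed occurrence record");
    ++p;
    if (p >= end || (*p != '+' && *p != '-')) stop("malformed occurrence record");
    ++p;
    pos.push_back(pv);
    code.push_back(cv);
  }
}

// [[Rcpp::export]]
SEXP cpp_parse_ref_list(std::string records) {
  XPtr<RefList> ptr(new RefList(), true);
  parse_block(records, ptr->pos, ptr->code);
  return ptr;
}

// Scores one alignment: reference sublist from the cached list (binary
// search on [start, end - k]), query sublist from its raw fixed-width
// block, unique-unique code matching, then LIS of reference positions in
// query order (reversed first for '-' strand alignments).
// [[Rcpp::export]]
List cpp_score_interval(SEXP ref_ptr, double start, double end, int k,
                        std::string qry_block, std::string strand) {
  XPtr<RefList> ref(ref_ptr);
  long lo_pos = (long)start;
  long hi_pos = (long)end - k;
  auto first = std::lower_bound(ref->pos.begin(), ref->pos.end(), lo_pos);
  auto last = std::upper_bound(ref->pos.begin(), ref->pos.end(), hi_pos);
  size_t i0 = first - ref->pos.begin();
  size_t i1 = last - ref->pos.begin();
  int l_r = (int)(i1 - i0);

  std::vector<long> qpos;
  std::vector<uint64_t> qcode;
  parse_block(qry_block, qpos, qcode);
  int l_q = (int)qpos.size();

  // code -> (multiplicity, ref position) within the reference sublist
  std::unordered_map<uint64_t, std::pair<int, long>> rmap;
  rmap.reserve((size_t)l_r * 2 + 8);
  for (size_t i = i0; i < i1; ++i) {
    auto& e = rmap[ref->code[i]];
    e.first += 1;
    e.second = ref->pos[i];
  }
  std::unordered_map<uint64_t, int> qcount;
  qcount.reserve((size_t)l_q * 2 + 8);
  for (int i = 0; i < l_q; ++i) qcount[qcode[i]] += 1;

  std::vector<int> seq;  // ref positions of unique-unique matches, query order
  seq.reserve(std::min(l_r, l_q));
  for (int i = 0; i < l_q; ++i) {
    if (qcount[qcode[i]] != 1) continue;
    auto it = rmap.find(qcode[i]);
    if (it == rmap.end() || it->second.first != 1) continue;
    seq.push_back((int)it->second.second);
  }
  if (strand == "-") std::reverse(seq.begin(), seq.end());

  std::vector<int> tails;
  tails.reserve(seq.size());
  for (int v : seq) {
    auto it = std::lower_bound(tails.begin(), tails.end(), v);
    if (it == tails.end()) tails.push_back(v); else *it = v;
  }
  return List::create(_["l_r"] = l_r, _["l_q"] = l_q,
                      _["l_lis"] = (int)tails.size());
}
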
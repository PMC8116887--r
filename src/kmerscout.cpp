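// Core external-memory kernels: 2-bit k-mer codes, sort-reduce runs,
// the k-mer-indexed histogram file and the chunked root key-value store.
// All integer keys live here as uint64; only root codes (<= 2^52 for k <= 28)
// cross the R boundary as doubles.
#include <Rcpp.h>
#include <cstdint>
#include <cstdio>
#include <cstring>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

static const char* RUN_MAGIC = "SRR1";
static const char* HIST_MAGIC = "KMH1";
static const char* STORE_MAGIC = "KVR1";
static const int REC_BYTES = 12;          // 8-byte key + two 2-byte counters
static const int ROOT_REC_BYTES = 136;    // 8-byte root + 64 x 2-byte counters

struct Rec {
  uint64_t key;
  uint16_t n, t;
};

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}
static inline char code_base(int b) { return "ACGT"[b & 3]; }

static inline uint64_t revcomp_code(uint64_t code, int n) {
  uint64_t res = 0;
  for (int i = 0; i < n; ++i) {
    res = (res << 2) | (3ULL - (code & 3ULL));
    code >>= 2;
  }
  return res;
}

static inline uint16_t sat_add(uint16_t a, uint16_t b) {
  uint32_t s = (uint32_t)a + (uint32_t)b;
  return s > 65535u ? (uint16_t)65535u : (uint16_t)s;
}

// key layout: (root << 5) | (stem_flag << 4) | (first << 2) | last
static inline void kmer_key_parts(uint64_t code, int k, uint64_t* key,
                                  uint64_t* root, int* vidx) {
  int ks = k - 2;
  uint64_t first = code >> (2 * (k - 1));
  uint64_t last = code & 3ULL;
  uint64_t stem_mask = (ks >= 32) ? ~0ULL : ((1ULL << (2 * ks)) - 1ULL);
  uint64_t stem = (code >> 2) & stem_mask;
  uint64_t rc = revcomp_code(stem, ks);
  uint64_t rt = stem <= rc ? stem : rc;
  uint64_t flag = stem == rt ? 0 : 1;
  int v = (int)((flag << 4) | (first << 2) | last);
  *key = (rt << 5) | (uint64_t)v;
  *root = rt;
  *vidx = v;
}

static std::string decode_code(uint64_t code, int n) {
  std::string s(n, 'A');
  for (int i = n - 1; i >= 0; --i) {
    s[i] = code_base((int)(code & 3ULL));
    code >>= 2;
  }
  return s;
}

// ---------------------------------------------------------------- encoding

// [[Rcpp::export]]
NumericVector cpp_encode_codes(CharacterVector seqs) {
  R_xlen_t m = seqs.size();
  NumericVector out(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    if (seqs[i] == NA_STRING) { out[i] = NA_REAL; continue; }
    const char* s = CHAR(seqs[i]);
    size_t n = std::strlen(s);
    if (n == 0 || n > 26) { out[i] = NA_REAL; continue; }
    uint64_t code = 0;
    bool ok = true;
    for (size_t j = 0; j < n; ++j) {
      int b = base_code(s[j]);
      if (b < 0) { ok = false; break; }
      code = (code << 2) | (uint64_t)b;
    }
    out[i] = ok ? (double)code : NA_REAL;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_decode_codes(NumericVector codes, int n) {
  R_xlen_t m = codes.size();
  CharacterVector out(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    if (NumericVector::is_na(codes[i])) { out[i] = NA_STRING; continue; }
    out[i] = decode_code((uint64_t)codes[i], n);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp_str(CharacterVector seqs) {
  R_xlen_t m = seqs.size();
  CharacterVector out(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    if (seqs[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    const char* s = CHAR(seqs[i]);
    size_t n = std::strlen(s);
    std::string r(n, 'N');
    for (size_t j = 0; j < n; ++j) {
      int b = base_code(s[n - 1 - j]);
      if (b < 0) stop("revcomp: non-ACGT character in '%s'", s);
      r[j] = code_base(3 - b);
    }
    out[i] = r;
  }
  return out;
}

// Per-window k-mer hits of a set of reads, restricted to a root range.
// Returns 1-based read index, 0-based window start, root code, variant index.
// [[Rcpp::export]]
List cpp_read_kmer_hits(CharacterVector seqs, int k, double root_lo,
                        double root_hi) {
  uint64_t lo = (uint64_t)root_lo, hi = (uint64_t)root_hi;
  std::vector<int> rd, pos, vidx;
  std::vector<double> root;
  uint64_t kmask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(seqs[i]);
    int n = (int)std::strlen(s);
    uint64_t code = 0;
    int len = 0;
    for (int j = 0; j < n; ++j) {
      int b = base_code(s[j]);
      if (b < 0) { len = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & kmask;
      if (++len >= k) {
        uint64_t key, rt; int v;
        kmer_key_parts(code, k, &key, &rt, &v);
        if (rt >= lo && rt < hi) {
          rd.push_back((int)i + 1);
          pos.push_back(j - k + 1);
          root.push_back((double)rt);
          vidx.push_back(v);
        }
      }
    }
  }
  return List::create(_["read"] = wrap(rd), _["pos"] = wrap(pos),
                      _["root"] = wrap(root), _["vidx"] = wrap(vidx));
}

// ---------------------------------------------------------------- run files

static FILE* open_checked(const std::string& path, const char* mode) {
  FILE* f = std::fopen(path.c_str(), mode);
  if (!f) stop("cannot open '%s'", path);
  return f;
}

static void write_run_file(const std::string& path, const std::vector<Rec>& recs) {
  FILE* f = open_checked(path, "wb");
  std::fwrite(RUN_MAGIC, 1, 4, f);
  uint64_t cnt = recs.size();
  std::fwrite(&cnt, 8, 1, f);
  for (const Rec& r : recs) {
    std::fwrite(&r.key, 8, 1, f);
    std::fwrite(&r.n, 2, 1, f);
    std::fwrite(&r.t, 2, 1, f);
  }
  std::fclose(f);
}

static void sort_reduce_buffer(std::vector<Rec>& buf) {
  std::sort(buf.begin(), buf.end(),
            [](const Rec& a, const Rec& b) { return a.key < b.key; });
  size_t w = 0;
  for (size_t i = 0; i < buf.size(); ++i) {
    if (w > 0 && buf[w - 1].key == buf[i].key) {
      buf[w - 1].n = sat_add(buf[w - 1].n, buf[i].n);
      buf[w - 1].t = sat_add(buf[w - 1].t, buf[i].t);
    } else {
      buf[w++] = buf[i];
    }
  }
  buf.resize(w);
}

struct RunReader {
  FILE* f = nullptr;
  uint64_t left = 0;
  Rec cur;
  bool has = false;
  std::string path;
  void open(const std::string& p) {
    path = p;
    f = open_checked(p, "rb");
    char magic[4];
    if (std::fread(magic, 1, 4, f) != 4 || std::memcmp(magic, RUN_MAGIC, 4) != 0)
      stop("'%s' is not a run file", p);
    if (std::fread(&left, 8, 1, f) != 1) stop("truncated run '%s'", p);
    advance();
  }
  void advance() {
    if (left == 0) { has = false; return; }
    if (std::fread(&cur.key, 8, 1, f) != 1 || std::fread(&cur.n, 2, 1, f) != 1 ||
        std::fread(&cur.t, 2, 1, f) != 1)
      stop("truncated run '%s'", path);
    --left;
    has = true;
  }
  void close() { if (f) { std::fclose(f); f = nullptr; } }
};

// [[Rcpp::export]]
CharacterVector cpp_spill_runs(NumericVector keys, IntegerVector n,
                               IntegerVector t, double max_records,
                               std::string dir, std::string prefix) {
  size_t cap = (size_t)std::max(1.0, max_records);
  std::vector<Rec> buf;
  buf.reserve(std::min(cap, (size_t)keys.size()));
  std::vector<std::string> paths;
  int runno = 0;
  for (R_xlen_t i = 0; i < keys.size(); ++i) {
    Rec r;
    r.key = (uint64_t)keys[i];
    r.n = (uint16_t)std::min(n[i], 65535);
    r.t = (uint16_t)std::min(t[i], 65535);
    buf.push_back(r);
    if (buf.size() >= cap) {
      sort_reduce_buffer(buf);
      std::string p = dir + "/" + prefix + "_" + std::to_string(runno++) + ".srr";
      write_run_file(p, buf);
      paths.push_back(p);
      buf.clear();
    }
  }
  if (!buf.empty()) {
    sort_reduce_buffer(buf);
    std::string p = dir + "/" + prefix + "_" + std::to_string(runno++) + ".srr";
    write_run_file(p, buf);
    paths.push_back(p);
  }
  return wrap(paths);
}

// [[Rcpp::export]]
void cpp_write_run(NumericVector keys, IntegerVector n, IntegerVector t,
                   std::string path) {
  std::vector<Rec> recs(keys.size());
  for (R_xlen_t i = 0; i < keys.size(); ++i) {
    recs[i].key = (uint64_t)keys[i];
    recs[i].n = (uint16_t)std::min(n[i], 65535);
    recs[i].t = (uint16_t)std::min(t[i], 65535);
    if (i > 0 && recs[i].key <= recs[i - 1].key)
      stop("run records must be strictly increasing by key");
  }
  write_run_file(path, recs);
}

// [[Rcpp::export]]
List cpp_read_run(std::string path) {
  RunReader rr;
  rr.open(path);
  std::vector<double> keys;
  std::vector<int> n, t;
  while (rr.has) {
    keys.push_back((double)rr.cur.key);
    n.push_back(rr.cur.n);
    t.push_back(rr.cur.t);
    rr.advance();
  }
  rr.close();
  return List::create(_["key"] = wrap(keys), _["n"] = wrap(n), _["t"] = wrap(t));
}

// [[Rcpp::export]]
double cpp_run_count(std::string path) {
  FILE* f = open_checked(path, "rb");
  char magic[4];
  uint64_t cnt = 0;
  if (std::fread(magic, 1, 4, f) != 4 || std::memcmp(magic, RUN_MAGIC, 4) != 0)
    stop("'%s' is not a run file", path);
  if (std::fread(&cnt, 8, 1, f) != 1) stop("truncated run '%s'", path);
  std::fclose(f);
  return (double)cnt;
}

// Merge <= fan-in sorted runs into one, reducing equal keys by saturating
// addition. Validates monotonicity of every input.
// [[Rcpp::export]]
double cpp_merge_runs_pass(CharacterVector runs, std::string out) {
  size_t m = runs.size();
  std::vector<RunReader> rs(m);
  for (size_t i = 0; i < m; ++i) rs[i].open(std::string(runs[i]));
  FILE* f = open_checked(out, "wb");
  std::fwrite(RUN_MAGIC, 1, 4, f);
  uint64_t cnt = 0;
  std::fwrite(&cnt, 8, 1, f);  // patched at end
  bool have_pending = false;
  Rec pend{};
  std::vector<uint64_t> last(m, 0);
  std::vector<bool> first(m, true);
  while (true) {
    int best = -1;
    for (size_t i = 0; i < m; ++i) {
      if (rs[i].has && (best < 0 || rs[i].cur.key < rs[best].cur.key)) best = (int)i;
    }
    if (best < 0) break;
    Rec r = rs[best].cur;
    if (!first[best] && r.key <= last[best])
      stop("corrupt run '%s': keys not strictly increasing", rs[best].path);
    first[best] = false;
    last[best] = r.key;
    rs[best].advance();
    if (have_pending && pend.key == r.key) {
      pend.n = sat_add(pend.n, r.n);
      pend.t = sat_add(pend.t, r.t);
    } else {
      if (have_pending) {
        std::fwrite(&pend.key, 8, 1, f);
        std::fwrite(&pend.n, 2, 1, f);
        std::fwrite(&pend.t, 2, 1, f);
        ++cnt;
      }
      pend = r;
      have_pending = true;
    }
  }
  if (have_pending) {
    std::fwrite(&pend.key, 8, 1, f);
    std::fwrite(&pend.n, 2, 1, f);
    std::fwrite(&pend.t, 2, 1, f);
    ++cnt;
  }
  std::fseek(f, 4, SEEK_SET);
  std::fwrite(&cnt, 8, 1, f);
  std::fclose(f);
  for (size_t i = 0; i < m; ++i) rs[i].close();
  return (double)cnt;
}

// Emit (sort_key, counter-pair) updates for every valid window of every read
// whose root falls in [lo, hi), spilling sorted-reduced runs of at most
// max_records buffered updates (phase 1 fused with emission).
// [[Rcpp::export]]
CharacterVector cpp_count_spill(CharacterVector seqs, bool tumoral, int k,
                                double root_lo, double root_hi,
                                double max_records, std::string dir,
                                std::string prefix) {
  uint64_t lo = (uint64_t)root_lo, hi = (uint64_t)root_hi;
  size_t cap = (size_t)std::max(1.0, max_records);
  uint64_t kmask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  std::vector<Rec> buf;
  buf.reserve(cap);
  std::vector<std::string> paths;
  int runno = 0;
  uint16_t un = tumoral ? 0 : 1, ut = tumoral ? 1 : 0;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(seqs[i]);
    int n = (int)std::strlen(s);
    uint64_t code = 0;
    int len = 0;
    for (int j = 0; j < n; ++j) {
      int b = base_code(s[j]);
      if (b < 0) { len = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & kmask;
      if (++len >= k) {
        uint64_t key, rt; int v;
        kmer_key_parts(code, k, &key, &rt, &v);
        if (rt >= lo && rt < hi) {
          buf.push_back(Rec{key, un, ut});
          if (buf.size() >= cap) {
            sort_reduce_buffer(buf);
            std::string p =
                dir + "/" + prefix + "_" + std::to_string(runno++) + ".srr";
            write_run_file(p, buf);
            paths.push_back(p);
            buf.clear();
          }
        }
      }
    }
  }
  if (!buf.empty()) {
    sort_reduce_buffer(buf);
    std::string p = dir + "/" + prefix + "_" + std::to_string(runno++) + ".srr";
    write_run_file(p, buf);
    paths.push_back(p);
  }
  return wrap(paths);
}

// ------------------------------------------------------------- histogram

struct HistHeader {
  uint32_t k;
  uint64_t root_lo, root_hi, n_entries, n_roots, singleton_roots;
  uint8_t saturated;
};

static void write_hist_header(FILE* f, const HistHeader& h) {
  std::fwrite(HIST_MAGIC, 1, 4, f);
  std::fwrite(&h.k, 4, 1, f);
  std::fwrite(&h.root_lo, 8, 1, f);
  std::fwrite(&h.root_hi, 8, 1, f);
  std::fwrite(&h.n_entries, 8, 1, f);
  std::fwrite(&h.n_roots, 8, 1, f);
  std::fwrite(&h.singleton_roots, 8, 1, f);
  std::fwrite(&h.saturated, 1, 1, f);
}

static HistHeader read_hist_header(FILE* f, const std::string& path) {
  char magic[4];
  HistHeader h{};
  if (std::fread(magic, 1, 4, f) != 4 || std::memcmp(magic, HIST_MAGIC, 4) != 0)
    stop("'%s' is not a histogram file", path);
  if (std::fread(&h.k, 4, 1, f) != 1 || std::fread(&h.root_lo, 8, 1, f) != 1 ||
      std::fread(&h.root_hi, 8, 1, f) != 1 ||
      std::fread(&h.n_entries, 8, 1, f) != 1 ||
      std::fread(&h.n_roots, 8, 1, f) != 1 ||
      std::fread(&h.singleton_roots, 8, 1, f) != 1 ||
      std::fread(&h.saturated, 1, 1, f) != 1)
    stop("truncated histogram header in '%s'", path);
  return h;
}

// Stream a reduced run, drop all entries of singleton roots (root total 1),
// write the KMH1 histogram file.
// [[Rcpp::export]]
List cpp_finalize_histogram(std::string run_path, std::string out_path, int k,
                            double root_lo, double root_hi) {
  RunReader rr;
  rr.open(run_path);
  FILE* f = open_checked(out_path, "wb");
  HistHeader h{};
  h.k = (uint32_t)k;
  h.root_lo = (uint64_t)root_lo;
  h.root_hi = (uint64_t)root_hi;
  write_hist_header(f, h);  // placeholder counts, rewritten below
  std::vector<Rec> grp;
  uint64_t prev_key = 0;
  bool any = false;
  auto flush_group = [&](void) {
    if (grp.empty()) return;
    uint64_t total = 0;
    for (const Rec& r : grp) total += (uint64_t)r.n + (uint64_t)r.t;
    if (total <= 1) {
      h.singleton_roots++;
    } else {
      for (const Rec& r : grp) {
        std::fwrite(&r.key, 8, 1, f);
        std::fwrite(&r.n, 2, 1, f);
        std::fwrite(&r.t, 2, 1, f);
        if (r.n == 65535 || r.t == 65535) h.saturated = 1;
        h.n_entries++;
      }
      h.n_roots++;
    }
    grp.clear();
  };
  while (rr.has) {
    Rec r = rr.cur;
    if (any && r.key <= prev_key)
      stop("corrupt run '%s': keys not strictly increasing", run_path);
    prev_key = r.key;
    any = true;
    if (!grp.empty() && (grp.back().key >> 5) != (r.key >> 5)) flush_group();
    grp.push_back(r);
    rr.advance();
  }
  flush_group();
  rr.close();
  std::fseek(f, 0, SEEK_SET);
  write_hist_header(f, h);
  std::fclose(f);
  return List::create(_["n_entries"] = (double)h.n_entries,
                      _["n_roots"] = (double)h.n_roots,
                      _["singleton_roots"] = (double)h.singleton_roots,
                      _["saturated"] = (bool)h.saturated);
}

// [[Rcpp::export]]
List cpp_histogram_info(std::string path) {
  FILE* f = open_checked(path, "rb");
  HistHeader h = read_hist_header(f, path);
  std::fclose(f);
  return List::create(
      _["k"] = (int)h.k, _["root_lo"] = (double)h.root_lo,
      _["root_hi"] = (double)h.root_hi, _["n_entries"] = (double)h.n_entries,
      _["n_roots"] = (double)h.n_roots,
      _["singleton_roots"] = (double)h.singleton_roots,
      _["saturated"] = (bool)h.saturated);
}

// [[Rcpp::export]]
List cpp_read_histogram(std::string path) {
  FILE* f = open_checked(path, "rb");
  HistHeader h = read_hist_header(f, path);
  size_t m = (size_t)h.n_entries;
  CharacterVector kmer(m), root(m);
  NumericVector rootc(m);
  IntegerVector vidx(m), n(m), t(m);
  int ks = (int)h.k - 2;
  for (size_t i = 0; i < m; ++i) {
    Rec r;
    if (std::fread(&r.key, 8, 1, f) != 1 || std::fread(&r.n, 2, 1, f) != 1 ||
        std::fread(&r.t, 2, 1, f) != 1)
      stop("truncated histogram '%s'", path);
    uint64_t rt = r.key >> 5;
    int v = (int)(r.key & 31ULL);
    uint64_t stem = (v & 16) ? revcomp_code(rt, ks) : rt;
    std::string km;
    km.push_back(code_base((v >> 2) & 3));
    km += decode_code(stem, ks);
    km.push_back(code_base(v & 3));
    kmer[i] = km;
    root[i] = decode_code(rt, ks);
    rootc[i] = (double)rt;
    vidx[i] = v;
    n[i] = r.n;
    t[i] = r.t;
  }
  std::fclose(f);
  return List::create(_["kmer"] = kmer, _["root"] = root,
                      _["root_code"] = rootc, _["variant"] = vidx, _["n"] = n,
                      _["t"] = t);
}

// ---------------------------------------------------------------- kv store

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline void bloom_set(std::vector<uint8_t>& bits, uint64_t m_bits,
                             uint64_t root, int n_hashes, uint64_t s1,
                             uint64_t s2) {
  uint64_t h1 = splitmix64(root ^ s1);
  uint64_t h2 = splitmix64(root ^ s2) | 1ULL;
  for (int i = 0; i < n_hashes; ++i) {
    uint64_t b = (h1 + (uint64_t)i * h2) % m_bits;
    bits[b >> 3] |= (uint8_t)(1u << (b & 7));
  }
}

static inline bool bloom_get(const uint8_t* bits, uint64_t m_bits, uint64_t root,
                             int n_hashes, uint64_t s1, uint64_t s2) {
  uint64_t h1 = splitmix64(root ^ s1);
  uint64_t h2 = splitmix64(root ^ s2) | 1ULL;
  for (int i = 0; i < n_hashes; ++i) {
    uint64_t b = (h1 + (uint64_t)i * h2) % m_bits;
    if (!(bits[b >> 3] & (1u << (b & 7)))) return false;
  }
  return true;
}

struct StoreHeader {
  uint32_t k, chunk_bytes;
  uint64_t n_records, n_data_chunks, n_bloom_bytes, m_bits;
  uint32_t bits_per_key, n_hashes;
  uint64_t seed1, seed2, min_root, max_root;
};

static void write_store_header(FILE* f, const StoreHeader& h) {
  std::fwrite(STORE_MAGIC, 1, 4, f);
  std::fwrite(&h.k, 4, 1, f);
  std::fwrite(&h.chunk_bytes, 4, 1, f);
  std::fwrite(&h.n_records, 8, 1, f);
  std::fwrite(&h.n_data_chunks, 8, 1, f);
  std::fwrite(&h.n_bloom_bytes, 8, 1, f);
  std::fwrite(&h.m_bits, 8, 1, f);
  std::fwrite(&h.bits_per_key, 4, 1, f);
  std::fwrite(&h.n_hashes, 4, 1, f);
  std::fwrite(&h.seed1, 8, 1, f);
  std::fwrite(&h.seed2, 8, 1, f);
  std::fwrite(&h.min_root, 8, 1, f);
  std::fwrite(&h.max_root, 8, 1, f);
}

static StoreHeader read_store_header(FILE* f, const std::string& path) {
  char magic[4];
  StoreHeader h{};
  if (std::fread(magic, 1, 4, f) != 4 || std::memcmp(magic, STORE_MAGIC, 4) != 0)
    stop("'%s' is not a key-value store file", path);
  bool ok = std::fread(&h.k, 4, 1, f) == 1 &&
            std::fread(&h.chunk_bytes, 4, 1, f) == 1 &&
            std::fread(&h.n_records, 8, 1, f) == 1 &&
            std::fread(&h.n_data_chunks, 8, 1, f) == 1 &&
            std::fread(&h.n_bloom_bytes, 8, 1, f) == 1 &&
            std::fread(&h.m_bits, 8, 1, f) == 1 &&
            std::fread(&h.bits_per_key, 4, 1, f) == 1 &&
            std::fread(&h.n_hashes, 4, 1, f) == 1 &&
            std::fread(&h.seed1, 8, 1, f) == 1 &&
            std::fread(&h.seed2, 8, 1, f) == 1 &&
            std::fread(&h.min_root, 8, 1, f) == 1 &&
            std::fread(&h.max_root, 8, 1, f) == 1;
  if (!ok) stop("truncated store header in '%s'", path);
  return h;
}

// Fold consecutive histogram entries of each root into one 136-byte record,
// pack records into fixed-size chunks, build the Bloom filter, write
// header | bloom | data in one file.
// [[Rcpp::export]]
List cpp_build_store(std::string hist_path, std::string store_path,
                     int chunk_bytes, int bits_per_key, int n_hashes,
                     double seed1, double seed2) {
  FILE* hf = open_checked(hist_path, "rb");
  HistHeader hh = read_hist_header(hf, hist_path);
  if (chunk_bytes < ROOT_REC_BYTES) stop("chunk_bytes below one record");
  int cap = chunk_bytes / ROOT_REC_BYTES;
  StoreHeader sh{};
  sh.k = hh.k;
  sh.chunk_bytes = (uint32_t)chunk_bytes;
  sh.n_records = hh.n_roots;
  sh.n_data_chunks = (hh.n_roots + cap - 1) / cap;
  sh.bits_per_key = (uint32_t)bits_per_key;
  sh.n_hashes = (uint32_t)n_hashes;
  sh.seed1 = (uint64_t)seed1;
  sh.seed2 = (uint64_t)seed2;
  sh.m_bits = std::max<uint64_t>(64, (uint64_t)bits_per_key * hh.n_roots);
  uint64_t bloom_raw = (sh.m_bits + 7) / 8;
  sh.n_bloom_bytes =
      ((bloom_raw + chunk_bytes - 1) / chunk_bytes) * (uint64_t)chunk_bytes;
  std::vector<uint8_t> bloom((size_t)bloom_raw, 0);

  FILE* f = open_checked(store_path, "wb");
  std::vector<uint8_t> zero((size_t)chunk_bytes, 0);
  std::fwrite(zero.data(), 1, chunk_bytes, f);  // header chunk placeholder
  for (uint64_t i = 0; i < sh.n_bloom_bytes / chunk_bytes; ++i)
    std::fwrite(zero.data(), 1, chunk_bytes, f);

  std::vector<uint8_t> chunk((size_t)chunk_bytes, 0);
  int in_chunk = 0;
  uint64_t cur_root = 0;
  uint16_t counters[64];
  bool have_root = false, first_root = true;
  auto flush_record = [&](void) {
    if (!have_root) return;
    uint8_t* p = chunk.data() + (size_t)in_chunk * ROOT_REC_BYTES;
    std::memcpy(p, &cur_root, 8);
    std::memcpy(p + 8, counters, 128);
    bloom_set(bloom, sh.m_bits, cur_root, n_hashes, sh.seed1, sh.seed2);
    if (first_root) { sh.min_root = cur_root; first_root = false; }
    sh.max_root = cur_root;
    if (++in_chunk == cap) {
      std::fwrite(chunk.data(), 1, chunk_bytes, f);
      std::fill(chunk.begin(), chunk.end(), 0);
      in_chunk = 0;
    }
    have_root = false;
  };
  uint64_t prev_key = 0;
  bool any = false;
  for (uint64_t i = 0; i < hh.n_entries; ++i) {
    Rec r;
    if (std::fread(&r.key, 8, 1, hf) != 1 || std::fread(&r.n, 2, 1, hf) != 1 ||
        std::fread(&r.t, 2, 1, hf) != 1)
      stop("truncated histogram '%s'", hist_path);
    if (any && r.key <= prev_key)
      stop("histogram '%s' is not sorted", hist_path);
    prev_key = r.key;
    any = true;
    uint64_t rt = r.key >> 5;
    int v = (int)(r.key & 31ULL);
    if (!have_root || rt != cur_root) {
      flush_record();
      cur_root = rt;
      std::memset(counters, 0, sizeof(counters));
      have_root = true;
    }
    counters[2 * v] = r.n;
    counters[2 * v + 1] = r.t;
  }
  flush_record();
  if (in_chunk > 0) std::fwrite(chunk.data(), 1, chunk_bytes, f);
  std::fclose(hf);
  std::fseek(f, 0, SEEK_SET);
  write_store_header(f, sh);
  std::fseek(f, chunk_bytes, SEEK_SET);
  std::fwrite(bloom.data(), 1, (size_t)bloom_raw, f);
  std::fclose(f);
  return List::create(
      _["n_records"] = (double)sh.n_records,
      _["n_data_chunks"] = (double)sh.n_data_chunks,
      _["min_root"] = (double)sh.min_root, _["max_root"] = (double)sh.max_root,
      _["m_bits"] = (double)sh.m_bits,
      _["n_bloom_bytes"] = (double)sh.n_bloom_bytes);
}

// [[Rcpp::export]]
List cpp_open_store(std::string path) {
  FILE* f = open_checked(path, "rb");
  StoreHeader h = read_store_header(f, path);
  RawVector bloom((R_xlen_t)((h.m_bits + 7) / 8));
  std::fseek(f, h.chunk_bytes, SEEK_SET);
  if (bloom.size() > 0 &&
      std::fread(RAW(bloom), 1, bloom.size(), f) != (size_t)bloom.size())
    stop("truncated bloom region in '%s'", path);
  NumericVector first_keys((R_xlen_t)h.n_data_chunks);
  uint64_t data_off = (uint64_t)h.chunk_bytes + h.n_bloom_bytes;
  for (uint64_t c = 0; c < h.n_data_chunks; ++c) {
    uint64_t root;
#ifdef _WIN32
    std::fseek(f, (long)(data_off + c * h.chunk_bytes), SEEK_SET);
#else
    fseeko(f, (off_t)(data_off + c * h.chunk_bytes), SEEK_SET);
#endif
    if (std::fread(&root, 8, 1, f) != 1) stop("truncated store '%s'", path);
    first_keys[(R_xlen_t)c] = (double)root;
  }
  std::fclose(f);
  return List::create(
      _["k"] = (int)h.k, _["chunk_bytes"] = (int)h.chunk_bytes,
      _["n_records"] = (double)h.n_records,
      _["n_data_chunks"] = (double)h.n_data_chunks,
      _["m_bits"] = (double)h.m_bits,
      _["bits_per_key"] = (int)h.bits_per_key, _["n_hashes"] = (int)h.n_hashes,
      _["seed1"] = (double)h.seed1, _["seed2"] = (double)h.seed2,
      _["min_root"] = (double)h.min_root, _["max_root"] = (double)h.max_root,
      _["n_bloom_bytes"] = (double)h.n_bloom_bytes,
      _["first_keys"] = first_keys, _["bloom"] = bloom);
}

// [[Rcpp::export]]
LogicalVector cpp_bloom_maybe(RawVector bloom, NumericVector roots,
                              double m_bits, int n_hashes, double seed1,
                              double seed2) {
  LogicalVector out(roots.size());
  const uint8_t* bits = RAW(bloom);
  for (R_xlen_t i = 0; i < roots.size(); ++i)
    out[i] = bloom_get(bits, (uint64_t)m_bits, (uint64_t)roots[i], n_hashes,
                       (uint64_t)seed1, (uint64_t)seed2);
  return out;
}

// One chunk read per probe (chunks are re-read for repeated ids on purpose:
// the one-storage-read-per-look-up contract is per look-up, not per chunk).
// [[Rcpp::export]]
List cpp_read_store_records(std::string path, IntegerVector chunk_ids,
                            NumericVector roots) {
  FILE* f = open_checked(path, "rb");
  StoreHeader h = read_store_header(f, path);
  int cap = h.chunk_bytes / ROOT_REC_BYTES;
  uint64_t data_off = (uint64_t)h.chunk_bytes + h.n_bloom_bytes;
  R_xlen_t m = roots.size();
  LogicalVector found(m);
  IntegerMatrix counters(m, 64);
  std::vector<uint8_t> chunk((size_t)h.chunk_bytes);
  double reads = 0;
  for (R_xlen_t i = 0; i < m; ++i) {
    int c = chunk_ids[i];
    if (c < 0 || (uint64_t)c >= h.n_data_chunks) { found[i] = false; continue; }
#ifdef _WIN32
    std::fseek(f, (long)(data_off + (uint64_t)c * h.chunk_bytes), SEEK_SET);
#else
    fseeko(f, (off_t)(data_off + (uint64_t)c * h.chunk_bytes), SEEK_SET);
#endif
    if (std::fread(chunk.data(), 1, h.chunk_bytes, f) != h.chunk_bytes)
      stop("truncated store '%s'", path);
    reads += 1;
    int nrec = (int)std::min<uint64_t>((uint64_t)cap,
                                       h.n_records - (uint64_t)c * cap);
    uint64_t want = (uint64_t)roots[i];
    int lo = 0, hi = nrec - 1, hit = -1;
    while (lo <= hi) {
      int mid = (lo + hi) / 2;
      uint64_t root;
      std::memcpy(&root, chunk.data() + (size_t)mid * ROOT_REC_BYTES, 8);
      if (root == want) { hit = mid; break; }
      if (root < want) lo = mid + 1; else hi = mid - 1;
    }
    if (hit >= 0) {
      found[i] = true;
      const uint8_t* p = chunk.data() + (size_t)hit * ROOT_REC_BYTES + 8;
      for (int j = 0; j < 64; ++j) {
        uint16_t v;
        std::memcpy(&v, p + 2 * j, 2);
        counters(i, j) = (int)v;
      }
    } else {
      found[i] = false;
    }
  }
  std::fclose(f);
  return List::create(_["found"] = found, _["counters"] = counters,
                      _["chunk_reads"] = reads);
}

// [[Rcpp::export]]
NumericVector cpp_store_all_roots(std::string path) {
  FILE* f = open_checked(path, "rb");
  StoreHeader h = read_store_header(f, path);
  int cap = h.chunk_bytes / ROOT_REC_BYTES;
  uint64_t data_off = (uint64_t)h.chunk_bytes + h.n_bloom_bytes;
  NumericVector out((R_xlen_t)h.n_records);
  std::vector<uint8_t> chunk((size_t)h.chunk_bytes);
  R_xlen_t w = 0;
  for (uint64_t c = 0; c < h.n_data_chunks; ++c) {
#ifdef _WIN32
    std::fseek(f, (long)(data_off + c * h.chunk_bytes), SEEK_SET);
#else
    fseeko(f, (off_t)(data_off + c * h.chunk_bytes), SEEK_SET);
#endif
    if (std::fread(chunk.data(), 1, h.chunk_bytes, f) != h.chunk_bytes)
      stop("truncated store '%s'", path);
    int nrec = (int)std::min<uint64_t>((uint64_t)cap, h.n_records - c * cap);
    for (int j = 0; j < nrec; ++j) {
      uint64_t root;
      std::memcpy(&root, chunk.data() + (size_t)j * ROOT_REC_BYTES, 8);
      out[w++] = (double)root;
    }
  }
  std::fclose(f);
  return out;
}

// Multi-level implicit-index descent for a batch of probes; bottom level is
// first_keys, each level above keeps every F-th key. Returns 0-based chunk
// ids (clamped to chunk 0 below the first key).
// [[Rcpp::export]]
IntegerVector cpp_locate_chunks(NumericVector roots, NumericVector first_keys,
                                int fanout) {
  R_xlen_t nfk = first_keys.size();
  std::vector<std::vector<uint64_t>> levels;
  {
    std::vector<uint64_t> base(nfk);
    for (R_xlen_t i = 0; i < nfk; ++i) base[i] = (uint64_t)first_keys[i];
    levels.push_back(base);
    while (levels.back().size() > (size_t)fanout) {
      const std::vector<uint64_t>& below = levels.back();
      std::vector<uint64_t> up;
      for (size_t i = 0; i < below.size(); i += fanout) up.push_back(below[i]);
      levels.push_back(up);
    }
  }
  IntegerVector out(roots.size());
  for (R_xlen_t p = 0; p < roots.size(); ++p) {
    if (nfk == 0) { out[p] = NA_INTEGER; continue; }
    uint64_t key = (uint64_t)roots[p];
    size_t idx = 0;
    for (size_t lv = levels.size(); lv-- > 0;) {
      const std::vector<uint64_t>& arr = levels[lv];
      size_t beg = idx * (size_t)fanout;
      size_t end = std::min(arr.size(), beg + (size_t)fanout);
      size_t child = beg;
      for (size_t i = beg; i < end; ++i) {
        if (arr[i] <= key) child = i; else break;
      }
      idx = child;
    }
    out[p] = (int)idx;
  }
  return out;
}
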
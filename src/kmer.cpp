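#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <map>
#include <cstdint>

using namespace Rcpp;

// 2-bit encoding of A/C/G/T; -1 for anything else (N etc.).
static inline int base2bit(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    out[s.size() - 1 - i] = comp_base(s[i]);
  return out;
}

// Enumerate valid k-mers of s as 64-bit codes; positions holding any non-ACGT
// base are skipped. Returns pairs (offset, code).
static void enumerate_kmers(const std::string &s, int k,
                            std::vector<std::pair<int, uint64_t> > &out) {
  int n = (int)s.size();
  if (n < k) return;
  uint64_t code = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;  // number of consecutive valid bases ending here
  for (int i = 0; i < n; ++i) {
    int b = base2bit(s[i]);
    if (b < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)b) & mask;
    if (++run >= k) out.push_back(std::make_pair(i - k + 1, code));
  }
}

typedef std::unordered_map<uint64_t, std::vector<int> > KmerMap;

// Build kmer -> sorted unique transcript index list (0-based).
static void build_map(const std::vector<std::string> &seqs, int k, KmerMap &map) {
  std::vector<std::pair<int, uint64_t> > kmers;
  for (int t = 0; t < (int)seqs.size(); ++t) {
    kmers.clear();
    enumerate_kmers(seqs[t], k, kmers);
    for (size_t i = 0; i < kmers.size(); ++i) {
      std::vector<int> &v = map[kmers[i].second];
      if (v.empty() || v.back() != t) v.push_back(t);
    }
  }
}

static std::string decode_kmer(uint64_t code, int k) {
  static const char *b = "ACGT";
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) { s[i] = b[code & 3]; code >>= 2; }
  return s;
}

// [[Rcpp::export]]
DataFrame cpp_kmer_transcript_map(CharacterVector tx_seqs, int k) {
  std::vector<std::string> seqs(tx_seqs.size());
  for (int i = 0; i < tx_seqs.size(); ++i) seqs[i] = as<std::string>(tx_seqs[i]);
  KmerMap map;
  build_map(seqs, k, map);
  std::vector<uint64_t> keys;
  keys.reserve(map.size());
  for (KmerMap::const_iterator it = map.begin(); it != map.end(); ++it)
    keys.push_back(it->first);
  std::sort(keys.begin(), keys.end());
  CharacterVector kmer(keys.size()), txs(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    kmer[i] = decode_kmer(keys[i], k);
    const std::vector<int> &v = map[keys[i]];
    std::string lab;
    for (size_t j = 0; j < v.size(); ++j) {
      if (j) lab += ",";
      lab += std::to_string(v[j] + 1);  // 1-based for R
    }
    txs[i] = lab;
  }
  return DataFrame::create(_["kmer"] = kmer, _["transcripts"] = txs,
                           _["stringsAsFactors"] = false);
}

// Assign reads to equivalence classes.
// A read is compatible with transcript t when >= compat_fraction of its k-mer
// positions (invalid positions included in the denominator) occur in t; both
// orientations are tried and the one with the larger best-transcript hit count
// is kept (forward wins ties).
// [[Rcpp::export]]
List cpp_assign_reads(CharacterVector tx_seqs, CharacterVector reads, int k,
                      double compat_fraction) {
  std::vector<std::string> seqs(tx_seqs.size());
  for (int i = 0; i < tx_seqs.size(); ++i) seqs[i] = as<std::string>(tx_seqs[i]);
  KmerMap map;
  build_map(seqs, k, map);

  std::map<std::vector<int>, int> class_counts;
  int unassigned = 0;
  int n_reads = reads.size();
  std::vector<std::pair<int, uint64_t> > kmers;
  std::unordered_map<int, int> hits;

  for (int r = 0; r < n_reads; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    int n_pos = (int)fwd.size() - k + 1;
    if (n_pos < 1) { ++unassigned; continue; }
    std::vector<int> best_set;
    int best_top = -1;
    for (int ori = 0; ori < 2; ++ori) {
      std::string seq = ori ? revcomp(fwd) : fwd;
      kmers.clear();
      enumerate_kmers(seq, k, kmers);
      hits.clear();
      for (size_t i = 0; i < kmers.size(); ++i) {
        KmerMap::const_iterator it = map.find(kmers[i].second);
        if (it == map.end()) continue;
        for (size_t j = 0; j < it->second.size(); ++j) ++hits[it->second[j]];
      }
      int top = 0;
      for (std::unordered_map<int, int>::const_iterator it = hits.begin();
           it != hits.end(); ++it)
        if (it->second > top) top = it->second;
      if (top > best_top) {
        best_top = top;
        best_set.clear();
        double need = compat_fraction * n_pos - 1e-9;
        for (std::unordered_map<int, int>::const_iterator it = hits.begin();
             it != hits.end(); ++it)
          if ((double)it->second >= need) best_set.push_back(it->first);
        std::sort(best_set.begin(), best_set.end());
      }
    }
    if (best_set.empty()) ++unassigned;
    else ++class_counts[best_set];
  }

  int n_class = (int)class_counts.size();
  List classes(n_class);
  IntegerVector counts(n_class);
  int idx = 0;
  for (std::map<std::vector<int>, int>::const_iterator it = class_counts.begin();
       it != class_counts.end(); ++it, ++idx) {
    IntegerVector cl(it->first.size());
    for (size_t j = 0; j < it->first.size(); ++j) cl[j] = it->first[j] + 1;
    classes[idx] = cl;
    counts[idx] = it->second;
  }
  return List::create(_["classes"] = classes, _["counts"] = counts,
                      _["unassigned"] = unassigned, _["n_reads"] = n_reads);
}

// All approximate occurrences (Hamming distance <= max_mm) of `pattern` in
// each subject and its reverse complement. Offsets are 0-based on the
// plus-strand subject; strand "-" means the reverse complement of the pattern
// matched there.
// [[Rcpp::export]]
DataFrame cpp_hamming_hits(std::string pattern, CharacterVector subjects,
                           int max_mm) {
  int m = (int)pattern.size();
  std::string rc = revcomp(pattern);
  std::vector<int> out_seq, out_off, out_mm;
  std::vector<std::string> out_strand;
  for (int s = 0; s < subjects.size(); ++s) {
    std::string subj = as<std::string>(subjects[s]);
    int n = (int)subj.size();
    for (int o = 0; o + m <= n; ++o) {
      int mmF = 0, mmR = 0;
      bool okF = true, okR = true;
      for (int i = 0; i < m && (okF || okR); ++i) {
        char c = subj[o + i];
        if (okF && c != pattern[i] && ++mmF > max_mm) okF = false;
        if (okR && c != rc[i] && ++mmR > max_mm) okR = false;
      }
      if (okF) { out_seq.push_back(s + 1); out_off.push_back(o);
                 out_strand.push_back("+"); out_mm.push_back(mmF); }
      if (okR) { out_seq.push_back(s + 1); out_off.push_back(o);
                 out_strand.push_back("-"); out_mm.push_back(mmR); }
    }
  }
  return DataFrame::create(_["seq_index"] = wrap(out_seq),
                           _["offset"] = wrap(out_off),
                           _["strand"] = wrap(out_strand),
                           _["mismatches"] = wrap(out_mm),
                           _["stringsAsFactors"] = false);
}

// Count reads spanning a junction probe. The junction sits between probe
// positions flank-1 and flank (0-based). A read counts if some ungapped
// placement of the probe against the read (either read orientation) covers
// >= min_overlap read bases on each side of the junction with <= max_mm
// mismatches over the overlapping region. Each read counts at most once.
// [[Rcpp::export]]
List cpp_count_junction_reads(CharacterVector reads, std::string probe,
                              int flank, int min_overlap, int max_mm) {
  int m = (int)probe.size();
  std::vector<int> hit_read, hit_off, hit_mm;
  std::vector<std::string> hit_strand;
  int count = 0;
  for (int r = 0; r < reads.size(); ++r) {
    std::string fwd = as<std::string>(reads[r]);
    bool counted = false;
    for (int ori = 0; ori < 2 && !counted; ++ori) {
      std::string read = ori ? revcomp(fwd) : fwd;
      int n = (int)read.size();
      // o = read position aligned with probe position 0 (may be negative)
      for (int o = -(m - 1); o < n && !counted; ++o) {
        int lo = std::max(0, -o), hi = std::min(m, n - o);
        if (hi <= lo) continue;
        int donor = std::max(0, std::min(hi, flank) - lo);
        int acceptor = std::max(0, hi - std::max(lo, flank));
        if (donor < min_overlap || acceptor < min_overlap) continue;
        int mm = 0;
        bool ok = true;
        for (int p = lo; p < hi && ok; ++p)
          if (read[o + p] != probe[p] && ++mm > max_mm) ok = false;
        if (ok) {
          counted = true;
          hit_read.push_back(r + 1);
          hit_off.push_back(o);
          hit_strand.push_back(ori ? "-" : "+");
          hit_mm.push_back(mm);
        }
      }
    }
    if (counted) ++count;
  }
  DataFrame hits = DataFrame::create(_["read_index"] = wrap(hit_read),
                                     _["offset"] = wrap(hit_off),
                                     _["strand"] = wrap(hit_strand),
                                     _["mismatches"] = wrap(hit_mm),
                                     _["stringsAsFactors"] = false);
  return List::create(_["count"] = count, _["hits"] = hits);
}

// For each read, report which of the supplied k-mer sets it hits (any k-mer
// of the read or its reverse complement). Returns an n_reads x n_sets
// logical matrix.
// [[Rcpp::export]]
LogicalMatrix cpp_kmer_set_hits(CharacterVector reads, List kmer_sets, int k) {
  int ns = kmer_sets.size();
  std::vector<std::unordered_map<uint64_t, char> > sets(ns);
  for (int s = 0; s < ns; ++s) {
    CharacterVector kms = kmer_sets[s];
    std::vector<std::pair<int, uint64_t> > enc;
    for (int i = 0; i < kms.size(); ++i) {
      std::string km = as<std::string>(kms[i]);
      if ((int)km.size() != k) stop("k-mer length mismatch");
      enc.clear();
      enumerate_kmers(km, k, enc);
      if (enc.size() == 1) sets[s][enc[0].second] = 1;
    }
  }
  LogicalMatrix out(reads.size(), ns);
  std::vector<std::pair<int, uint64_t> > kmers;
  for (int r = 0; r < reads.size(); ++r) {
    std::string fwd = as<std::string>(reads[r]);
    std::string rc = revcomp(fwd);
    kmers.clear();
    enumerate_kmers(fwd, k, kmers);
    enumerate_kmers(rc, k, kmers);
    for (int s = 0; s < ns; ++s) {
      bool hit = false;
      for (size_t i = 0; i < kmers.size() && !hit; ++i)
        if (sets[s].count(kmers[i].second)) hit = true;
      out(r, s) = hit;
    }
  }
  return out;
}
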
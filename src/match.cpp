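#include <Rcpp.h>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

// Full-length ungapped matching of short tags against a reference set within
// a Hamming-distance bound k. Seed-and-extend: each tag is cut into k+1
// contiguous blocks; by pigeonhole a hit with <= k mismatches carries at
// least one mismatch-free block, so its leading q-gram occurs exactly in the
// reference. Candidate offsets come from a q-gram position index and are
// verified by a full Hamming count, which makes the output identical to an
// exhaustive scan (the contract the tests enforce with a brute-force oracle).

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    case 'a': return 't';
    case 'c': return 'g';
    case 'g': return 'c';
    case 't': return 'a';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

struct SeedIndex {
  int q;
  // q-gram -> packed (ref << 32 | pos)
  std::unordered_map<std::string, std::vector<uint64_t> > table;
};

static void build_index(const std::vector<std::string>& refs, int q, SeedIndex& idx) {
  idx.q = q;
  for (size_t r = 0; r < refs.size(); ++r) {
    const std::string& s = refs[r];
    if ((int)s.size() < q) continue;
    for (size_t p = 0; p + q <= s.size(); ++p) {
      idx.table[s.substr(p, q)].push_back(((uint64_t)r << 32) | (uint64_t)p);
    }
  }
}

static inline int hamming_leq(const std::string& a, const std::string& b,
                              size_t off, int k) {
  // mismatches of a vs b[off, off + |a|), early exit above k; -1 if > k
  int mm = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    if (a[i] != b[off + i]) {
      if (++mm > k) return -1;
    }
  }
  return mm;
}

struct HitSink {
  std::vector<int> tag, ref, offset, mism;
  std::vector<std::string> strand;
};

static void match_one(const std::string& s, int tag_i, char strand,
                      const std::vector<std::string>& refs,
                      const SeedIndex& idx, int k, HitSink& out) {
  const int L = (int)s.size();
  const int nb = k + 1;
  std::unordered_set<uint64_t> seen;
  if (idx.q >= 1 && L >= nb * idx.q) {
    for (int b = 0; b < nb; ++b) {
      int start = (int)(((long long)b * L) / nb);
      auto it = idx.table.find(s.substr(start, idx.q));
      if (it == idx.table.end()) continue;
      for (uint64_t packed : it->second) {
        int r = (int)(packed >> 32);
        long long pos = (long long)(packed & 0xffffffffULL);
        long long off = pos - start;
        if (off < 0 || off + L > (long long)refs[r].size()) continue;
        uint64_t key = ((uint64_t)r << 40) | (uint64_t)off;
        if (!seen.insert(key).second) continue;
        int mm = hamming_leq(s, refs[r], (size_t)off, k);
        if (mm >= 0) {
          out.tag.push_back(tag_i + 1);
          out.ref.push_back(r + 1);
          out.offset.push_back((int)off);
          out.strand.push_back(std::string(1, strand));
          out.mism.push_back(mm);
        }
      }
    }
  } else {
    // tags too short for the pigeonhole blocks: exhaustive scan
    for (size_t r = 0; r < refs.size(); ++r) {
      if ((int)refs[r].size() < L) continue;
      for (size_t off = 0; off + L <= refs[r].size(); ++off) {
        int mm = hamming_leq(s, refs[r], off, k);
        if (mm >= 0) {
          out.tag.push_back(tag_i + 1);
          out.ref.push_back((int)r + 1);
          out.offset.push_back((int)off);
          out.strand.push_back(std::string(1, strand));
          out.mism.push_back(mm);
        }
      }
    }
  }
}

// [[Rcpp::export]]
List match_tags_cpp(CharacterVector tags, CharacterVector refs, int k,
                    bool search_minus) {
  std::vector<std::string> rv(refs.size());
  for (int i = 0; i < refs.size(); ++i) rv[i] = as<std::string>(refs[i]);

  int min_len = INT_MAX;
  for (int i = 0; i < tags.size(); ++i) {
    int L = LENGTH(STRING_ELT(tags, i));
    if (L < min_len) min_len = L;
  }
  if (tags.size() == 0) min_len = 0;
  int q = min_len / (k + 1);
  if (q > 16) q = 16;

  SeedIndex idx;
  if (q >= 1) build_index(rv, q, idx); else idx.q = 0;

  HitSink out;
  for (int i = 0; i < tags.size(); ++i) {
    std::string s = as<std::string>(tags[i]);
    match_one(s, i, '+', rv, idx, k, out);
    if (search_minus) match_one(revcomp(s), i, '-', rv, idx, k, out);
  }
  return List::create(_["tag"] = wrap(out.tag), _["ref"] = wrap(out.ref),
                      _["offset"] = wrap(out.offset),
                      _["strand"] = wrap(out.strand),
                      _["mismatches"] = wrap(out.mism));
}

// [[Rcpp::export]]
CharacterVector mutate_reads_cpp(CharacterVector reads, double rate) {
  // per-base substitution at `rate`, drawing from R's RNG so results are
  // reproducible under set.seed()
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  RNGScope scope;
  CharacterVector out(reads.size());
  for (int i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    for (size_t j = 0; j < s.size(); ++j) {
      if (unif_rand() < rate) {
        char c = bases[(int)(unif_rand() * 4) & 3];
        while (c == s[j]) c = bases[(int)(unif_rand() * 4) & 3];
        s[j] = c;
      }
    }
    out[i] = s;
  }
  return out;
}
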
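#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Base encoding: A/C/G/T (either case) -> 0..3, everything else -> -1.
static inline int baseCode(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Match counts for every candidate overlap between the 3' end of read 1
// and the 5' end of the reverse-complemented mate: out[o-1] = number of
// equal characters when the last o bases of `a` sit on the first o bases
// of `b`. Ambiguity characters never match (they compare by character).
// [[Rcpp::export]]
IntegerVector cpp_overlap_matches(std::string a, std::string b) {
  const int na = a.size(), nb = b.size();
  const int m = std::min(na, nb);
  IntegerVector out(m);
  for (int o = 1; o <= m; ++o) {
    int cnt = 0;
    const char* pa = a.data() + (na - o);
    for (int i = 0; i < o; ++i)
      if (pa[i] == b[i] && baseCode(pa[i]) >= 0) ++cnt;
    out[o - 1] = cnt;
  }
  return out;
}

// Spaced-seed reference mapping.
//
// The index holds, for every reference offset admitting a full spaced
// 20-mer, four 5-position blocks of that spaced 20-mer. A read seed with
// at most (20 - prelimMin) mismatches must match at least one block
// exactly (pigeonhole over 4 blocks of 5), so block lookups enumerate
// every candidate seed; candidates are then verified at all 20 spaced
// positions (preliminary >= prelimMin matches) and confirmed against the
// reference over up to `confirmWindow` aligned bases, requiring matches
// strictly greater than confirmProp * window.
//
// Returns per read: locus (1-based; 0 = unmapped, -1 = ambiguous tie
// between loci), pos (0-based reference position of the read start, may
// be negative), score (confirmed match count).
// [[Rcpp::export]]
List cpp_map_reads(CharacterVector reads, CharacterVector refs,
                   IntegerVector pattern, int prelimMin,
                   double confirmProp, int confirmWindow) {
  const int k = pattern.size();
  const int span = pattern[k - 1] + 1;
  const int nBlocks = 4;
  const int blockLen = k / nBlocks; // 5 for k = 20
  const int maxMismatch = k - prelimMin;

  // encode references
  const int nr = refs.size();
  std::vector<std::vector<int8_t>> refCode(nr);
  for (int r = 0; r < nr; ++r) {
    std::string s = as<std::string>(refs[r]);
    refCode[r].resize(s.size());
    for (size_t i = 0; i < s.size(); ++i) refCode[r][i] = baseCode(s[i]);
  }

  // block index: key = (block << 10) | 2-bit-packed 5 bases
  std::vector<std::vector<int64_t>> table(nBlocks << 10);
  // packed spaced words per reference offset, for O(1) seed verification:
  // refWord[r][2*off] holds the 20 spaced codes in 2-bit lanes and
  // refWord[r][2*off + 1] flags invalid positions (bit 2j for position j)
  std::vector<std::vector<uint64_t>> refWord(nr);
  for (int r = 0; r < nr; ++r) {
    const std::vector<int8_t>& rc = refCode[r];
    const int len = rc.size();
    const int nOff = len - span + 1;
    if (nOff > 0) refWord[r].assign((size_t)2 * nOff, 0);
    for (int off = 0; off + span <= len; ++off) {
      uint64_t w = 0, bad = 0;
      for (int j = 0; j < k; ++j) {
        int code = rc[off + pattern[j]];
        if (code < 0) { bad |= (uint64_t)1 << (2 * j); code = 0; }
        w |= (uint64_t)code << (2 * j);
      }
      refWord[r][2 * off] = w;
      refWord[r][2 * off + 1] = bad;
      for (int b = 0; b < nBlocks; ++b) {
        int key = 0;
        bool ok = true;
        for (int j = 0; j < blockLen; ++j) {
          int code = rc[off + pattern[b * blockLen + j]];
          if (code < 0) { ok = false; break; }
          key = (key << 2) | code;
        }
        if (ok) table[(b << 10) | key].push_back(((int64_t)r << 32) | off);
      }
    }
  }

  const int n = reads.size();
  IntegerVector locus(n), pos(n), score(n);
  std::vector<int8_t> rdCode;

  int maxRefLen = 0, maxReadLen = 0;
  for (int r = 0; r < nr; ++r)
    maxRefLen = std::max(maxRefLen, (int)refCode[r].size());
  for (int i = 0; i < n; ++i)
    maxReadLen = std::max(maxReadLen, (int)LENGTH(STRING_ELT(reads, i)));

  // per-(reference, diagonal) confirmation state, reset lazily between
  // reads via the touched list: 0 = unseen, 1 = confirmed, 2 = rejected
  const int64_t stride = (int64_t)maxRefLen + maxReadLen + 1;
  std::vector<uint8_t> state((size_t)nr * stride, 0);
  std::vector<int> confVal((size_t)nr * stride, 0);
  std::vector<int64_t> touched;

  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(reads[i]);
    const int rl = s.size();
    rdCode.assign(rl, -1);
    for (int p = 0; p < rl; ++p) rdCode[p] = baseCode(s[p]);

    // per-locus best confirmed (score, diag)
    std::unordered_map<int, std::pair<int, int>> best;
    for (size_t t = 0; t < touched.size(); ++t) state[touched[t]] = 0;
    touched.clear();

    for (int off = 0; off + span <= rl; ++off) {
      // packed spaced word for this read offset, mirroring refWord
      uint64_t rw = 0, rbad = 0;
      for (int j = 0; j < k; ++j) {
        int code = rdCode[off + pattern[j]];
        if (code < 0) { rbad |= (uint64_t)1 << (2 * j); code = 0; }
        rw |= (uint64_t)code << (2 * j);
      }
      for (int b = 0; b < nBlocks; ++b) {
        int key = 0;
        bool ok = true;
        for (int j = 0; j < blockLen; ++j) {
          int code = rdCode[off + pattern[b * blockLen + j]];
          if (code < 0) { ok = false; break; }
          key = (key << 2) | code;
        }
        if (!ok) continue;
        const std::vector<int64_t>& post = table[(b << 10) | key];
        for (size_t t = 0; t < post.size(); ++t) {
          const int r = (int)(post[t] >> 32);
          const int roff = (int)(post[t] & 0xffffffff);
          const std::vector<int8_t>& rc = refCode[r];
          const int diag = roff - off; // read start on reference
          const int64_t ckey = (int64_t)r * stride + diag + maxReadLen;
          // a (reference, diagonal) pair whose confirmation was already
          // decided needs no further seed verification
          const uint8_t st = state[ckey];
          int conf;
          if (st == 1) {
            conf = confVal[ckey];
          } else if (st == 2) {
            continue;
          } else {
            // verify the seed at all spaced positions: XOR the packed
            // words, collapse each 2-bit lane to one difference bit, and
            // count mismatches (invalid positions always mismatch)
            const uint64_t x = refWord[r][2 * (size_t)roff] ^ rw;
            const uint64_t d = ((x | (x >> 1)) & 0x5555555555ULL)
              | refWord[r][2 * (size_t)roff + 1] | rbad;
            if (__builtin_popcountll(d) > maxMismatch) continue;
            const int startRead = diag < 0 ? -diag : 0;
            const int startRef = diag > 0 ? diag : 0;
            const int reflen = (int)rc.size();
            int ov = std::min(rl - startRead, reflen - startRef);
            conf = -1;
            if (ov > 0) {
              const int w = std::min(ov, confirmWindow);
              int cnt = 0;
              for (int j = 0; j < w; ++j) {
                int cr = rdCode[startRead + j];
                if (cr >= 0 && cr == rc[startRef + j]) ++cnt;
              }
              if ((double)cnt > confirmProp * w) conf = cnt;
            }
            state[ckey] = conf > 0 ? 1 : 2;
            confVal[ckey] = conf;
            touched.push_back(ckey);
          }
          if (conf > 0) {
            std::unordered_map<int, std::pair<int, int>>::iterator cur =
              best.find(r);
            if (cur == best.end() || conf > cur->second.first) {
              best[r] = std::make_pair(conf, diag);
            }
          }
        }
      }
    }

    if (best.empty()) {
      locus[i] = 0; pos[i] = NA_INTEGER; score[i] = 0;
    } else {
      int bestR = -1, bestScore = -1, bestDiag = 0;
      bool tie = false;
      for (std::unordered_map<int, std::pair<int, int>>::iterator it =
             best.begin(); it != best.end(); ++it) {
        if (it->second.first > bestScore) {
          bestScore = it->second.first;
          bestR = it->first;
          bestDiag = it->second.second;
          tie = false;
        } else if (it->second.first == bestScore) {
          tie = true;
        }
      }
      if (tie) {
        locus[i] = -1; pos[i] = NA_INTEGER; score[i] = bestScore;
      } else {
        locus[i] = bestR + 1; pos[i] = bestDiag; score[i] = bestScore;
      }
    }
  }

  return List::create(_["locus"] = locus, _["pos"] = pos,
                      _["score"] = score);
}
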
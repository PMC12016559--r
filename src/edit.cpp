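// Bit-vector edit-distance engine: Myers-1999 block computation over 64-bit
// words, with a whole-sequence mode and a banded "limit" mode (Ukkonen cutoff
// at a maximum distance k). Optional traceback stores the per-column block
// states and walks the stored bit deltas back to (0, 0).
#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
using namespace Rcpp;

typedef uint64_t Word;
static const int WORD_SIZE = 64;
static const long long ED_LARGE = (1LL << 40);

static inline int ed_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2;
    case 'T': return 3; case 'N': return 4;
    default: return -1;
  }
}

// One block update (Hyyro's block variant of Myers' algorithm).
// Pv/Mv are the plus/minus vertical delta words, Eq the match bits for the
// current text character, hin the horizontal delta entering the block's top
// row (-1, 0 or +1). Returns the horizontal delta leaving the bottom row.
static inline int calc_block(Word& Pv, Word& Mv, Word Eq, int hin) {
  Word hinNeg = (Word)(hin < 0 ? 1 : 0);
  Word Xv = Eq | Mv;
  Eq |= hinNeg;
  Word Xh = (((Eq & Pv) + Pv) ^ Pv) | Eq;
  Word Ph = Mv | ~(Xh | Pv);
  Word Mh = Pv & Xh;
  int hout = (int)((Ph >> (WORD_SIZE - 1)) & 1) - (int)((Mh >> (WORD_SIZE - 1)) & 1);
  Ph <<= 1;
  Mh <<= 1;
  Mh |= hinNeg;
  Ph |= (Word)(hin > 0 ? 1 : 0);
  Pv = Mh | ~(Xv | Ph);
  Mv = Ph & Xv;
  return hout;
}

struct ColStore {
  int bf, bl;                 // active block range for this column
  std::vector<Word> P, M;     // one entry per active block
  std::vector<long long> score;  // score at each active block's bottom row
};

// value D[i][j] (DP coordinates, i rows of the query 0..m) reconstructed from
// a stored column; rows outside the stored blocks report ED_LARGE (they are
// outside the Ukkonen band, hence provably > the limit).
static long long cell_value(const ColStore& col, long long i, long long j) {
  if (i == 0) return j;
  long long ib = (i - 1) / WORD_SIZE;  // block holding bit-row i-1
  if (ib < col.bf || ib > col.bl) return ED_LARGE;
  int idx = (int)(ib - col.bf);
  Word P = col.P[idx], M = col.M[idx];
  int bit = (int)((i - 1) % WORD_SIZE);
  // score stored at the block's bottom bit-row (WORD_SIZE-1); subtract the
  // vertical deltas of the rows below bit
  Word maskAbove = (bit == WORD_SIZE - 1) ? 0 : (~(Word)0) << (bit + 1);
  long long v = col.score[idx];
  v -= (long long)__builtin_popcountll(P & maskAbove);
  v += (long long)__builtin_popcountll(M & maskAbove);
  return v;
}

static std::string ed_rle(const std::vector<char>& ops_rev) {
  std::string out;
  size_t i = ops_rev.size();
  while (i > 0) {
    char op = ops_rev[i - 1];
    size_t run = 0;
    while (i > 0 && ops_rev[i - 1] == op) { ++run; --i; }
    out += std::to_string(run);
    out += op;
  }
  return out;
}

// limit < 0 means "whole" mode (no limit)
// [[Rcpp::export(name = ".edit_distance_cpp")]]
List edit_distance_cpp(std::string query, std::string ref,
                       double limit, bool want_cigar) {
  const long long m = (long long)query.size(), n = (long long)ref.size();
  if (m == 0 || n == 0) stop("sequences must be non-empty");
  std::vector<uint8_t> q(m), r(n);
  for (long long i = 0; i < m; ++i) {
    int c = ed_code(query[i]);
    if (c < 0) stop("invalid query base '%c'", query[i]);
    q[i] = (uint8_t)c;
  }
  for (long long j = 0; j < n; ++j) {
    int c = ed_code(ref[j]);
    if (c < 0) stop("invalid reference base '%c'", ref[j]);
    r[j] = (uint8_t)c;
  }
  const bool limited = limit >= 0;
  const long long k = limited ? (long long)limit : (m > n ? m : n);

  if (limited && (m - n > k || n - m > k)) {
    // no alignment can cost <= k when the length difference alone exceeds it
    return List::create(_["distance"] = R_NilValue, _["exceeded"] = true,
                        _["cells"] = 0.0, _["cigar"] = R_NilValue);
  }

  const long long nb = (m + WORD_SIZE - 1) / WORD_SIZE;
  // Peq: match masks per symbol per block; padding rows (>= m) match all
  // symbols so their deltas stay +1-free of the true rows below row m
  std::vector<Word> Peq(5 * nb, 0), pad(nb, 0);
  for (long long i = 0; i < m; ++i) {
    if (q[i] != 4)  // N never matches anything
      Peq[q[i] * nb + i / WORD_SIZE] |= (Word)1 << (i % WORD_SIZE);
  }
  for (long long i = m; i < nb * WORD_SIZE; ++i)
    pad[i / WORD_SIZE] |= (Word)1 << (i % WORD_SIZE);

  // diagonal window (Ukkonen): a cell (i, j) can lie on a path of cost <= k
  // only if i - j is within [lo_d, hi_d]
  const long long lo_d = limited ? std::max(-k, (m - n) - k) : -(n + 1);
  const long long hi_d = limited ? std::min(k, (m - n) + k) : (m + 1);

  std::vector<Word> P(nb), M(nb);
  std::vector<long long> score(nb);
  auto init_block = [&](long long b, long long sc) {
    P[b] = ~(Word)0; M[b] = 0; score[b] = sc;
  };

  // active block range at column j (1-based)
  auto range_at = [&](long long j, long long& bf, long long& bl) {
    long long lo_i = std::max((long long)1, j + lo_d);
    long long hi_i = std::min(m, j + hi_d);
    bf = (lo_i - 1) / WORD_SIZE;
    bl = (hi_i - 1) / WORD_SIZE;
  };

  long long bf_prev, bl_prev;
  range_at(1, bf_prev, bl_prev);
  for (long long b = bf_prev; b <= bl_prev; ++b)
    init_block(b, (b + 1) * WORD_SIZE);  // exact column-0 values: D[i][0] = i

  std::vector<ColStore> cols;
  if (want_cigar) {
    double blocks_per_col =
        std::min((double)nb, (double)(hi_d - lo_d) / WORD_SIZE + 2.0);
    if ((double)n * blocks_per_col * 24.0 > 6e8)
      stop("sequences too long for edit-distance traceback storage");
    cols.resize(n);
  }

  double cells = 0.0;
  long long bf = bf_prev, bl = bl_prev;
  for (long long j = 1; j <= n; ++j) {
    range_at(j, bf, bl);
    // activate new bottom blocks with worst-case (upper bound) states
    for (long long b = bl_prev + 1; b <= bl; ++b)
      init_block(b, score[b - 1] + WORD_SIZE);
    uint8_t c = r[j - 1];
    // +1 into the top: exact at the row-0 boundary (D[0][j] = j), an upper
    // bound at the band wall (out-of-band cells are provably > limit)
    int hin = 1;
    for (long long b = bf; b <= bl; ++b) {
      Word Eq = (c == 4 ? 0 : Peq[c * nb + b]) | pad[b];
      int hout = calc_block(P[b], M[b], Eq, hin);
      score[b] += hout;
      hin = hout;
    }
    cells += (double)(bl - bf + 1) * WORD_SIZE;
    if (want_cigar) {
      ColStore& cs = cols[j - 1];
      cs.bf = (int)bf; cs.bl = (int)bl;
      cs.P.assign(P.begin() + bf, P.begin() + bl + 1);
      cs.M.assign(M.begin() + bf, M.begin() + bl + 1);
      cs.score.assign(score.begin() + bf, score.begin() + bl + 1);
    }
    bf_prev = bf; bl_prev = bl;
  }

  // extract D[m][n] from the block holding row m
  long long lb = (m - 1) / WORD_SIZE;
  long long d;
  {
    int bit = (int)((m - 1) % WORD_SIZE);
    Word maskAbove = (bit == WORD_SIZE - 1) ? 0 : (~(Word)0) << (bit + 1);
    d = score[lb];
    d -= (long long)__builtin_popcountll(P[lb] & maskAbove);
    d += (long long)__builtin_popcountll(M[lb] & maskAbove);
  }

  if (limited && d > k) {
    return List::create(_["distance"] = R_NilValue, _["exceeded"] = true,
                        _["cells"] = cells, _["cigar"] = R_NilValue);
  }

  SEXP cigar = R_NilValue;
  if (want_cigar) {
    std::vector<char> ops;
    long long i = m, j = n, cur = d;
    while (i > 0 && j > 0) {
      long long dDiag = (j >= 2) ? cell_value(cols[j - 2], i - 1, j - 1)
                                 : (i - 1);
      long long dUp   = cell_value(cols[j - 1], i - 1, j);
      long long dLeft = (j >= 2) ? cell_value(cols[j - 2], i, j - 1) : i;
      bool isMatch = (q[i - 1] == r[j - 1] && q[i - 1] != 4);
      if (isMatch && dDiag == cur) {
        ops.push_back('='); --i; --j;
      } else if (dDiag == cur - 1) {
        ops.push_back('X'); --i; --j; --cur;
      } else if (dUp == cur - 1) {
        ops.push_back('I'); --i; --cur;
      } else if (dLeft == cur - 1) {
        ops.push_back('D'); --j; --cur;
      } else {
        stop("internal error: edit traceback lost the optimal path");
      }
    }
    while (i > 0) { ops.push_back('I'); --i; }
    while (j > 0) { ops.push_back('D'); --j; }
    cigar = Rf_mkString(ed_rle(ops).c_str());
  }

  return List::create(_["distance"] = (double)d, _["exceeded"] = false,
                      _["cells"] = cells, _["cigar"] = cigar);
}
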
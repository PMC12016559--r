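// Brute-force full-matrix references: Gotoh affine-gap global alignment,
// Smith-Waterman local alignment and Wagner-Fischer edit distance.
// These are written as plain row sweeps over absolute scores, with no code
// shared with the banded striped kernel, so the two paths fail independently.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
using namespace Rcpp;

typedef long long ll;
static const ll ORA_NEG = -(1LL << 40);

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2;
    case 'T': return 3; case 'N': return 4;
    default: return -1;
  }
}

static void encode_seq(const std::string& s, std::vector<uint8_t>& out,
                       const char* what) {
  out.resize(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int c = base_code(s[i]);
    if (c < 0) stop("invalid %s base '%c' (expected A/C/G/T/N)", what, s[i]);
    out[i] = (uint8_t)c;
  }
}

static inline ll sub_score(uint8_t a, uint8_t b, ll match, ll mismatch) {
  // N never matches, by convention
  return (a == b && a != 4) ? match : mismatch;
}

static std::string rle_cigar(const std::vector<char>& ops_rev) {
  // ops collected back-to-front
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

// Tie-breaking shared with the banded aligner: in H, diagonal >= E (reference
// gap, 'D') >= F (query gap, 'I'); in E and F, extension >= opening.
// [[Rcpp::export(name = ".gotoh_global_cpp")]]
List gotoh_global_cpp(std::string query, std::string ref,
                      int match, int mismatch, int gap_open_ext, int gap_ext,
                      bool want_cigar) {
  std::vector<uint8_t> q, r;
  encode_seq(query, q, "query");
  encode_seq(ref, r, "reference");
  const ll m = (ll)q.size(), n = (ll)r.size();
  if (m == 0 || n == 0) stop("sequences must be non-empty");
  const ll goe = gap_open_ext, ge = gap_ext;

  if (!want_cigar) {
    // rolling arrays over the reference (columns j): H and F of the previous
    // row; E (reference gap) is carried along the row, F (query gap) down the
    // column.
    std::vector<ll> H(n + 1), Fcol(n + 1, ORA_NEG);
    H[0] = 0;
    for (ll j = 1; j <= n; ++j) H[j] = goe + (j - 1) * ge;
    for (ll i = 1; i <= m; ++i) {
      ll Hdiag = H[0];
      H[0] = goe + (i - 1) * ge;
      ll Ecur = ORA_NEG, Hleft = H[0];
      for (ll j = 1; j <= n; ++j) {
        Ecur = std::max(Ecur + ge, Hleft + goe);          // E[i][j]
        Fcol[j] = std::max(Fcol[j] + ge, H[j] + goe);     // F[i][j]
        ll h = Hdiag + sub_score(q[i - 1], r[j - 1], match, mismatch);
        if (Ecur > h) h = Ecur;
        if (Fcol[j] > h) h = Fcol[j];
        Hdiag = H[j];
        H[j] = h;
        Hleft = h;
      }
    }
    return List::create(_["score"] = (double)H[n], _["cigar"] = R_NilValue);
  }

  // full pointer matrices (byte-packed) for traceback
  double cells = (double)(m + 1) * (double)(n + 1);
  if (cells > 4.5e8)
    stop("sequences too long for full-matrix traceback; use score-only mode");
  std::vector<ll> H(n + 1);
  std::vector<uint8_t> ptr((size_t)((m + 1) * (n + 1)), 0);
  // ptr bits: 0-1 H source (0 diag, 1 E, 2 F, 3 boundary-gap), 2 E-extend, 3 F-extend
  H[0] = 0;
  for (ll j = 1; j <= n; ++j) { H[j] = goe + (j - 1) * ge; ptr[j] = 1; }
  std::vector<ll> Fcol(n + 1, ORA_NEG);
  for (ll i = 1; i <= m; ++i) {
    ll Hdiag = H[0];
    H[0] = goe + (i - 1) * ge;
    ptr[(size_t)(i * (n + 1))] = 2;
    ll Ecur = ORA_NEG, Hleft = H[0];
    for (ll j = 1; j <= n; ++j) {
      uint8_t pb = 0;
      // E[i][j] = max(E[i][j-1] + ge, H[i][j-1] + goe), extend wins ties
      ll eExt = Ecur + ge, eOpen = Hleft + goe;
      Ecur = (eExt >= eOpen) ? eExt : eOpen;
      if (eExt >= eOpen) pb |= 4;
      // F[i][j] = max(F[i-1][j] + ge, H[i-1][j] + goe)
      ll fExt = Fcol[j] + ge, fOpen = H[j] + goe;
      Fcol[j] = (fExt >= fOpen) ? fExt : fOpen;
      if (fExt >= fOpen) pb |= 8;
      ll h = Hdiag + sub_score(q[i - 1], r[j - 1], match, mismatch);
      uint8_t dir = 0;
      if (Ecur > h) { h = Ecur; dir = 1; }
      if (Fcol[j] > h) { h = Fcol[j]; dir = 2; }
      pb |= dir;
      Hdiag = H[j];
      H[j] = h;
      Hleft = h;
      ptr[(size_t)(i * (n + 1) + j)] = pb;
    }
  }
  ll score = H[n];
  // traceback
  std::vector<char> ops;
  ll i = m, j = n;
  int state = 0;  // 0 = H, 1 = E, 2 = F
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i == 0) { while (j > 0) { ops.push_back('D'); --j; } break; }
      if (j == 0) { while (i > 0) { ops.push_back('I'); --i; } break; }
      uint8_t pb = ptr[(size_t)(i * (n + 1) + j)];
      uint8_t dir = pb & 3;
      if (dir == 0) {
        ops.push_back((q[i - 1] == r[j - 1] && q[i - 1] != 4) ? '=' : 'X');
        --i; --j;
      } else if (dir == 1) state = 1;
      else state = 2;
    } else if (state == 1) {
      uint8_t pb = ptr[(size_t)(i * (n + 1) + j)];
      ops.push_back('D');
      --j;
      if (!(pb & 4)) state = 0;
      if (j == 0) state = 0;
    } else {
      uint8_t pb = ptr[(size_t)(i * (n + 1) + j)];
      ops.push_back('I');
      --i;
      if (!(pb & 8)) state = 0;
      if (i == 0) state = 0;
    }
  }
  return List::create(_["score"] = (double)score, _["cigar"] = rle_cigar(ops));
}

// [[Rcpp::export(name = ".sw_local_cpp")]]
List sw_local_cpp(std::string query, std::string ref,
                  int match, int mismatch, int gap_open_ext, int gap_ext) {
  std::vector<uint8_t> q, r;
  encode_seq(query, q, "query");
  encode_seq(ref, r, "reference");
  const ll m = (ll)q.size(), n = (ll)r.size();
  if (m == 0 || n == 0) stop("sequences must be non-empty");
  const ll goe = gap_open_ext, ge = gap_ext;
  double cells = (double)(m + 1) * (double)(n + 1);
  if (cells > 4.5e8) stop("sequences too long for the local-alignment oracle");
  std::vector<ll> H(n + 1, 0), Fcol(n + 1, ORA_NEG);
  std::vector<uint8_t> ptr((size_t)((m + 1) * (n + 1)), 0);
  // ptr bits as in gotoh, plus dir==3 meaning "local start (H==0)"
  ll best = 0, bi = 0, bj = 0;
  for (ll j = 0; j <= n; ++j) ptr[j] = 3;
  for (ll i = 1; i <= m; ++i) {
    ll Hdiag = H[0];
    ll Ecur = ORA_NEG, Hleft = 0;
    ptr[(size_t)(i * (n + 1))] = 3;
    for (ll j = 1; j <= n; ++j) {
      uint8_t pb = 0;
      ll eExt = Ecur + ge, eOpen = Hleft + goe;
      Ecur = (eExt >= eOpen) ? eExt : eOpen;
      if (eExt >= eOpen) pb |= 4;
      ll fExt = Fcol[j] + ge, fOpen = H[j] + goe;
      Fcol[j] = (fExt >= fOpen) ? fExt : fOpen;
      if (fExt >= fOpen) pb |= 8;
      ll h = Hdiag + sub_score(q[i - 1], r[j - 1], match, mismatch);
      uint8_t dir = 0;
      if (Ecur > h) { h = Ecur; dir = 1; }
      if (Fcol[j] > h) { h = Fcol[j]; dir = 2; }
      if (h <= 0) { h = 0; dir = 3; }
      pb |= dir;
      Hdiag = H[j];
      H[j] = h;
      Hleft = h;
      ptr[(size_t)(i * (n + 1) + j)] = pb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  // traceback from the best cell until a 0 cell
  std::vector<char> ops;
  ll i = bi, j = bj;
  int state = 0;
  while (i > 0 && j > 0) {
    uint8_t pb = ptr[(size_t)(i * (n + 1) + j)];
    if (state == 0) {
      uint8_t dir = pb & 3;
      if (dir == 3) break;
      if (dir == 0) {
        ops.push_back((q[i - 1] == r[j - 1] && q[i - 1] != 4) ? '=' : 'X');
        --i; --j;
      } else if (dir == 1) state = 1;
      else state = 2;
    } else if (state == 1) {
      ops.push_back('D'); --j;
      if (!(pb & 4)) state = 0;
    } else {
      ops.push_back('I'); --i;
      if (!(pb & 8)) state = 0;
    }
  }
  return List::create(
    _["score"] = (double)best,
    _["cigar"] = best > 0 ? rle_cigar(ops) : std::string(""),
    _["query_range"] = IntegerVector::create((int)i, (int)bi),
    _["ref_range"] = IntegerVector::create((int)j, (int)bj));
}

// [[Rcpp::export(name = ".wagner_fischer_cpp")]]
double wagner_fischer_cpp(std::string query, std::string ref) {
  std::vector<uint8_t> q, r;
  encode_seq(query, q, "query");
  encode_seq(ref, r, "reference");
  const size_t m = q.size(), n = r.size();
  if (m == 0 || n == 0) stop("sequences must be non-empty");
  std::vector<int64_t> row(n + 1);
  for (size_t j = 0; j <= n; ++j) row[j] = (int64_t)j;
  for (size_t i = 1; i <= m; ++i) {
    int64_t diag = row[0];
    row[0] = (int64_t)i;
    for (size_t j = 1; j <= n; ++j) {
      int64_t sub = diag + ((q[i - 1] == r[j - 1] && q[i - 1] != 4) ? 0 : 1);
      int64_t del = row[j] + 1;      // from (i-1, j)
      int64_t ins = row[j - 1] + 1;  // from (i, j-1)
      diag = row[j];
      int64_t v = sub;
      if (del < v) v = del;
      if (ins < v) v = ins;
      row[j] = v;
    }
  }
  return (double)row[n];
}
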
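// Banded striped global aligner.
//
// Rows iterate over the reference; each row holds a band of W consecutive
// query offsets laid out across s_bar registers of p lanes (striped layout:
// register k, lane t holds in-band offset k + t*s_bar). Between rows the band
// shifts right by 0/1/2 cells, realized on the striped arrays as a register
// rotation plus a one-lane shift with sentinel fill on wrapped registers
// (the striped move). Row scores are evaluated in difference form -- only
// the vertical difference u and the gap difference e are carried between
// rows -- with a two-pass active F-loop: an initial pass seeds every
// segment's horizontal difference f with the sentinel, a single serial sweep
// over the segment-entry lanes corrects F penetration (a horizontal gap
// crossing whole segments), and a final pass recomputes the row from the
// corrected seeds. Exactly two passes per row, for every input.
//
// Boundary semantics are banded DP with NEG walls: cells outside the band or
// the matrix hold the sentinel NEG exactly, and u is stored as the raw
// difference of (sentinel-floored) absolute scores, so every difference
// telescopes exactly across walls -- no special cases in the recurrences.
// Differences use wide (64-bit) integers; lane semantics are emulated and
// width-agnostic. Absolute scores along one row are kept as scratch for the
// band-shift decision and boundary bookkeeping; no score matrix is stored.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
using namespace Rcpp;

typedef long long ll;
static const ll NEG = -(1LL << 40);   // wall sentinel: never wins a max
static const ll DEAD = -(1LL << 39);  // liveness threshold for absolute scores

static inline int bs_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2;
    case 'T': return 3; case 'N': return 4;
    default: return -1;
  }
}

static void bs_encode(const std::string& s, std::vector<uint8_t>& out,
                      const char* what) {
  out.resize(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int c = bs_code(s[i]);
    if (c < 0) stop("invalid %s base '%c' (expected A/C/G/T/N)", what, s[i]);
    out[i] = (uint8_t)c;
  }
}

static inline ll bs_sub(uint8_t a, uint8_t b, ll match, ll mismatch) {
  return (a == b && a != 4) ? match : mismatch;
}

static std::string bs_rle(const std::vector<char>& ops_rev) {
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

// striped position of in-band offset x: register x % sbar, lane x / sbar,
// registers stored contiguously (register-major)
static inline size_t spos(ll x, ll sbar, ll p) {
  return (size_t)((x % sbar) * p + x / sbar);
}

// striped move: normal-order left shift by s cells with sentinel fill,
// realized as register rotation plus a one-lane shift on wrapped registers
static void striped_move_vec(std::vector<ll>& v, std::vector<ll>& tmp,
                             ll s, ll sbar, ll p) {
  if (s == 0) return;
  tmp.resize(v.size());
  for (ll k = 0; k < sbar; ++k) {
    ll tot = k + s;
    ll src = tot % sbar;   // source register
    ll wrap = tot / sbar;  // lane-shift count (one lane per wrap)
    for (ll t = 0; t < p; ++t)
      tmp[(size_t)(k * p + t)] =
          (t + wrap < p) ? v[(size_t)(src * p + t + wrap)] : NEG;
  }
  v.swap(tmp);
}

// band-shift heuristic: compare summed absolute H over the first and last
// register (strided samples; rule 1 sums the leftmost/rightmost p contiguous
// cells instead). 0: favour a vertical gap; 1: diagonal; 2: horizontal gap.
static int decide_shift_ll(const std::vector<ll>& Hnorm, ll sbar, ll p, ll W,
                           int rule) {
  ll sumF = 0, sumL = 0;
  if (rule == 0) {
    for (ll t = 0; t < p; ++t) {
      sumF += Hnorm[(size_t)(t * sbar)];
      sumL += Hnorm[(size_t)(sbar - 1 + t * sbar)];
    }
  } else {
    for (ll t = 0; t < p; ++t) {
      sumF += Hnorm[(size_t)t];
      sumL += Hnorm[(size_t)(W - p + t)];
    }
  }
  if (sumF > sumL) return 0;
  if (sumF == sumL) return 1;
  return 2;
}

// [[Rcpp::export(name = ".align_banded_cpp")]]
List align_banded_cpp(std::string query, std::string ref,
                      int match, int mismatch, int gap_open_ext, int gap_ext,
                      int band_width, int lanes, bool want_cigar,
                      int shift_rule) {
  std::vector<uint8_t> q, r;
  bs_encode(query, q, "query");
  bs_encode(ref, r, "reference");
  const ll m = (ll)q.size(), n = (ll)r.size();
  if (m == 0 || n == 0) stop("sequences must be non-empty");
  const ll W = band_width, p = lanes;
  if (p < 1 || W < p || W % p != 0)
    stop("band width must be a positive multiple of the lane count");
  const ll sbar = W / p;
  const ll goe = gap_open_ext, ge = gap_ext, ma = match, mi = mismatch;
  const ll cap = std::max((ll)0, m + 1 - W);  // rightmost band origin
  if (m > 2 * n + W - 1)
    stop("query too long for this band width and reference (band cannot reach the corner)");

  std::vector<ll> u(W), e(W), Snow(W), hfin(W), Hprev(W), Hcur(W), tmp;
  std::vector<ll> MF(p), seedF(p);
  std::vector<uint8_t> seedFb(p), exitFb(p);
  std::vector<int> i0_row(n + 1), shifts(n);
  // traceback: per row a byte per cell (bits 0-1 H source, bit 2 F-extend);
  // E-source bits for row j are produced during row j-1 and indexed by row
  // j-1's band offsets
  std::vector<uint8_t> tb, eb;
  if (want_cigar) {
    double bytes = (double)(n + 1) * (double)W * 2.0;
    if (bytes > 6e8) stop("traceback storage too large; use score-only mode");
    tb.assign((size_t)((n + 1) * W), 0);
    eb.assign((size_t)((n + 1) * W), 0);
  }

  // row 0: H[x][0] = gap_cost(x); u[0] is the difference against the NEG
  // wall left of the band; e enters row 1 as GapOE (open from row 0)
  ll i0 = 0;
  i0_row[0] = 0;
  for (ll x = 0; x < W; ++x) {
    Hprev[(size_t)x] = (x == 0) ? 0 : (x <= m ? goe + (x - 1) * ge : NEG);
    u[spos(x, sbar, p)] =
        Hprev[(size_t)x] - (x == 0 ? NEG : Hprev[(size_t)(x - 1)]);
    e[spos(x, sbar, p)] = goe;
  }

  int overridden = 0;
  for (ll j = 1; j <= n; ++j) {
    // ---- band shift: heuristic, clamped so the corner stays reachable ----
    int s = decide_shift_ll(Hprev, sbar, p, W, shift_rule);
    ll smin = std::max((ll)0, cap - 2 * (n - j) - i0);
    ll smax = std::min((ll)2, cap - i0);
    int sc = (int)std::min(std::max((ll)s, smin), smax);
    if (sc != s) ++overridden;
    s = sc;
    // diagonal parent of the band's first cell (NEG wall when out of band)
    ll diag0 = (s >= 1) ? Hprev[(size_t)(s - 1)] : NEG;
    i0 += s;
    i0_row[j] = (int)i0;
    shifts[j - 1] = s;

    // ---- striped move of the carried difference rows; scratch H follows ----
    striped_move_vec(u, tmp, s, sbar, p);
    striped_move_vec(e, tmp, s, sbar, p);
    if (s > 0) {
      for (ll x = 0; x < W - s; ++x) Hprev[(size_t)x] = Hprev[(size_t)(x + s)];
      for (ll x = W - s; x < W; ++x) Hprev[(size_t)x] = NEG;
      // repair the moved-in trailing cells so u stays the raw difference of
      // the walled scratch row and e restarts from the wall
      for (ll x = W - s; x < W; ++x) {
        u[spos(x, sbar, p)] =
            Hprev[(size_t)x] - (x == 0 ? NEG : Hprev[(size_t)(x - 1)]);
        e[spos(x, sbar, p)] = goe;
      }
    }

    // ---- substitution scores for this row, striped ----
    uint8_t rb = r[j - 1];
    for (ll x = 0; x < W; ++x) {
      ll i = i0 + x;
      Snow[spos(x, sbar, p)] =
          (i >= 1 && i <= m) ? bs_sub(q[i - 1], rb, ma, mi) : mi;
    }

    // ---- initial pass: f seeded with the sentinel in every segment;
    // h = max(S, e + u, f); f advances along the lane ----
    for (ll t = 0; t < p; ++t) MF[t] = NEG;
    for (ll k = 0; k < sbar; ++k) {
      for (ll t = 0; t < p; ++t) {
        size_t x = (size_t)(k * p + t);
        ll h = Snow[x];
        ll hE = e[x] + u[x];
        if (hE > h) h = hE;
        if (MF[t] > h) h = MF[t];
        ll fx = MF[t] + ge, fo = h + goe;
        exitFb[t] = (fx >= fo) ? 1 : 0;
        MF[t] = (fx >= fo ? fx : fo) - u[x];
      }
    }

    // ---- active F correction: one serial sweep over the segment-entry
    // lanes; the candidate is a gap extending across the whole previous
    // segment, re-anchored by the previous row's absolute step ----
    for (ll t = 1; t < p; ++t) {
      ll x = (t + 1) * sbar;  // MF lane t holds f at in-band offset x
      ll cand = MF[t - 1] + sbar * ge -
                (Hprev[(size_t)(x - 1)] - Hprev[(size_t)(x - 1 - sbar)]);
      if (cand > MF[t]) { MF[t] = cand; exitFb[t] = 1; }
    }
    // right shift one lane with a sentinel in lane 0: corrected first register
    seedF[0] = NEG; seedFb[0] = 0;
    for (ll t = 1; t < p; ++t) { seedF[t] = MF[t - 1]; seedFb[t] = exitFb[t - 1]; }

    // ---- final pass: recompute the row from the corrected seeds; this is a
    // fixed point, so h/u/v/e/f are final after exactly two passes ----
    uint8_t* tbrow = want_cigar ? &tb[(size_t)(j * W)] : nullptr;
    uint8_t* ebrow = (want_cigar && j < n) ? &eb[(size_t)((j + 1) * W)] : nullptr;
    for (ll t = 0; t < p; ++t) { MF[t] = seedF[t]; exitFb[t] = seedFb[t]; }
    for (ll k = 0; k < sbar; ++k) {
      for (ll t = 0; t < p; ++t) {
        size_t x = (size_t)(k * p + t);
        ll h = Snow[x];
        uint8_t dir = 0;
        ll hE = e[x] + u[x];
        if (hE > h) { h = hE; dir = 1; }
        if (MF[t] > h) { h = MF[t]; dir = 2; }
        hfin[x] = h;
        if (tbrow) tbrow[(size_t)(k + t * sbar)] = dir | (exitFb[t] << 2);
        ll en = hE - h + ge;
        uint8_t ebit = (en >= goe) ? 1 : 0;
        e[x] = (en >= goe) ? en : goe;
        if (ebrow) ebrow[(size_t)(k + t * sbar)] = ebit;
        ll fx = MF[t] + ge, fo = h + goe;
        exitFb[t] = (fx >= fo) ? 1 : 0;
        MF[t] = (fx >= fo ? fx : fo) - u[x];
      }
    }
    // the final pass re-derives the segment-entry f values (a fixed point);
    // its exit bits carry the true extend/open provenance for those cells,
    // which the initial pass could not know yet
    if (tbrow) {
      for (ll t = 1; t < p; ++t) {
        size_t xn = (size_t)(t * sbar);
        tbrow[xn] = (tbrow[xn] & 3) | (exitFb[t - 1] << 2);
      }
    }

    // ---- absolute row reconstruction (scratch), wall flooring, new u/e ----
    Hcur[0] = diag0 + hfin[spos(0, sbar, p)];
    for (ll x = 1; x < W; ++x)
      Hcur[(size_t)x] = Hprev[(size_t)(x - 1)] + hfin[spos(x, sbar, p)];
    for (ll x = 0; x < W; ++x)
      if (i0 + x > m || Hcur[(size_t)x] < DEAD) Hcur[(size_t)x] = NEG;
    for (ll x = 0; x < W; ++x) {
      size_t sp = spos(x, sbar, p);
      u[sp] = Hcur[(size_t)x] - (x == 0 ? NEG : Hcur[(size_t)(x - 1)]);
      if (Hcur[(size_t)x] == NEG) e[sp] = goe;  // restart from the wall
    }
    Hprev.swap(Hcur);
  }

  ll xend = m - i0;
  if (xend < 0 || xend >= W) stop("internal error: corner left the band");
  ll score = Hprev[(size_t)xend];
  if (score <= DEAD)
    stop("no global alignment path fits inside this band; increase the band width");

  SEXP cigar = R_NilValue;
  if (want_cigar) {
    std::vector<char> ops;
    ll i = m, jj = n;
    int state = 0;  // 0 H, 1 E, 2 F
    while (i > 0 || jj > 0) {
      if (state == 0) {
        if (i == 0) { while (jj > 0) { ops.push_back('D'); --jj; } break; }
        if (jj == 0) { while (i > 0) { ops.push_back('I'); --i; } break; }
        ll x = i - i0_row[jj];
        if (x < 0 || x >= W) stop("internal error: traceback left the band");
        uint8_t b = tb[(size_t)(jj * W + x)];
        uint8_t dir = b & 3;
        if (dir == 0) {
          ops.push_back((q[i - 1] == r[jj - 1] && q[i - 1] != 4) ? '=' : 'X');
          --i; --jj;
        } else if (dir == 1) state = 1;
        else state = 2;
      } else if (state == 1) {
        // E source bits for row jj live in row jj-1's offsets
        ll xe = i - i0_row[jj - 1];
        uint8_t bit = (xe >= 0 && xe < W) ? eb[(size_t)(jj * W + xe)] : 0;
        ops.push_back('D');
        --jj;
        if (!bit || jj == 0) state = 0;
      } else {
        ll x = i - i0_row[jj];
        if (x < 0 || x >= W) stop("internal error: traceback left the band");
        uint8_t bit = (tb[(size_t)(jj * W + x)] >> 2) & 1;
        ops.push_back('I');
        --i;
        if (!bit || i == 0) state = 0;
      }
    }
    cigar = Rf_mkString(bs_rle(ops).c_str());
  }

  return List::create(
    _["score"] = (double)score,
    _["cigar"] = cigar,
    _["shifts"] = IntegerVector(shifts.begin(), shifts.end()),
    _["overridden"] = overridden,
    _["band_origin_final"] = (double)i0,
    _["cells"] = (double)n * (double)W);
}

// Scalar banded reference aligner: the same band schedule (identical shift
// decisions) evaluated left-to-right over absolute H/E/F scores. Shares no
// state with the striped difference kernel; used to cross-check it.
// [[Rcpp::export(name = ".align_banded_scalar_cpp")]]
List align_banded_scalar_cpp(std::string query, std::string ref,
                             int match, int mismatch, int gap_open_ext,
                             int gap_ext, int band_width, int lanes,
                             bool want_cigar, int shift_rule) {
  std::vector<uint8_t> q, r;
  bs_encode(query, q, "query");
  bs_encode(ref, r, "reference");
  const ll m = (ll)q.size(), n = (ll)r.size();
  if (m == 0 || n == 0) stop("sequences must be non-empty");
  const ll W = band_width, p = lanes;
  if (p < 1 || W < p || W % p != 0)
    stop("band width must be a positive multiple of the lane count");
  const ll sbar = W / p;
  const ll goe = gap_open_ext, ge = gap_ext, ma = match, mi = mismatch;
  const ll cap = std::max((ll)0, m + 1 - W);
  if (m > 2 * n + W - 1)
    stop("query too long for this band width and reference (band cannot reach the corner)");

  std::vector<ll> Hprev(W), Eprev(W), Hcur(W), Ecur(W);
  std::vector<int> i0_row(n + 1), shifts(n);
  std::vector<uint8_t> tb;  // bits 0-1 dir, bit 2 F-extend, bit 3 E-extend
  if (want_cigar) {
    double bytes = (double)(n + 1) * (double)W;
    if (bytes > 6e8) stop("traceback storage too large; use score-only mode");
    tb.assign((size_t)((n + 1) * W), 0);
  }

  ll i0 = 0;
  i0_row[0] = 0;
  for (ll x = 0; x < W; ++x) {
    Hprev[(size_t)x] = (x == 0) ? 0 : (x <= m ? goe + (x - 1) * ge : NEG);
    Eprev[(size_t)x] = NEG;
  }

  int overridden = 0;
  for (ll j = 1; j <= n; ++j) {
    int s = decide_shift_ll(Hprev, sbar, p, W, shift_rule);
    ll smin = std::max((ll)0, cap - 2 * (n - j) - i0);
    ll smax = std::min((ll)2, cap - i0);
    int sc = (int)std::min(std::max((ll)s, smin), smax);
    if (sc != s) ++overridden;
    s = sc;
    ll diag0 = (s >= 1) ? Hprev[(size_t)(s - 1)] : NEG;
    i0 += s;
    i0_row[j] = (int)i0;
    shifts[j - 1] = s;
    if (s > 0) {
      for (ll x = 0; x < W - s; ++x) {
        Hprev[(size_t)x] = Hprev[(size_t)(x + s)];
        Eprev[(size_t)x] = Eprev[(size_t)(x + s)];
      }
      for (ll x = W - s; x < W; ++x) { Hprev[(size_t)x] = NEG; Eprev[(size_t)x] = NEG; }
    }

    uint8_t rb = r[j - 1];
    uint8_t* tbrow = want_cigar ? &tb[(size_t)(j * W)] : nullptr;
    ll F = NEG;
    for (ll x = 0; x < W; ++x) {
      ll i = i0 + x;
      ll eExt = Eprev[(size_t)x] + ge, eOpen = Hprev[(size_t)x] + goe;
      ll E = (eExt >= eOpen) ? eExt : eOpen;
      uint8_t ebit = (eExt >= eOpen) ? 1 : 0;
      uint8_t fbit = 0;
      if (x == 0) {
        F = NEG;
      } else {
        ll fExt = F + ge, fOpen = Hcur[(size_t)(x - 1)] + goe;
        fbit = (fExt >= fOpen) ? 1 : 0;
        F = (fExt >= fOpen) ? fExt : fOpen;
      }
      ll hd = (x == 0) ? diag0 : Hprev[(size_t)(x - 1)];
      ll h = (i >= 1 && i <= m) ? hd + bs_sub(q[i - 1], rb, ma, mi) : NEG;
      uint8_t dir = 0;
      if (E > h) { h = E; dir = 1; }
      if (F > h) { h = F; dir = 2; }
      if (i > m || h < DEAD) { h = NEG; E = NEG; }
      Hcur[(size_t)x] = h;
      Ecur[(size_t)x] = E;
      if (tbrow) tbrow[(size_t)x] = dir | (fbit << 2) | (ebit << 3);
    }
    Hprev.swap(Hcur);
    Eprev.swap(Ecur);
  }

  ll xend = m - i0;
  if (xend < 0 || xend >= W) stop("internal error: corner left the band");
  ll score = Hprev[(size_t)xend];
  if (score <= DEAD)
    stop("no global alignment path fits inside this band; increase the band width");

  SEXP cigar = R_NilValue;
  if (want_cigar) {
    std::vector<char> ops;
    ll i = m, jj = n;
    int state = 0;
    while (i > 0 || jj > 0) {
      if (state == 0) {
        if (i == 0) { while (jj > 0) { ops.push_back('D'); --jj; } break; }
        if (jj == 0) { while (i > 0) { ops.push_back('I'); --i; } break; }
        ll x = i - i0_row[jj];
        if (x < 0 || x >= W) stop("internal error: traceback left the band");
        uint8_t b = tb[(size_t)(jj * W + x)];
        uint8_t dir = b & 3;
        if (dir == 0) {
          ops.push_back((q[i - 1] == r[jj - 1] && q[i - 1] != 4) ? '=' : 'X');
          --i; --jj;
        } else if (dir == 1) state = 1;
        else state = 2;
      } else if (state == 1) {
        ll x = i - i0_row[jj];
        uint8_t bit = (x >= 0 && x < W) ? ((tb[(size_t)(jj * W + x)] >> 3) & 1) : 0;
        ops.push_back('D');
        --jj;
        if (!bit || jj == 0) state = 0;
      } else {
        ll x = i - i0_row[jj];
        if (x < 0 || x >= W) stop("internal error: traceback left the band");
        uint8_t bit = (tb[(size_t)(jj * W + x)] >> 2) & 1;
        ops.push_back('I');
        --i;
        if (!bit || i == 0) state = 0;
      }
    }
    cigar = Rf_mkString(bs_rle(ops).c_str());
  }

  return List::create(
    _["score"] = (double)score,
    _["cigar"] = cigar,
    _["shifts"] = IntegerVector(shifts.begin(), shifts.end()),
    _["overridden"] = overridden,
    _["band_origin_final"] = (double)i0,
    _["cells"] = (double)n * (double)W);
}
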
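# One banded row of the affine-gap DP in difference form.
#
# Quantities per cell (i = in-band query offset, j = reference row):
#   h = H[i,j] - H[i-1,j-1]   (diagonal difference)
#   u = H[i,j] - H[i-1,j]     (difference along the row)
#   v = H[i,j] - H[i,j-1]     (difference between rows)
#   e = E[i,j] - H[i,j-1]     (reference-gap score, asymmetric anchor)
#   f = F[i,j] - H[i-1,j-1]   (query-gap score, anchored like h)
# carried between rows: u and e only. Within a row:
#   h[i]   = max(S[i], e[i] + u[i], f[i])
#   e'[i]  = max(e[i] + u[i] - h[i] + GapE, GapOE)        (for the next row)
#   f[i+1] = max(f[i] + GapE, h[i] + GapOE) - u[i]
# The f chain runs along the row, which the striped layout breaks: the
# active F-loop fixes it with exactly two passes plus one serial sweep of
# the segment-entry lanes (see active_f_correct).
#
# All striped arguments are lanes x segments matrices as in striped_row();
# lane t of register k holds in-band offset k + t*s_bar.

.check_striped_mat <- function(m, cfg, what) {
  if (!is.matrix(m) || nrow(m) != cfg$lanes || ncol(m) != cfg$segments)
    stop(sprintf("%s must be a %d x %d (lanes x segments) striped matrix",
                 what, cfg$lanes, cfg$segments))
  m
}

#' Initial pass of the active F-loop row evaluation
#'
#' Evaluates one banded row register-by-register with every segment's f
#' seeded at the sentinel (the first F register is minus infinity). The h
#' values of cells reachable without a horizontal gap crossing a segment
#' boundary are already final; the returned last F register (lane t holds
#' the f value leaving segment t, i.e. at in-band offset (t+1)*s_bar) feeds
#' the penetration correction.
#'
#' @param prev_u,prev_e striped matrices of the previous row's u and the e
#'   entering this row, already striped-moved for this row's shift.
#' @param S_row striped matrix of substitution scores for this row.
#' @param scheme a [scoring_scheme()].
#' @param cfg a [band_config()].
#' @param neg_inf sentinel value.
#' @return A list with `h` and `f` (striped matrices of candidate values;
#'   `f` holds the value entering each cell) and `MF_last` (numeric, p
#'   lanes).
#' @export
row_initial_pass <- function(prev_u, prev_e, S_row, scheme = scoring_scheme(),
                             cfg, neg_inf = neg_inf_sentinel()) {
  .check_scheme(scheme)
  .check_cfg(cfg)
  .check_striped_mat(prev_u, cfg, "prev_u")
  .check_striped_mat(prev_e, cfg, "prev_e")
  .check_striped_mat(S_row, cfg, "S_row")
  ge <- scheme$gap_ext
  goe <- scheme$gap_open_ext
  p <- cfg$lanes
  sb <- cfg$segments
  h <- matrix(0, p, sb)
  fmat <- matrix(0, p, sb)
  f <- rep(neg_inf, p)
  for (k in seq_len(sb)) {
    fmat[, k] <- f
    hk <- pmax(S_row[, k], prev_e[, k] + prev_u[, k], f)
    h[, k] <- hk
    f <- pmax(f + ge, hk + goe) - prev_u[, k]
  }
  list(h = h, f = fmat, MF_last = f)
}

#' Active F correction: one serial sweep over the segment-entry lanes
#'
#' When a horizontal gap is long enough to penetrate a whole segment, the f
#' value entering the next segment must be at least the previous segment's
#' exit f extended across s_bar cells. One sweep over lanes t = 1..p-1 of
#' the last F register (serial, never iterated to convergence) propagates
#' such penetrations across any number of segments; the swept register is
#' then shifted right by one lane with a sentinel in lane 0, yielding the
#' corrected first F register that seeds the final pass.
#'
#' @param MF_last numeric vector of p lane values returned by
#'   [row_initial_pass()].
#' @param H_step numeric vector of p values; entry t+1 (lane t, t >= 1)
#'   holds the previous row's absolute step
#'   `H[x-1, j-1] - H[x-1-s_bar, j-1]` for x = (t+1)*s_bar, i.e. the sum of
#'   the previous row's u over in-band offsets x-s_bar .. x-1 (see
#'   [kernel_h_step()]). Entry 1 is ignored.
#' @param scheme a [scoring_scheme()].
#' @param cfg a [band_config()].
#' @param neg_inf sentinel value.
#' @return Numeric vector of p lanes: the corrected first F register.
#' @export
active_f_correct <- function(MF_last, H_step, scheme = scoring_scheme(),
                             cfg, neg_inf = neg_inf_sentinel()) {
  .check_scheme(scheme)
  .check_cfg(cfg)
  p <- cfg$lanes
  if (length(MF_last) != p) stop("MF_last must have one value per lane")
  if (length(H_step) != p) stop("H_step must have one value per lane")
  mf <- MF_last
  if (p > 1L) {
    for (t in 2:p) {  # lane t-1 (0-based), in-band offset t * s_bar
      cand <- mf[t - 1L] + cfg$segments * scheme$gap_ext - H_step[t]
      if (cand > mf[t]) mf[t] <- cand
    }
  }
  c(neg_inf, mf[-p])  # right shift one lane, sentinel into lane 0
}

#' Final pass: re-evaluate the row from the corrected F seeds
#'
#' Identical recurrence to [row_initial_pass()] but seeded with the
#' corrected first F register. Its outputs are final: re-running the pass on
#' its own re-derived seeds is a fixed point, so every row costs exactly two
#' passes regardless of gap length.
#'
#' @param MF_first corrected first F register from [active_f_correct()].
#' @inheritParams row_initial_pass
#' @return A list of striped matrices `h`, `v`, `u`, `e_next`, `f` plus
#'   `MF_last`. `v = h - prev_u` is the between-row difference;
#'   `u[x] = h[x] - v[x-1]` is the along-row difference (its offset-0 cell,
#'   whose left neighbour lies outside the band, is `NA`); `e_next` enters
#'   the next row; `f` holds the value entering each cell.
#' @export
row_final_pass <- function(MF_first, prev_u, prev_e, S_row,
                           scheme = scoring_scheme(), cfg,
                           neg_inf = neg_inf_sentinel()) {
  .check_scheme(scheme)
  .check_cfg(cfg)
  .check_striped_mat(prev_u, cfg, "prev_u")
  .check_striped_mat(prev_e, cfg, "prev_e")
  .check_striped_mat(S_row, cfg, "S_row")
  p <- cfg$lanes
  sb <- cfg$segments
  if (length(MF_first) != p) stop("MF_first must have one value per lane")
  ge <- scheme$gap_ext
  goe <- scheme$gap_open_ext
  h <- matrix(0, p, sb)
  e_next <- matrix(0, p, sb)
  fmat <- matrix(0, p, sb)
  f <- MF_first
  for (k in seq_len(sb)) {
    fmat[, k] <- f
    hE <- prev_e[, k] + prev_u[, k]
    hk <- pmax(S_row[, k], hE, f)
    h[, k] <- hk
    e_next[, k] <- pmax(hE - hk + ge, goe)
    f <- pmax(f + ge, hk + goe) - prev_u[, k]
  }
  v <- h - prev_u
  # u[x] = h[x] - v[x-1]: shift v by one normal cell (register k-1, with a
  # lane-crossing wrap at register 0)
  vN <- as.vector(t(v))
  uN <- c(NA_real_, as.vector(t(h))[-1] - vN[-cfg$width])
  u <- matrix(uN, nrow = p, byrow = TRUE)
  list(h = h, v = v, u = u, e_next = e_next, f = fmat, MF_last = f)
}

#' Previous-row absolute steps for the penetration correction
#'
#' Computes the `H_step` vector consumed by [active_f_correct()] from the
#' previous row's u differences: entry t+1 is the sum of u over the s_bar
#' in-band offsets preceding offset (t+1)*s_bar.
#'
#' @param prev_u striped matrix of the previous row's u (already moved).
#' @param cfg a [band_config()].
#' @return Numeric vector of p values; entry 1 is `NA` (lane 0 needs no
#'   correction).
#' @export
kernel_h_step <- function(prev_u, cfg) {
  .check_cfg(cfg)
  .check_striped_mat(prev_u, cfg, "prev_u")
  uN <- as.vector(t(prev_u))
  sb <- cfg$segments
  p <- cfg$lanes
  out <- rep(NA_real_, p)
  if (p > 1L) {
    for (t in 2:p) {  # offsets (t-1)*sb .. t*sb - 1 (0-based), R-shifted by 1
      out[t] <- sum(uN[((t - 1L) * sb + 1L):(t * sb)])
    }
  }
  out
}

#' Evaluate one banded row with the two-pass active F-loop
#'
#' Convenience wrapper chaining [row_initial_pass()], [active_f_correct()]
#' and [row_final_pass()]; what the aligner's compiled kernel executes per
#' row.
#'
#' @inheritParams row_initial_pass
#' @return The [row_final_pass()] result, plus `MF_first` (the corrected
#'   seeds) and `passes` (always 2).
#' @export
kernel_row <- function(prev_u, prev_e, S_row, scheme = scoring_scheme(), cfg,
                       neg_inf = neg_inf_sentinel()) {
  ip <- row_initial_pass(prev_u, prev_e, S_row, scheme, cfg, neg_inf)
  hstep <- kernel_h_step(prev_u, cfg)
  hstep[1] <- 0
  seeds <- active_f_correct(ip$MF_last, hstep, scheme, cfg, neg_inf)
  fp <- row_final_pass(seeds, prev_u, prev_e, S_row, scheme, cfg, neg_inf)
  fp$MF_first <- seeds
  fp$passes <- 2L
  fp
}

#' Scalar left-to-right reference evaluation of one banded row
#'
#' The same row recurrence evaluated in plain normal order with the f chain
#' carried cell to cell -- no striping, no passes. Used as the trusted
#' comparator for the two-pass kernel (they must agree cell for cell) and by
#' the row debugging CLI.
#'
#' @param prev_u,prev_e,S_row numeric vectors in normal (in-band) order.
#' @param scheme a [scoring_scheme()].
#' @param neg_inf sentinel value.
#' @return A list of normal-order vectors `h`, `e_next`, `f` (value entering
#'   each cell).
#' @export
row_scalar_reference <- function(prev_u, prev_e, S_row,
                                 scheme = scoring_scheme(),
                                 neg_inf = neg_inf_sentinel()) {
  .check_scheme(scheme)
  W <- length(prev_u)
  if (length(prev_e) != W || length(S_row) != W)
    stop("prev_u, prev_e and S_row must have equal length")
  ge <- scheme$gap_ext
  goe <- scheme$gap_open_ext
  h <- numeric(W); e_next <- numeric(W); fvec <- numeric(W)
  f <- neg_inf
  for (x in seq_len(W)) {
    fvec[x] <- f
    hE <- prev_e[x] + prev_u[x]
    hx <- max(S_row[x], hE, f)
    h[x] <- hx
    e_next[x] <- max(hE - hx + ge, goe)
    f <- max(f + ge, hx + goe) - prev_u[x]
  }
  list(h = h, e_next = e_next, f = fvec)
}

#' Reconstruct absolute scores along a band row
#'
#' Absolute scores are never stored by the kernel; they are recovered from
#' the band origin's anchor score plus a prefix sum of the along-row
#' differences u in normal order. Between rows, the anchor itself advances
#' by the between-row difference v at the offset matching the shift; the two
#' chains must agree wherever both apply.
#'
#' @param origin_score absolute score at in-band offset 0.
#' @param u striped matrix (or normal-order vector) of along-row u
#'   differences; the offset-0 entry is ignored.
#' @param cfg a [band_config()] (required when `u` is a striped matrix).
#' @return Numeric vector of absolute scores in normal order.
#' @export
reconstruct_H <- function(origin_score, u, cfg = NULL) {
  if (is.matrix(u)) {
    if (is.null(cfg)) stop("cfg is required for a striped matrix input")
    .check_cfg(cfg)
    .check_striped_mat(u, cfg, "u")
    u <- as.vector(t(u))
  }
  origin_score + c(0, cumsum(u[-1]))
}
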
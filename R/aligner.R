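#' Banded striped global alignment
#'
#' Needleman-Wunsch/Gotoh global alignment restricted to an adaptive band of
#' `band_width` query cells per reference row. The band is evaluated in a
#' striped vector layout with the difference recurrence relation and a
#' two-pass active F-loop; between rows it shifts right by 0, 1 or 2 cells
#' (favouring a vertical gap, the diagonal, or a horizontal gap) according
#' to the summed scores of its first and last register, and the striped
#' arrays follow by a register rotation plus a one-lane shift (the striped
#' move). Shift decisions near the sequence ends are overridden so the
#' terminal corner always lies inside the final band.
#'
#' With `band_width = NULL` (or 0/`Inf`/"full") the band spans the whole
#' query -- the "no band" mode, which still exercises the striped kernel and
#' is exactly the full Gotoh optimum. With a finite band the score is a
#' lower bound on the optimum; the returned CIGAR always re-scores exactly
#' to the returned score.
#'
#' The band indexes the query and rows iterate over the reference; when the
#' query is longer than the reference the roles are swapped internally and
#' the CIGAR transposed back. A requested width is rounded up to a multiple
#' of `lanes`, and a width of at least the query length is clamped to the
#' full-width mode (both with a message).
#'
#' @param query,reference nucleotide strings (A/C/G/T/N, case-insensitive;
#'   other IUPAC codes fold to N).
#' @param scheme a [scoring_scheme()].
#' @param band_width band width in query cells, or `NULL`/0/`Inf`/"full"
#'   for the full-width mode.
#' @param lanes emulated vector width p (correctness is independent of it).
#' @param score_only skip the traceback and return only the score.
#' @param engine `"striped"` for the two-pass active-F difference kernel
#'   (default), `"scalar"` for the plain left-to-right banded reference
#'   evaluation of the same band schedule (cross-check path).
#' @param shift_rule `"register"` compares the summed first/last register
#'   (strided samples, the shipped heuristic); `"contiguous"` compares the
#'   leftmost/rightmost p contiguous cells.
#' @param quiet suppress band-adjustment messages.
#' @return An object of class `bandstripe_alignment`: a list with `score`,
#'   `cigar` (NULL when `score_only`), `query_range` and `ref_range`
#'   (0-based half-open), `identity` (fraction of `=` columns), `band_width`
#'   (the width used, `Inf` for full), `lanes`, `shifts_overridden`,
#'   `swapped`, `engine`, `cells`.
#' @examples
#' align_global("ACGT", "ACGT")$score           # 8, cigar "4="
#' align_global("ACGT", "AGT")$cigar            # "1=1I2="
#' @export
align_global <- function(query, reference, scheme = scoring_scheme(),
                         band_width = NULL, lanes = 16L, score_only = FALSE,
                         engine = c("striped", "scalar"),
                         shift_rule = c("register", "contiguous"),
                         quiet = FALSE) {
  .check_scheme(scheme)
  engine <- match.arg(engine)
  shift_rule <- match.arg(shift_rule)
  if (!.is_count(lanes) || lanes < 1) stop("lanes must be a positive integer")
  lanes <- as.integer(lanes)
  q <- normalize_seq(query, "query")
  r <- normalize_seq(reference, "reference")

  swapped <- nchar(q) > nchar(r)
  if (swapped) { tmp <- q; q <- r; r <- tmp }
  m <- nchar(q); n <- nchar(r)

  full_w <- as.integer(ceiling((m + 1) / lanes) * lanes)
  full <- is.null(band_width) ||
    (is.character(band_width) && identical(tolower(band_width), "full")) ||
    (is.numeric(band_width) && (band_width == 0 || is.infinite(band_width)))
  if (!full) {
    if (!.is_count(band_width) || band_width < 1)
      stop("band_width must be a positive integer, 0/Inf/\"full\", or NULL")
    W <- as.integer(band_width)
    if (W %% lanes != 0L) {
      W2 <- as.integer(ceiling(W / lanes) * lanes)
      if (!quiet)
        message(sprintf("band width %d rounded up to %d (multiple of %d lanes)",
                        W, W2, lanes))
      W <- W2
    }
    if (W >= m + 1L) {
      if (!quiet)
        message(sprintf("band width %d covers the whole query (length %d); using full width",
                        W, m))
      full <- TRUE
    }
  }
  if (full) W <- full_w

  fn <- if (engine == "striped") .align_banded_cpp else .align_banded_scalar_cpp
  res <- fn(q, r, scheme$match, scheme$mismatch, scheme$gap_open_ext,
            scheme$gap_ext, W, lanes, !score_only,
            if (shift_rule == "register") 0L else 1L)

  cigar <- res$cigar
  qlen0 <- if (swapped) n else m
  rlen0 <- if (swapped) m else n
  if (!is.null(cigar) && swapped) cigar <- transpose_cigar(cigar)
  out <- structure(list(
    score = res$score,
    cigar = cigar,
    query_range = c(0L, qlen0),
    ref_range = c(0L, rlen0),
    identity = if (is.null(cigar)) NA_real_ else cigar_identity(cigar),
    band_width = if (full) Inf else W,
    lanes = lanes,
    shifts_overridden = res$overridden,
    swapped = swapped,
    engine = engine,
    cells = res$cells), class = "bandstripe_alignment")
  out
}

#' Global alignment score only
#'
#' As [align_global()] but without allocating the traceback store.
#'
#' @inheritParams align_global
#' @param ... passed on to [align_global()].
#' @return Numeric score.
#' @export
align_score_only <- function(query, reference, scheme = scoring_scheme(),
                             band_width = NULL, ...) {
  align_global(query, reference, scheme = scheme, band_width = band_width,
               score_only = TRUE, ...)$score
}

#' @export
print.bandstripe_alignment <- function(x, ...) {
  bw <- if (is.infinite(x$band_width)) "full" else as.character(x$band_width)
  cat(sprintf("<bandstripe_alignment> score %s, band %s (%d lanes)%s\n",
              format(x$score), bw, x$lanes,
              if (x$swapped) ", roles swapped" else ""))
  cat(sprintf("  query 0..%d, reference 0..%d", x$query_range[2],
              x$ref_range[2]))
  if (!is.na(x$identity)) cat(sprintf(", identity %.4f", x$identity))
  cat("\n")
  if (!is.null(x$cigar)) {
    cg <- x$cigar
    if (nchar(cg) > 60) cg <- paste0(substr(cg, 1, 57), "...")
    cat("  cigar:", cg, "\n")
  }
  invisible(x)
}
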
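#' Sentinel used for cells outside the band or the matrix
#'
#' A finite stand-in for minus infinity: small enough that it never wins a
#' maximum against any reachable score, large enough that sums and
#' differences of a full row of sentinels stay exactly representable in
#' double precision (and in the 64-bit integers of the compiled kernel).
#'
#' @return A single negative numeric value.
#' @export
neg_inf_sentinel <- function() -(2^40)

# liveness threshold matching the compiled kernel
.dead_threshold <- function() -(2^39)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Normalize a nucleotide string: upper-case, fold IUPAC ambiguity codes other
# than N to N (with an optional one-time warning), reject anything else.
normalize_seq <- function(seq, what = "sequence", warn_iupac = TRUE) {
  if (length(seq) != 1L || !is.character(seq) || is.na(seq))
    stop(sprintf("%s must be a single character string", what), call. = FALSE)
  s <- toupper(seq)
  if (nchar(s) == 0L)
    stop(sprintf("%s must be non-empty", what), call. = FALSE)
  if (grepl("[^ACGTN]", s)) {
    iupac <- "RYSWKMBDHV"
    cleaned <- chartr(iupac, strrep("N", nchar(iupac)), s)
    if (grepl("[^ACGTN]", cleaned)) {
      bad <- regmatches(cleaned, regexpr("[^ACGTN]", cleaned))
      stop(sprintf("%s contains invalid symbol '%s'", what, bad), call. = FALSE)
    }
    if (warn_iupac)
      warning(sprintf("%s: IUPAC ambiguity codes mapped to N", what),
              call. = FALSE)
    s <- cleaned
  }
  s
}

.is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == floor(x)
}
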
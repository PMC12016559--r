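# Sequence I/O and result writers. FASTA/FASTQ parsing (plain or gzipped)
# is delegated to Biostrings; records are normalized to upper-case A/C/G/T/N
# with other IUPAC codes folded to N.

#' Read sequences from FASTA or FASTQ
#'
#' @param path file path; gzip is detected from the magic bytes.
#' @param format `"auto"` (sniff `>` vs `@` on the first record), `"fasta"`
#'   or `"fastq"`.
#' @return A data.frame with columns `name`, `seq` (normalized), and
#'   `source` (`file:record-index`).
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto") {
    con <- gzfile(path, "rt")
    first <- tryCatch(readLines(con, n = 1L), finally = close(con))
    if (length(first) == 0L) stop(sprintf("%s: empty file", path))
    format <- if (startsWith(first, ">")) "fasta"
      else if (startsWith(first, "@")) "fastq"
      else stop(sprintf("%s: cannot detect format (first character '%s')",
                        path, substr(first, 1, 1)))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = format),
    error = function(e) stop(sprintf("%s: malformed %s (%s)", path, format,
                                     conditionMessage(e)), call. = FALSE))
  if (length(set) == 0L) stop(sprintf("%s: no records", path))
  seqs <- as.character(set)
  nms <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(nms)))
    nms[!nzchar(nms)] <- sprintf("record%d", which(!nzchar(nms)))
  warned <- FALSE
  out <- character(length(seqs))
  for (i in seq_along(seqs)) {
    s <- toupper(seqs[i])
    if (grepl("[^ACGTN]", s)) {
      if (!warned) {
        warning(sprintf("%s: IUPAC ambiguity codes mapped to N", path),
                call. = FALSE)
        warned <- TRUE
      }
      s <- tryCatch(normalize_seq(s, sprintf("%s record %d", path, i),
                                  warn_iupac = FALSE),
                    error = function(e) stop(conditionMessage(e), call. = FALSE))
    }
    if (nchar(s) == 0L)
      stop(sprintf("%s record %d (%s): empty sequence", path, i, nms[i]))
    out[i] <- s
  }
  data.frame(name = nms, seq = out,
             source = sprintf("%s:%d", path, seq_along(out)),
             stringsAsFactors = FALSE)
}

# Assemble query/reference pairs from CLI-style inputs: either a single
# --pairs file with alternating query (even 0-based index) / reference
# records, or two files zipped positionally.
pair_sequences <- function(query_path = NULL, ref_path = NULL,
                           pairs_path = NULL) {
  if (!is.null(pairs_path)) {
    recs <- read_sequences(pairs_path)
    if (nrow(recs) %% 2 != 0)
      stop(sprintf("%s: --pairs needs an even record count (query/reference alternating)",
                   pairs_path))
    qi <- seq(1, nrow(recs), by = 2)
    data.frame(qname = recs$name[qi], query = recs$seq[qi],
               rname = recs$name[qi + 1], reference = recs$seq[qi + 1],
               stringsAsFactors = FALSE)
  } else {
    if (is.null(query_path) || is.null(ref_path))
      stop("provide either --pairs or both --query and --ref")
    qs <- read_sequences(query_path)
    rs <- read_sequences(ref_path)
    if (nrow(qs) != nrow(rs))
      stop(sprintf("query file has %d records but reference file has %d",
                   nrow(qs), nrow(rs)))
    data.frame(qname = qs$name, query = qs$seq,
               rname = rs$name, reference = rs$seq, stringsAsFactors = FALSE)
  }
}

#' Write alignment results as TSV
#'
#' One row per pair with the fixed columns `qname`, `rname`, `qlen`,
#' `rlen`, `score`, `qstart`, `qend`, `rstart`, `rend`, `cigar`,
#' `identity`; coordinates 0-based half-open, rows in input order.
#'
#' @param results a data.frame with those columns (see [align_pairs()]).
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_alignment_tsv <- function(results, path) {
  cols <- c("qname", "rname", "qlen", "rlen", "score", "qstart", "qend",
            "rstart", "rend", "cigar", "identity")
  missing <- setdiff(cols, names(results))
  if (length(missing) > 0)
    stop(sprintf("results lack column(s): %s", paste(missing, collapse = ", ")))
  utils::write.table(results[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align query/reference pairs
#'
#' Applies [align_global()] to each pair and collects the TSV-ready table.
#'
#' @param pairs data.frame with columns `qname`, `query`, `rname`,
#'   `reference` (see [pair_sequences()] for the file conventions).
#' @param scheme a [scoring_scheme()].
#' @param band_width,lanes,score_only,shift_rule as in [align_global()].
#' @return A data.frame in [write_alignment_tsv()] column layout.
#' @export
align_pairs <- function(pairs, scheme = scoring_scheme(), band_width = NULL,
                        lanes = 16L, score_only = FALSE,
                        shift_rule = "register") {
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    al <- align_global(pairs$query[i], pairs$reference[i], scheme,
                       band_width = band_width, lanes = lanes,
                       score_only = score_only, shift_rule = shift_rule,
                       quiet = TRUE)
    data.frame(qname = pairs$qname[i], rname = pairs$rname[i],
               qlen = nchar(pairs$query[i]), rlen = nchar(pairs$reference[i]),
               score = al$score,
               qstart = al$query_range[1], qend = al$query_range[2],
               rstart = al$ref_range[1], rend = al$ref_range[2],
               cigar = if (is.null(al$cigar)) "" else al$cigar,
               identity = if (is.na(al$identity)) "" else
                 sprintf("%.6f", al$identity),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Edit-distance over query/reference pairs
#'
#' @param pairs data.frame as for [align_pairs()].
#' @param limit maximum distance or `NULL`.
#' @param want_cigar also trace back each pair.
#' @return A data.frame with columns `qname`, `rname`, `distance`
#'   (`"EXCEEDED"` when over the limit) and `cigar`.
#' @export
edit_pairs <- function(pairs, limit = NULL, want_cigar = FALSE) {
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    ed <- edit_distance(pairs$query[i], pairs$reference[i], limit = limit,
                        want_cigar = want_cigar)
    data.frame(qname = pairs$qname[i], rname = pairs$rname[i],
               distance = if (ed$exceeded) "EXCEEDED" else
                 as.character(ed$distance),
               cigar = if (is.null(ed$cigar)) "" else ed$cigar,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Write simulated pairs as FASTA
#'
#' Records alternate query/reference, matching the `--pairs` convention.
#'
#' @param pairs data.frame with `qname`, `query`, `rname`, `reference`.
#' @param path output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_pairs_fasta <- function(pairs, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(pairs))) {
    writeLines(c(paste0(">", pairs$qname[i]), pairs$query[i],
                 paste0(">", pairs$rname[i]), pairs$reference[i]), con)
  }
  invisible(path)
}
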
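# Synthetic read-pair generator emulating long-read error profiles: i.i.d.
# per-base events at a total rate equal to the divergence, split between
# substitutions, single-base insertions and deletions by a configurable
# ratio, plus optional injection of one structural indel. Replaces HMM-based
# simulation with the printed, reproducible parameters; error clustering is
# not modelled.

.BS_RATIOS <- list(pacbio = c(sub = 6, ins = 50, del = 54),
                   nanopore = c(sub = 23, ins = 31, del = 46))

#' Mutation profile for the read simulator
#'
#' Divergence d is the total per-base event probability (1 - identity of the
#' simulated read); the sub:ins:del ratio splits it between event types.
#' Named profiles carry the published long-read ratios: 6:50:54 for PacBio
#' and 23:31:46 for Nanopore.
#'
#' @param divergence total per-base event probability, in `[0, 1)`.
#' @param name `"nanopore"`, `"pacbio"`, or `"custom"` (requires `ratio`).
#' @param ratio positive weights `c(sub, ins, del)`; overrides `name`.
#' @param seed integer seed driving [mutate()].
#' @return An object of class `mutation_profile`.
#' @examples
#' mutation_profile(0.2, "nanopore")
#' @export
mutation_profile <- function(divergence, name = c("nanopore", "pacbio", "custom"),
                             ratio = NULL, seed = 1L) {
  name <- match.arg(name)
  if (!is.numeric(divergence) || length(divergence) != 1L ||
      is.na(divergence) || divergence < 0 || divergence >= 1)
    stop("divergence must be a single value in [0, 1)")
  if (is.null(ratio)) {
    if (name == "custom") stop("a custom profile requires 'ratio'")
    ratio <- .BS_RATIOS[[name]]
  } else {
    if (length(ratio) != 3L || any(!is.finite(ratio)) || any(ratio < 0) ||
        sum(ratio) <= 0)
      stop("ratio must be three non-negative weights c(sub, ins, del)")
    names(ratio) <- c("sub", "ins", "del")
    name <- if (name %in% c("nanopore", "pacbio")) name else "custom"
  }
  if (!.is_count(seed)) stop("seed must be a single integer")
  structure(list(divergence = divergence, ratio = ratio / sum(ratio),
                 name = name, seed = as.integer(seed)),
            class = "mutation_profile")
}

#' @export
print.mutation_profile <- function(x, ...) {
  cat(sprintf("<mutation_profile> %s: divergence %.3f, sub:ins:del = %.3f:%.3f:%.3f, seed %d\n",
              x$name, x$divergence, x$ratio[1], x$ratio[2], x$ratio[3], x$seed))
  invisible(x)
}

#' Random uniform reference sequence
#'
#' @param length sequence length (>= 1).
#' @param seed integer seed.
#' @return A nucleotide string with i.i.d. uniform A/C/G/T bases.
#' @export
random_reference <- function(length, seed = 1L) {
  if (!.is_count(length) || length < 1) stop("length must be a positive integer")
  if (!.is_count(seed)) stop("seed must be a single integer")
  with_seed(seed, paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                        collapse = ""))
}

#' Mutate a reference into a simulated read
#'
#' Every reference base independently suffers an event with probability
#' `divergence`; the event type is drawn from the profile's sub:ins:del
#' weights. Substitutions replace the base with a uniformly chosen different
#' base, insertions add one uniform base in front of the kept base, and
#' deletions drop the base. A long insertion arises only from adjacent
#' single-base events, which is why structural indels are injected
#' separately (see [inject_indel()]).
#'
#' @param reference a nucleotide string.
#' @param profile a [mutation_profile()]; its seed makes the result
#'   reproducible.
#' @return The mutated sequence (the simulated read), with an `events`
#'   attribute holding the realized event counts
#'   `c(sub = , ins = , del = )`.
#' @examples
#' mutate(random_reference(50, 7), mutation_profile(0.2, "nanopore", seed = 7))
#' @export
mutate <- function(reference, profile) {
  if (!inherits(profile, "mutation_profile"))
    stop("profile must be a 'mutation_profile'")
  ref <- normalize_seq(reference, "reference")
  n <- nchar(ref)
  bases <- strsplit(ref, "", fixed = TRUE)[[1]]
  ALPH <- c("A", "C", "G", "T")
  with_seed(profile$seed, {
    hit <- runif(n) < profile$divergence
    nh <- sum(hit)
    out <- bases
    ev <- c(sub = 0L, ins = 0L, del = 0L)
    if (nh > 0) {
      type <- sample(c("sub", "ins", "del"), nh, replace = TRUE,
                     prob = profile$ratio)
      idx <- which(hit)
      is_sub <- type == "sub"
      if (any(is_sub)) {
        i <- idx[is_sub]
        # uniform over the three other bases
        shift <- sample.int(3L, length(i), replace = TRUE)
        cur <- match(bases[i], ALPH)
        cur[is.na(cur)] <- sample.int(4L, sum(is.na(cur)), replace = TRUE)  # N
        out[i] <- ALPH[((cur - 1L + shift) %% 4L) + 1L]
      }
      is_ins <- type == "ins"
      if (any(is_ins)) {
        i <- idx[is_ins]
        out[i] <- paste0(ALPH[sample.int(4L, length(i), replace = TRUE)],
                         out[i])
      }
      is_del <- type == "del"
      if (any(is_del)) out[idx[is_del]] <- ""
      ev <- c(sub = sum(is_sub), ins = sum(is_ins), del = sum(is_del))
    }
    structure(paste(out, collapse = ""), events = ev)
  })
}

#' Inject one structural indel into a reference
#'
#' Inserts or deletes one contiguous block of `size` bases at the sequence
#' midpoint, jittered uniformly by up to 10% of the length. Inserted bases
#' are uniform random.
#'
#' @param reference a nucleotide string.
#' @param size indel length (must be smaller than half the reference).
#' @param kind `"insertion"` or `"deletion"`.
#' @param seed integer seed (jitter and inserted bases).
#' @return The modified sequence.
#' @examples
#' nchar(inject_indel(random_reference(1000, 1), 50, "deletion", 1))  # 950
#' @export
inject_indel <- function(reference, size, kind = c("insertion", "deletion"),
                         seed = 1L) {
  kind <- match.arg(kind)
  ref <- normalize_seq(reference, "reference")
  n <- nchar(ref)
  if (!.is_count(size) || size < 1) stop("size must be a positive integer")
  if (size >= n / 2) stop("indel size must be smaller than half the reference length")
  if (!.is_count(seed)) stop("seed must be a single integer")
  with_seed(seed, {
    jitter <- round(runif(1, -0.1, 0.1) * n)
    pos <- max(1L, min(n - 1L, as.integer(round(n / 2) + jitter)))  # after base `pos`
    if (kind == "deletion") {
      if (pos + size > n) pos <- n - size
      paste0(substr(ref, 1L, pos), substr(ref, pos + size + 1L, n))
    } else {
      ins <- paste(sample(c("A", "C", "G", "T"), size, replace = TRUE),
                   collapse = "")
      paste0(substr(ref, 1L, pos), ins, substr(ref, pos + 1L, n))
    }
  })
}

#' Band-width recall experiment
#'
#' For each replicate, builds a random reference, optionally injects one
#' structural indel, mutates the result into a simulated read, and aligns
#' read against the original reference with the full-matrix Gotoh oracle
#' and with the banded striped aligner at each requested band width. Recall
#' of a band width is the fraction of replicates whose banded score equals
#' the oracle optimum.
#'
#' @param n_replicates number of simulated pairs (>= 1).
#' @param ref_length reference length in bp.
#' @param profile a [mutation_profile()]; replicate r uses seed
#'   `profile$seed + r`.
#' @param indel `NULL`, or `list(size =, kind =)` for one structural indel
#'   injected before mutation.
#' @param band_widths numeric vector of band widths; 0 or `Inf` denote the
#'   full-width ("no band") mode.
#' @param scheme a [scoring_scheme()].
#' @param lanes emulated vector width for the banded aligner.
#' @return An object of class `recall_experiment`: a list with `table`
#'   (data.frame: `band_width`, `recall`, `n`) and `replicates` (data.frame:
#'   `replicate`, `band_width`, `score`, `oracle_score`, `hit`).
#' @examples
#' \donttest{
#' recall_experiment(5, 400, mutation_profile(0.05, "nanopore", seed = 3),
#'                   band_widths = c(64, 0))$table
#' }
#' @export
recall_experiment <- function(n_replicates, ref_length, profile, indel = NULL,
                              band_widths = c(128, 0),
                              scheme = scoring_scheme(), lanes = 16L) {
  if (!.is_count(n_replicates) || n_replicates < 1)
    stop("n_replicates must be a positive integer")
  if (!inherits(profile, "mutation_profile"))
    stop("profile must be a 'mutation_profile'")
  if (!is.null(indel)) {
    if (!is.list(indel) || is.null(indel$size) || is.null(indel$kind))
      stop("indel must be NULL or list(size =, kind =)")
  }
  rows <- vector("list", n_replicates)
  for (rep_i in seq_len(n_replicates)) {
    seed_i <- profile$seed + rep_i
    ref <- random_reference(ref_length, seed = seed_i)
    tmpl <- ref
    if (!is.null(indel))
      tmpl <- inject_indel(ref, indel$size, indel$kind, seed = seed_i)
    prof_i <- profile
    prof_i$seed <- seed_i
    qry <- mutate(tmpl, prof_i)
    oracle <- gotoh_global(qry, ref, scheme, want_cigar = FALSE)$score
    sc <- vapply(band_widths, function(W) {
      bw <- if (W == 0 || is.infinite(W)) NULL else W
      align_score_only(qry, ref, scheme, band_width = bw, lanes = lanes,
                       quiet = TRUE)
    }, numeric(1))
    rows[[rep_i]] <- data.frame(
      replicate = rep_i,
      band_width = band_widths,
      score = sc,
      oracle_score = oracle,
      hit = sc == oracle)
  }
  reps <- do.call(rbind, rows)
  agg <- stats::aggregate(hit ~ band_width, data = reps, FUN = mean)
  tab <- data.frame(band_width = agg$band_width, recall = agg$hit,
                    n = n_replicates)
  tab <- tab[match(band_widths, tab$band_width), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, replicates = reps), class = "recall_experiment")
}

#' @export
print.recall_experiment <- function(x, ...) {
  cat("<recall_experiment>\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
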
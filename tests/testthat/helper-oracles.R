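# Independent brute-force helpers used only by the tests.

# random nucleotide string
rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# a mutated partner at roughly the given divergence (structure-rich pairs)
rand_pair <- function(n, divergence, seed) {
  ref <- random_reference(n, seed = seed)
  qry <- mutate(ref, mutation_profile(divergence, "nanopore", seed = seed))
  list(query = as.character(qry), reference = ref)
}

# Exhaustive enumeration of every global alignment of two tiny sequences
# under affine gap costs; exponential, so only for lengths <= ~7. Entirely
# independent of the package's DP code paths.
enumerate_global_score <- function(q, r, scheme = scoring_scheme()) {
  qs <- strsplit(q, "")[[1]]
  rs <- strsplit(r, "")[[1]]
  best <- -Inf
  rec <- function(i, j, last, sc) {
    if (i == length(qs) && j == length(rs)) {
      best <<- max(best, sc)
      return(invisible(NULL))
    }
    if (i < length(qs) && j < length(rs)) {
      sub <- if (qs[i + 1] == rs[j + 1] && qs[i + 1] != "N")
        scheme$match else scheme$mismatch
      rec(i + 1, j + 1, "M", sc + sub)
    }
    if (i < length(qs))
      rec(i + 1, j, "I",
          sc + if (identical(last, "I")) scheme$gap_ext else scheme$gap_open_ext)
    if (j < length(rs))
      rec(i, j + 1, "D",
          sc + if (identical(last, "D")) scheme$gap_ext else scheme$gap_open_ext)
  }
  rec(0L, 0L, "", 0)
  best
}

# Plain-R full-matrix affine DP (absolute H/E/F); small sizes only. Used to
# derive H matrices for difference-boundedness and reconstruction tests.
r_gotoh_matrix <- function(q, r, scheme = scoring_scheme()) {
  qs <- strsplit(q, "")[[1]]
  rs <- strsplit(r, "")[[1]]
  m <- length(qs); n <- length(rs)
  NEG <- neg_inf_sentinel()
  goe <- scheme$gap_open_ext; ge <- scheme$gap_ext
  H <- matrix(NEG, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  H[1, 1] <- 0
  for (i in 2:(m + 1)) H[i, 1] <- goe + (i - 2) * ge
  for (j in 2:(n + 1)) H[1, j] <- goe + (j - 2) * ge
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(E[i, j - 1] + ge, H[i, j - 1] + goe)
      F[i, j] <- max(F[i - 1, j] + ge, H[i - 1, j] + goe)
      sub <- if (qs[i - 1] == rs[j - 1] && qs[i - 1] != "N")
        scheme$match else scheme$mismatch
      H[i, j] <- max(H[i - 1, j - 1] + sub, E[i, j], F[i, j])
    }
  }
  list(H = H, E = E, F = F)
}

# normal-order vector -> lanes x segments striped matrix
to_striped <- function(v, cfg) {
  matrix(v, nrow = cfg$lanes, byrow = TRUE)
}

# left shift with sentinel fill, the normal-coordinate reference for the
# striped move
left_shift_sentinel <- function(v, shift, neg = neg_inf_sentinel()) {
  v <- as.numeric(v)
  W <- length(v)
  if (shift == 0) return(v)
  if (shift >= W) return(rep(neg, W))
  c(v[-seq_len(shift)], rep(neg, shift))
}

# random row inputs for the kernel equivalence tests; gap-heavy settings
# provoke F penetration across segments
rand_row_inputs <- function(W, gap_heavy = FALSE) {
  if (gap_heavy) {
    S <- sample(c(2, -30), W, replace = TRUE, prob = c(0.1, 0.9))
    S[sample.int(W, 1)] <- 40  # one strong anchor the gap extends from
    u <- sample(-2:2, W, replace = TRUE)
    e <- sample(c(-40, -20), W, replace = TRUE)
  } else {
    S <- sample(c(2, -4), W, replace = TRUE)
    u <- sample(-8:8, W, replace = TRUE)
    e <- sample(-12:0, W, replace = TRUE)
  }
  list(u = u, e = e, S = S)
}
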
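# Independent oracles used by the test suite.

# Base sets straight from the Biostrings IUPAC table (independent of the
# package's own algebra).
oracle_base_set <- function(code) {
  strsplit(Biostrings::IUPAC_CODE_MAP[[code]], "")[[1]]
}

# Score a complete gapped alignment (two equal-length character vectors,
# "-" for gaps) under the package's conventions, computed directly from
# the definition: terminal gap runs in either string are free; an internal
# gap run of length L costs gap_open + (L-1)*gap_extend; two non-gap
# states score `match` iff their base sets intersect, else `mismatch`.
score_alignment_oracle <- function(ac, bc, sc = alignment_scoring()) {
  n <- length(ac)
  run_len <- function(x) {
    lead <- 0L
    while (lead < n && x[lead + 1L] == "-") lead <- lead + 1L
    trail <- 0L
    while (trail < n - lead && x[n - trail] == "-") trail <- trail + 1L
    c(lead, trail)
  }
  ra <- run_len(ac); rb <- run_len(bc)
  free <- rep(FALSE, n)
  if (ra[1]) free[seq_len(ra[1])] <- TRUE
  if (ra[2]) free[(n - ra[2] + 1L):n] <- TRUE
  if (rb[1]) free[seq_len(rb[1])] <- TRUE
  if (rb[2]) free[(n - rb[2] + 1L):n] <- TRUE
  s <- 0
  for (i in seq_len(n)) {
    if (free[i]) next
    ga <- ac[i] == "-"; gb <- bc[i] == "-"
    if (ga) {
      s <- s + if (i > 1L && ac[i - 1L] == "-") sc$gap_extend else sc$gap_open
    } else if (gb) {
      s <- s + if (i > 1L && bc[i - 1L] == "-") sc$gap_extend else sc$gap_open
    } else {
      hit <- length(intersect(oracle_base_set(ac[i]),
                              oracle_base_set(bc[i]))) > 0L
      s <- s + if (hit) sc$match else sc$mismatch
    }
  }
  s
}

# Best alignment score by exhaustive enumeration of every gapped alignment
# (monotone path through the edit graph), scoring each complete alignment
# with score_alignment_oracle. Exponential; for short sequences only.
best_score_oracle <- function(a, b, sc = alignment_scoring()) {
  am <- strsplit(a, "")[[1]]; bm <- strsplit(b, "")[[1]]
  n <- length(am); m <- length(bm)
  best <- -Inf
  rec <- function(i, j, acol, bcol) {
    if (i > n && j > m) {
      s <- score_alignment_oracle(acol, bcol, sc)
      if (s > best) best <<- s
      return(invisible(NULL))
    }
    if (i <= n && j <= m) rec(i + 1L, j + 1L, c(acol, am[i]), c(bcol, bm[j]))
    if (i <= n) rec(i + 1L, j, c(acol, am[i]), c(bcol, "-"))
    if (j <= m) rec(i, j + 1L, c(acol, "-"), c(bcol, bm[j]))
  }
  rec(1L, 1L, character(0), character(0))
  best
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# strip flanks from a generated record using the truth table
record_body <- function(ds, acc) {
  tr <- ds$truth[ds$truth$accession == acc, ]
  s <- ds$sequences[[acc]]
  substr(s, tr$flank5_len + 1L, nchar(s) - tr$flank3_len)
}

# run the full in-memory pipeline on a synthetic dataset
pipeline_from_dataset <- function(ds, scoring = alignment_scoring()) {
  alns <- lapply(names(ds$sequences), function(id)
    trim_homologous_region(
      global_align(ds$sequences[[id]], ds$reference, scoring = scoring,
                   sample_id = id)))
  names(alns) <- names(ds$sequences)
  msa <- build_anchored_msa(alns, ds$reference)
  cols <- detect_alteration_columns(msa)
  pm <- build_profile_matrix(cols, names(ds$sequences),
                             family = ds$family)
  list(alignments = alns, msa = msa, columns = cols, pm = pm)
}
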
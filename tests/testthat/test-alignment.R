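test_that("identity and single-substitution alignments behave as defined", {
  a <- global_align("ACGTACGTAC", "ACGTACGTAC")
  expect_equal(a$identity_fraction, 1)
  expect_equal(a$score, 10)
  expect_false(grepl("-", a$aligned_sample))
  expect_false(grepl("-", a$aligned_reference))
  expect_equal(a$region, c(0L, 10L))

  b <- global_align("ACGTTCGTAC", "ACGTACGTAC")
  expect_equal(b$identity_fraction, 0.9)
})

test_that("ambiguity codes are compatible with any constituent base", {
  # R = {A,G} against A: matched, not penalized
  a <- global_align("RCGT", "ACGT")
  expect_equal(a$identity_fraction, 1)
  expect_equal(a$score, 4)
  # but Y = {C,T} against A is a mismatch
  b <- global_align("YCGT", "ACGT")
  expect_equal(b$identity_fraction, 0.75)
})

test_that("DP score equals brute-force enumeration over all gapped alignments", {
  set.seed(421)
  lens <- list(c(1, 1), c(2, 3), c(3, 3), c(4, 2), c(4, 6), c(5, 5),
               c(6, 4), c(6, 6), c(7, 5), c(7, 7), c(8, 4), c(8, 3))
  for (ln in lens) {
    a <- random_dna(ln[1]); b <- random_dna(ln[2])
    expected <- best_score_oracle(a, b)
    got <- global_align(a, b)$score
    expect_equal(got, expected,
                 info = paste("pair", a, "/", b))
    # score symmetry
    expect_equal(global_align(b, a)$score, expected)
  }
})

test_that("emitted alignments score what the DP reports and recover the inputs", {
  set.seed(77)
  for (k in 1:10) {
    a <- random_dna(sample(5:40, 1)); b <- random_dna(sample(5:40, 1))
    aln <- global_align(a, b)
    ac <- strsplit(aln$aligned_sample, "")[[1]]
    bc <- strsplit(aln$aligned_reference, "")[[1]]
    expect_equal(length(ac), length(bc))
    expect_identical(paste(ac[ac != "-"], collapse = ""), a)
    expect_identical(paste(bc[bc != "-"], collapse = ""), b)
    expect_equal(score_alignment_oracle(ac, bc), aln$score)
  }
})

test_that("percent homology is the integer-rounded identity over the region", {
  expect_equal(percent_homology(global_align("ACGTACGTAC", "ACGTACGTAC")), 100)
  set.seed(11)
  ref <- random_dna(538)
  rc <- strsplit(ref, "")[[1]]
  mut <- rc
  idx <- c(50, 150, 250, 350, 450)
  for (p in idx) mut[p] <- setdiff(c("A", "C", "G", "T"), rc[p])[1]
  expect_equal(percent_homology(global_align(paste(mut, collapse = ""), ref)),
               99)  # 533/538
})

test_that("homology of noisy generated samples equals an independent recount", {
  cfg <- con2_family_config(seed = 5, background_rate = 0.07)
  cfg$length <- 333L  # fragment-scale check on a shorter monomer
  cfg$positions <- as.integer(floor(seq_len(8) * 333 / 9))
  ds <- generate_dataset(cfg)
  acc <- names(ds$sequences)[1]
  aln <- trim_homologous_region(
    global_align(ds$sequences[[acc]], ds$reference, sample_id = acc))
  ac <- strsplit(aln$aligned_sample, "")[[1]]
  bc <- strsplit(aln$aligned_reference, "")[[1]]
  inside <- satprof:::region_columns(list(a = ac, b = bc,
                                          ref_pos = {
                                            rp <- cumsum(bc != "-") - 1L
                                            rp[bc == "-"] <- NA_integer_
                                            rp
                                          }), aln$region)
  compat <- vapply(inside, function(i) {
    ac[i] != "-" && bc[i] != "-" &&
      length(intersect(oracle_base_set(ac[i]), oracle_base_set(bc[i]))) > 0
  }, TRUE)
  expect_equal(percent_homology(aln), round(100 * mean(compat)))
})

test_that("trimming leaves clean alignments alone and recovers flank bounds", {
  ref <- "ACGTACGTACGTACGTACGT"
  aln <- trim_homologous_region(global_align(ref, ref))
  expect_equal(aln$region, c(0L, 20L))
  expect_equal(aln$identity_fraction, 1)

  # noise-free synthetic CON2 records carry 20/18 bp primer flanks; the
  # trimmed homologous region must be exactly the full reference
  ds <- generate_dataset(con2_family_config(seed = 3))
  expect_equal(unique(ds$truth$flank5_len), 20L)
  expect_equal(unique(ds$truth$flank3_len), 18L)
  for (acc in names(ds$sequences)[c(1, 5, 13)]) {
    aln <- trim_homologous_region(
      global_align(ds$sequences[[acc]], ds$reference, sample_id = acc))
    expect_equal(aln$region, c(0L, 538L))
    expect_equal(aln$identity_fraction, 1)  # ambiguity-aware compatibility
  }
})

test_that("explicit flank lengths trim exactly", {
  set.seed(9)
  core <- random_dna(60)
  sample_seq <- paste0(random_dna(12), core, random_dna(7))
  aln <- global_align(sample_seq, core, sample_id = "s1")
  trimmed <- trim_homologous_region(aln, flank_lengths = c(12, 7))
  expect_equal(trimmed$region, c(0L, 60L))
  expect_error(trim_homologous_region(aln, flank_lengths = c(40, 40)),
               "s1")
})

test_that("anchored MSA projects samples onto reference coordinates", {
  ref <- "ACGTACGTACGTACGTACGTGCA"
  ident <- global_align(ref, ref, sample_id = "same")
  msa <- build_anchored_msa(list(same = ident), ref)
  expect_identical(paste(msa$states["same", ], collapse = ""), ref)

  # a single deletion appears as '-' at exactly the deleted position
  rc <- strsplit(ref, "")[[1]]
  del <- paste(rc[-10], collapse = "")
  alns <- list(same = ident,
               del = global_align(del, ref, sample_id = "del"))
  msa <- build_anchored_msa(alns, ref)
  expect_equal(which(msa$states["del", ] == "-"), 10L)
  expect_identical(paste(msa$states["del", -10], collapse = ""), del)

  # insertions relative to the reference are dropped and counted
  ins <- paste0(substr(ref, 1, 10), "TTTT", substr(ref, 11, nchar(ref)))
  expect_message(
    msa <- build_anchored_msa(list(ins = global_align(ins, ref,
                                                      sample_id = "ins")),
                              ref),
    "dropped")
  expect_equal(unname(msa$insertions_dropped["ins"]), 4L)
  expect_identical(paste(msa$states["ins", ], collapse = ""), ref)
})

test_that("anchored MSA dimensions match the noise-free CON2 dataset", {
  ds <- generate_dataset(con2_family_config(seed = 1))
  out <- pipeline_from_dataset(ds)
  expect_equal(dim(out$msa$states), c(13L, 538L))
  expect_equal(nchar(out$msa$reference), 538L)
})

test_that("alignments against a different reference are rejected", {
  a <- global_align("ACGTAC", "ACGTAC", sample_id = "x")
  expect_error(build_anchored_msa(list(x = a), "ACGTTT"),
               "different reference")
  b <- global_align("ACGTAC", "ACGTAC", sample_id = "x")
  expect_error(build_anchored_msa(list(x = a, x = b), "ACGTAC"),
               "duplicate")
})
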
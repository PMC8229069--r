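# Seeded generator of synthetic per-accession Sanger-style consensus
# sequences with planted alteration profiles, emulating PCR-amplified
# satellite DNA monomer fragments (CON1/CON2/COM2: 333/538/322 bp) with
# primer flanks, column-wise homozygous/heterozygous/triplet states, and
# optional background noise. Every emitted dataset carries a truth table.

# default fragment lengths per family
FAMILY_LENGTHS <- c(CON1 = 333L, CON2 = 538L, COM2 = 322L)

# the only primer pair printed for these assays; its forward sequence and
# the reverse-complement of its reverse sequence are reused as neutral
# flank material for all families
PRIMER_FLANK5 <- "CGGGATAGTACACTTTGGAC"
PRIMER_FLANK3 <- NULL  # computed below (revcomp of the reverse primer)

revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "")[[1]]),
        collapse = "")
}

# derive a reproducible 31-bit sub-seed for a named random substream
derive_seed <- function(seed, name) {
  h <- as.numeric(seed) %% 2147483647
  for (code in utf8ToInt(name)) h <- (h * 31 + code) %% 2147483647
  as.integer(max(h, 1))
}

# evaluate code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic family configuration
#'
#' Describes one satellite family's synthetic dataset: the reference
#' length, the planted alteration columns, the per-accession zygosity
#' profiles, primer flank sequences, and background noise rates. The
#' profile entries are zygosity words: `"hom_ref"` (reference allele),
#' `"het"` (two-base ambiguity of reference and alternative allele),
#' `"hom_alt"` (alternative allele), `"het3"` (three-base triplet
#' ambiguity), or `"missing"` (N). Each column's alternative allele is
#' drawn deterministically (the next base after the reference allele in
#' A-C-G-T cyclic order) and shared by all samples, so that zygosity — not
#' allele identity — drives the grouping.
#'
#' @param family Family name (`"CON1"`, `"CON2"`, `"COM2"`, or any label).
#' @param length Reference monomer length; defaults to 333/538/322 for
#'   CON1/CON2/COM2.
#' @param seed Integer seed; all randomness in the generated dataset flows
#'   from it through named substreams.
#' @param positions 0-based planted column positions (default: evenly
#'   spaced placeholders, `floor(k * length / (K + 1))`).
#' @param profiles Character matrix of zygosity words, one row per
#'   accession plus a row named `"reference"`, one column per planted
#'   column.
#' @param flank5,flank3 Flank sequences attached 5' and 3' of the monomer
#'   (default: the printed COM1 primer pair, forward sequence and
#'   reverse-complemented reverse sequence). Use `""` for none.
#' @param background_rate Per-position substitution probability outside
#'   planted columns (default 0).
#' @param indel_rate Per-position probability of a 1-bp indel outside
#'   planted columns (default 0).
#' @return A `family_config` object.
#' @export
family_config <- function(family, length = NULL, seed = 1L,
                          positions = NULL, profiles,
                          flank5 = PRIMER_FLANK5,
                          flank3 = revcomp("GGAGACCGATGGATTTTC"),
                          background_rate = 0, indel_rate = 0) {
  if (is.null(length))
    length <- unname(FAMILY_LENGTHS[family])
  if (is.null(length) || is.na(length) || length <= 0)
    stop("a positive reference length is required for family '", family,
         "'", call. = FALSE)
  stopifnot(is.matrix(profiles), "reference" %in% rownames(profiles))
  K <- ncol(profiles)
  if (is.null(positions))
    positions <- as.integer(floor(seq_len(K) * length / (K + 1)))
  if (length(positions) != K)
    stop("`positions` must have one entry per profile column", call. = FALSE)
  if (anyDuplicated(positions) || any(positions < 0) ||
      any(positions >= length))
    stop("planted positions must be unique and within [0, length)",
         call. = FALSE)
  if (background_rate < 0 || background_rate >= 1 ||
      indel_rate < 0 || indel_rate >= 1)
    stop("rates must lie in [0, 1)", call. = FALSE)
  bad <- setdiff(unique(as.vector(profiles)),
                 c("hom_ref", "het", "hom_alt", "het3", "missing"))
  if (length(bad))
    stop("unknown zygosity words: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(family = family, length = as.integer(length),
                 seed = as.integer(seed), positions = positions,
                 profiles = profiles, flank5 = flank5, flank3 = flank3,
                 background_rate = background_rate,
                 indel_rate = indel_rate),
            class = "family_config")
}

#' Generate the reference monomer sequence of a family configuration
#'
#' A pseudo-random canonical-base sequence of the configured length,
#' reproducible from the configuration seed.
#'
#' @param config A `family_config`.
#' @return Character string of A/C/G/T of length `config$length`.
#' @export
make_reference <- function(config) {
  stopifnot(inherits(config, "family_config"))
  with_seed(derive_seed(config$seed, paste0("reference:", config$family)), {
    paste(sample(DNA_BASES, config$length, replace = TRUE), collapse = "")
  })
}

# next base(s) after `base` in A-C-G-T cyclic order
next_base <- function(base, k = 1L) {
  DNA_BASES[((match(base, DNA_BASES) - 1L + k) %% 4L) + 1L]
}

# IUPAC code for a zygosity word given the column's reference allele
state_code <- function(word, ref_allele) {
  alt <- next_base(ref_allele)
  switch(word,
         hom_ref = ref_allele,
         hom_alt = alt,
         het = encode_set(c(ref_allele, alt)),
         het3 = encode_set(c(ref_allele, alt, next_base(ref_allele, 2L))),
         missing = "N",
         stop("unknown zygosity word: ", word, call. = FALSE))
}

#' Generate a synthetic consensus dataset with planted alteration profiles
#'
#' Emits one IUPAC-coded consensus per accession: the reference backbone
#' with each planted column substituted by the accession's configured
#' state, primer flanks attached, and background substitutions/indels
#' applied at the configured rates (never on planted columns, so the truth
#' table stays exact). The family reference consensus — the backbone with
#' the reference row's own states substituted — is emitted alongside.
#'
#' @param config A `family_config`.
#' @return A `synthetic_dataset`: `reference` (consensus string),
#'   `backbone` (canonical-base reference), named character vector
#'   `sequences`, data.frame `truth` (per accession: flank lengths,
#'   background-mutation positions, planted state codes), and the config.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "family_config"))
  backbone <- strsplit(make_reference(config), "")[[1]]
  pos1 <- config$positions + 1L                   # 1-based backbone index
  ref_alleles <- backbone[pos1]
  samples <- setdiff(rownames(config$profiles), "reference")

  plant <- function(row_states) {
    s <- backbone
    if (length(pos1))
      s[pos1] <- mapply(state_code, row_states, ref_alleles)
    s
  }
  ref_chars <- plant(config$profiles["reference", ])

  sequences <- character(0)
  truth <- list()
  for (acc in samples) {
    s <- plant(config$profiles[acc, ])
    free <- setdiff(seq_along(s), pos1)
    sub_pos <- integer(0); indel_pos <- integer(0)
    if (config$background_rate > 0 || config$indel_rate > 0) {
      with_seed(derive_seed(config$seed, paste0("noise:", acc)), {
        if (config$background_rate > 0) {
          sub_pos <- sort(free[stats::runif(length(free)) <
                                  config$background_rate])
          for (p in sub_pos)
            s[p] <- sample(setdiff(DNA_BASES, s[p]), 1L)
        }
        if (config$indel_rate > 0) {
          indel_pos <- sort(free[stats::runif(length(free)) <
                                    config$indel_rate])
          out <- as.list(s)
          for (p in indel_pos) {
            if (stats::runif(1) < 0.5) out[[p]] <- character(0)  # deletion
            else out[[p]] <- c(out[[p]], sample(DNA_BASES, 1L))  # insertion
          }
          s <- unlist(out)
        }
      })
    }
    sequences[[acc]] <- paste0(config$flank5, paste(s, collapse = ""),
                               config$flank3)
    truth[[acc]] <- data.frame(
      accession = acc,
      flank5_len = nchar(config$flank5),
      flank3_len = nchar(config$flank3),
      n_background = length(sub_pos),
      background_positions = paste(sub_pos - 1L, collapse = ","),
      n_indels = length(indel_pos),
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  if (length(pos1)) {
    planted <- t(vapply(samples, function(acc)
      mapply(state_code, config$profiles[acc, ], ref_alleles),
      character(length(pos1))))
    colnames(planted) <- paste0("col_", seq_along(pos1))
    truth <- cbind(truth, as.data.frame(planted, stringsAsFactors = FALSE))
  }

  structure(list(family = config$family,
                 reference = paste(ref_chars, collapse = ""),
                 backbone = paste(backbone, collapse = ""),
                 positions = config$positions,
                 ref_alleles = ref_alleles,
                 sequences = sequences,
                 truth = truth,
                 config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic ", x$family, " dataset: ", length(x$sequences),
      " accessions, reference ", nchar(x$reference), " bp, ",
      length(x$positions), " planted columns\n", sep = "")
  invisible(x)
}

#' Write a truth table as TSV
#'
#' @param dataset A `synthetic_dataset`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(dataset, path) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  write.table(dataset$truth, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
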
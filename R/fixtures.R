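# Packaged fixtures: the fully text-specified CON2 worked example (8
# alteration columns, 13 samples, four profile groups) and synthetic-style
# configurations for CON1 (11 columns, trio profile, triplet states) and
# COM2 (9 columns, 6 samples, all profiles unique). Base identities and
# column positions in all of these are synthetic conventions; the zygosity
# structure and group memberships are the documented facts.

#' Studied accessions
#'
#' The accession metadata table (id, species, catalog number, origin) for
#' the eleven Deschampsia accessions and three accessions from related
#' genera under study.
#'
#' @return A data.frame with columns `accession_id`, `species`, `catalog`,
#'   `origin`.
#' @export
accession_table <- function() {
  read.delim(system.file("extdata", "accessions.tsv", package = "satprof"),
             stringsAsFactors = FALSE)
}

#' The CON2 worked-example fixture
#'
#' Loads the packaged CON2 zygosity fixture: 8 alteration columns over 13
#' samples plus the reference consensus row, with the four documented
#' profile groups (sizes 4/6/2/1) and the per-group match/difference
#' counts against the reference profile.
#'
#' @return A list: `family`, `length`, `zygosity` (character matrix of
#'   zygosity words, rows = reference + samples), `samples`, `groups`
#'   (list of member id vectors), `reference_vs_group`.
#' @export
con2_fixture <- function() {
  tsv <- system.file("extdata", "con2_fixture.tsv", package = "satprof")
  js <- system.file("extdata", "con2_fixture.json", package = "satprof")
  tab <- read.delim(tsv, comment.char = "#", stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  zyg <- as.matrix(tab[, grep("^c[0-9]+$", names(tab))])
  rownames(zyg) <- tab$sample
  list(family = meta$family,
       length = meta$fragment_length,
       zygosity = zyg,
       samples = setdiff(tab$sample, "reference"),
       groups = lapply(meta$groups, unlist),
       reference_vs_group = meta$reference_vs_group)
}

#' Synthetic family configurations for the three studied families
#'
#' `con2_family_config()` wraps the packaged CON2 fixture in a generator
#' configuration (538-bp reference, 8 planted columns). The CON1 and COM2
#' base matrices are not text-reconstructable, so
#' `con1_style_config()` builds an 11-column, 13-sample configuration with
#' the documented structure — one shared profile for the two remaining
#' D. antarctica accessions plus D. parvula, one extra alteration for
#' D. antarctica KEW-0521613, unique profiles for the rest, and triplet
#' (three-base) heterozygous states for D. sukatschewii, D. cespitosa
#' PI-371724 and PI-562652, and H. pubescens — and `com2_style_config()`
#' a 9-column, 6-sample configuration in which every profile is unique.
#'
#' @param seed Integer seed driving the generated reference and any noise.
#' @param ... Further arguments passed to [family_config()]
#'   (e.g. `background_rate`).
#' @return A `family_config`.
#' @export
con2_family_config <- function(seed = 1L, ...) {
  fx <- con2_fixture()
  family_config("CON2", length = fx$length, seed = seed,
                profiles = fx$zygosity, ...)
}

#' @rdname con2_family_config
#' @export
con1_style_config <- function(seed = 1L, ...) {
  samples <- c("Da_KEW-0522816", "Da_KEW-0661919", "Da_KEW-0521613",
               "Dp_KEW-0661849", "Ds_78", "Dc_PI-562652", "Dc_PI-577069",
               "Dc_PI-371724", "De_PI-665545", "Df_PI-577075",
               "Dd_W6-39054", "Hp_KEW-065160", "Km_KEW-0096838")
  K <- 11L
  prof <- matrix("hom_ref", nrow = length(samples) + 1L, ncol = K,
                 dimnames = list(c("reference", samples), NULL))
  trio <- c("Da_KEW-0522816", "Da_KEW-0661919", "Dp_KEW-0661849")
  prof[trio, 1] <- "het"; prof[trio, 2] <- "hom_alt"
  prof["Da_KEW-0521613", c(1, 2)] <- c("het", "hom_alt")
  prof["Da_KEW-0521613", 3] <- "het"            # the one distinct alteration
  prof["Ds_78", 4] <- "het3"
  prof["Dc_PI-562652", 5] <- "het3"
  prof["Dc_PI-577069", 6] <- "hom_alt"
  prof["Dc_PI-371724", 7] <- "het3"
  prof["De_PI-665545", 8] <- "hom_alt"
  prof["Df_PI-577075", 9] <- "het"
  prof["Dd_W6-39054", 10] <- "hom_alt"
  prof["Hp_KEW-065160", 11] <- "het3"
  prof["Km_KEW-0096838", 1] <- "hom_alt"
  family_config("CON1", seed = seed, profiles = prof, ...)
}

#' @rdname con2_family_config
#' @export
com2_style_config <- function(seed = 1L, ...) {
  samples <- c("Dc_PI-577069", "Dc_PI-562652", "Dp_KEW-0661849",
               "Df_PI-577075", "Km_KEW-0096838", "Tp_KEW-0662385")
  K <- 9L
  prof <- matrix("hom_ref", nrow = length(samples) + 1L, ncol = K,
                 dimnames = list(c("reference", samples), NULL))
  for (i in seq_along(samples)) prof[samples[i], i] <- "hom_alt"
  prof["Dc_PI-577069", 7] <- "het"
  prof["Dc_PI-562652", 8] <- "het"
  prof["Dp_KEW-0661849", 9] <- "het"
  family_config("COM2", seed = seed, profiles = prof, ...)
}

#' Profile matrix encoded directly from a zygosity fixture
#'
#' Builds a `profile_matrix` from a zygosity-word matrix without going
#' through sequence simulation and alignment, using the package's allele
#' convention: column k's reference allele cycles through A/C/G/T and the
#' shared alternative allele is the next base in that order. Useful for
#' running the partition on the worked example directly.
#'
#' @param zygosity Character matrix of zygosity words with a
#'   `"reference"` row.
#' @param family Optional family label.
#' @param length Reference length used for the evenly spaced placeholder
#'   positions (default 100 * K).
#' @return A `profile_matrix`.
#' @export
fixture_profile_matrix <- function(zygosity, family = NULL, length = NULL) {
  stopifnot(is.matrix(zygosity), "reference" %in% rownames(zygosity))
  K <- ncol(zygosity)
  if (is.null(length)) length <- 100L * K
  positions <- as.integer(floor(seq_len(K) * length / (K + 1)))
  ref_alleles <- DNA_BASES[((seq_len(K) - 1L) %% 4L) + 1L]
  samples <- setdiff(rownames(zygosity), "reference")
  to_codes <- function(row)
    mapply(state_code, zygosity[row, ], ref_alleles, USE.NAMES = FALSE)
  states <- t(vapply(samples, to_codes, character(K)))
  colnames(states) <- if (K) paste0("c", seq_len(K))
  ref_states <- to_codes("reference")
  zyg <- states
  for (k in seq_len(K)) {
    rb <- base_set(ref_states[k])[1]
    zyg[, k] <- vapply(states[, k], classify_state, "", ref = rb)
  }
  structure(list(family = family, reference_id = "reference",
                 sample_ids = samples, ref_positions = positions,
                 ref_states = ref_states, states = states,
                 zygosity = zyg),
            class = "profile_matrix")
}
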
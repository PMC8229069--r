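# IUPAC nucleotide code algebra and zygosity classification.
#
# A Sanger consensus base call is one character over the 15-letter IUPAC
# nucleotide alphabet. Its base set (size 1-4) carries the zygosity
# semantics used throughout the package: size 1 = homozygous call, size 2 =
# heterozygous, size 3 = "triplet" heterozygous, size 4 (N) = no call.

DNA_BASES <- c("A", "C", "G", "T")

# code -> sorted base vector; the 15 valid codes
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
  W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# set key ("A|G") -> code, inverse of .IUPAC_SETS
.IUPAC_CODES <- local({
  keys <- vapply(.IUPAC_SETS, paste, "", collapse = "|")
  setNames(names(.IUPAC_SETS), keys)
})

# bitmask encoding (A=1, C=2, G=4, T=8) used by the aligner
.IUPAC_MASKS <- local({
  base_bit <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  vapply(.IUPAC_SETS, function(b) sum(base_bit[b]), 0L)
})

#' Zygosity labels
#'
#' The six zygosity states a consensus call can take relative to a canonical
#' reference base: `HOM_REF` (single base equal to the reference), `HOM_ALT`
#' (single base differing), `HET_WITH_REF` (two-base ambiguity containing
#' the reference base), `HET_ALT_ONLY` (two-base ambiguity without it),
#' `HET3` (three-base "triplet" ambiguity), and `MISSING` (N or gap: no
#' base call asserted).
#'
#' @format A character vector of the six labels.
#' @export
ZYGOSITY_LEVELS <- c("HOM_REF", "HOM_ALT", "HET_WITH_REF",
                     "HET_ALT_ONLY", "HET3", "MISSING")

# Normalize a vector of single characters: uppercase, U -> T (warn once).
# Characters in `extra` (e.g. "-", ".") pass through; anything else errors
# with the offending character and its position.
normalize_iupac <- function(chars, extra = character(0), context = "sequence") {
  chars <- toupper(chars)
  if (any(chars == "U")) {
    warning("'U' mapped to 'T' in ", context, " (DNA space)", call. = FALSE)
    chars[chars == "U"] <- "T"
  }
  bad <- which(!(chars %in% names(.IUPAC_SETS)) & !(chars %in% extra))
  if (length(bad)) {
    stop("invalid IUPAC character '", chars[bad[1]], "' at position ",
         bad[1], " in ", context, call. = FALSE)
  }
  chars
}

#' Base set denoted by an IUPAC code
#'
#' @param code A single IUPAC nucleotide character (case-insensitive;
#'   `"U"` is accepted and mapped to `"T"` with a warning).
#' @return Character vector of the canonical bases the code denotes,
#'   in alphabetical order (length 1-4).
#' @examples
#' base_set("R")  # "A" "G"
#' base_set("B")  # "C" "G" "T"
#' @export
base_set <- function(code) {
  if (!is.character(code) || length(code) != 1L || nchar(code) != 1L)
    stop("`code` must be a single character", call. = FALSE)
  code <- normalize_iupac(code, context = "code")
  .IUPAC_SETS[[code]]
}

#' Encode a base set as an IUPAC code
#'
#' Inverse of [base_set()]: `encode_set(base_set(c)) == c` for all 15 codes.
#'
#' @param bases Nonempty character vector of canonical bases (A/C/G/T),
#'   duplicates allowed.
#' @return The single IUPAC character denoting exactly that set.
#' @examples
#' encode_set(c("A", "G"))       # "R"
#' encode_set(c("C", "G", "T"))  # "B"
#' @export
encode_set <- function(bases) {
  bases <- unique(toupper(bases))
  if (length(bases) == 0L)
    stop("empty base set cannot be encoded", call. = FALSE)
  if (!all(bases %in% DNA_BASES))
    stop("base set may only contain A, C, G, T; got: ",
         paste(setdiff(bases, DNA_BASES), collapse = ", "), call. = FALSE)
  unname(.IUPAC_CODES[paste(sort(bases), collapse = "|")])
}

#' Classify the zygosity of a consensus state against a reference base
#'
#' A single-base call equal to the reference is `HOM_REF`; a single-base
#' call differing is `HOM_ALT`; a two-base ambiguity containing the
#' reference is `HET_WITH_REF`, otherwise `HET_ALT_ONLY`; a three-base
#' ambiguity is `HET3` (a "triplet" state); `N` and the gap character
#' `"-"` assert no base call and classify as `MISSING`.
#'
#' @param state A single IUPAC character, or `"-"` for a gap, or `"."` for
#'   an uncovered position.
#' @param ref A single canonical base (A/C/G/T).
#' @return One of [ZYGOSITY_LEVELS].
#' @examples
#' classify_state("A", "A")  # HOM_REF
#' classify_state("R", "A")  # HET_WITH_REF
#' classify_state("B", "A")  # HET3
#' @export
classify_state <- function(state, ref) {
  ref <- toupper(ref)
  if (!(is.character(ref) && length(ref) == 1L && ref %in% DNA_BASES))
    stop("`ref` must be a single canonical base (A/C/G/T)", call. = FALSE)
  state <- normalize_iupac(state, extra = c("-", "."), context = "state")
  if (state %in% c("-", ".", "N")) return("MISSING")
  set <- .IUPAC_SETS[[state]]
  n <- length(set)
  if (n == 1L) {
    if (set == ref) "HOM_REF" else "HOM_ALT"
  } else if (n == 2L) {
    if (ref %in% set) "HET_WITH_REF" else "HET_ALT_ONLY"
  } else {
    "HET3"
  }
}

# TRUE where a character asserts no base call (gap, uncovered, or N)
is_missing_state <- function(chars) chars %in% c("-", ".", "N")

# Integer bitmasks for a character vector of IUPAC codes (A=1,C=2,G=4,T=8)
iupac_masks <- function(chars) unname(.IUPAC_MASKS[chars])
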
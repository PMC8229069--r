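# Ambiguity-aware semi-global alignment of a monomer consensus to the
# family reference, percent-identity ("homology") computation, trimming of
# the homologous region, and reference-anchored multiple alignment.

#' Default alignment scoring parameters
#'
#' Match +1 (two states match iff their IUPAC base sets intersect, so a
#' heterozygous consensus call is never penalized against a reference
#' allele it contains), mismatch -1, gap open -2 (cost of the first gap
#' column of a run), gap extend -0.5 (each further column). Terminal gap
#' runs are free: the alignment is global but end-gap-free (semi-global),
#' appropriate for near-full-length monomer fragments with primer flanks.
#'
#' @return Named list with `match`, `mismatch`, `gap_open`, `gap_extend`.
#' @export
alignment_scoring <- function() {
  list(match = 1, mismatch = -1, gap_open = -2, gap_extend = -0.5)
}

#' Global (end-gap-free) pairwise alignment to a reference monomer
#'
#' Aligns an IUPAC-coded sample consensus to the family reference with the
#' Gotoh affine-gap dynamic program. The score is the maximum over all
#' gapped alignments under [alignment_scoring()]; the traceback tie-break
#' (diagonal over up over left) makes the emitted alignment deterministic.
#'
#' @param sample,reference Nonempty IUPAC nucleotide strings.
#' @param scoring Scoring parameters, as [alignment_scoring()].
#' @param sample_id Optional label carried through to error messages and
#'   downstream objects.
#' @return A `pairwise_alignment` object: equal-length `aligned_sample` and
#'   `aligned_reference` strings (`"-"` for gaps), `score`,
#'   `identity_fraction`, and `region`, the 0-based half-open interval of
#'   reference coordinates covered by the homologous region.
#' @seealso [percent_homology()], [trim_homologous_region()]
#' @export
global_align <- function(sample, reference, scoring = alignment_scoring(),
                         sample_id = NULL) {
  stopifnot(is.character(sample), length(sample) == 1L,
            is.character(reference), length(reference) == 1L)
  if (nchar(sample) == 0L || nchar(reference) == 0L)
    stop("sequences must be nonempty", call. = FALSE)
  a <- normalize_iupac(strsplit(sample, "")[[1]],
                       context = paste0("sample", if (!is.null(sample_id))
                         paste0(" '", sample_id, "'")))
  b <- normalize_iupac(strsplit(reference, "")[[1]], context = "reference")
  res <- align_semiglobal_c(iupac_masks(a), iupac_masks(b),
                            scoring$match, scoring$mismatch,
                            scoring$gap_open, scoring$gap_extend)

  # assemble full aligned strings: leading overhangs, core, trailing
  al <- character(0); bl <- character(0)
  if (res$start_j > 0) {                      # unaligned reference prefix
    al <- c(al, rep("-", res$start_j)); bl <- c(bl, b[seq_len(res$start_j)])
  }
  if (res$start_i > 0) {                      # unaligned sample prefix
    al <- c(al, a[seq_len(res$start_i)]); bl <- c(bl, rep("-", res$start_i))
  }
  core_a <- ifelse(res$a_idx == 0L, "-", a[pmax(res$a_idx, 1L)])
  core_b <- ifelse(res$b_idx == 0L, "-", b[pmax(res$b_idx, 1L)])
  al <- c(al, core_a); bl <- c(bl, core_b)
  if (res$end_i < length(a)) {
    al <- c(al, a[(res$end_i + 1L):length(a)])
    bl <- c(bl, rep("-", length(a) - res$end_i))
  }
  if (res$end_j < length(b)) {
    al <- c(al, rep("-", length(b) - res$end_j))
    bl <- c(bl, b[(res$end_j + 1L):length(b)])
  }

  aln <- structure(list(
    sample_id = sample_id,
    aligned_sample = paste(al, collapse = ""),
    aligned_reference = paste(bl, collapse = ""),
    score = res$score,
    reference_length = length(b),
    region = NULL, identity_fraction = NULL,
    scoring = scoring), class = "pairwise_alignment")
  initial_region(aln)
}

# column-level view of an alignment: characters, 0-based ref position per
# column (NA for gap-in-reference columns), sample non-gap flag
alignment_columns <- function(aln) {
  ac <- strsplit(aln$aligned_sample, "")[[1]]
  bc <- strsplit(aln$aligned_reference, "")[[1]]
  ref_pos <- cumsum(bc != "-") - 1L
  ref_pos[bc == "-"] <- NA_integer_
  list(a = ac, b = bc, ref_pos = ref_pos)
}

# homologous region before trimming: reference span between the first and
# last alignment column where the sample has a character
initial_region <- function(aln) {
  cols <- alignment_columns(aln)
  covered <- which(cols$a != "-")
  span <- covered[1]:covered[length(covered)]
  rp <- cols$ref_pos[span]
  rp <- rp[!is.na(rp)]
  if (length(rp) == 0L) {
    aln$region <- c(0L, 0L)
    aln$identity_fraction <- NA_real_
    return(aln)
  }
  set_region(aln, c(min(rp), max(rp) + 1L))
}

# restrict the region and recompute identity over columns inside it
set_region <- function(aln, region) {
  cols <- alignment_columns(aln)
  inside <- region_columns(cols, region)
  aln$region <- as.integer(region)
  if (length(inside) == 0L) {
    aln$identity_fraction <- NA_real_
  } else {
    aln$identity_fraction <- mean(compatible_columns(cols)[inside])
  }
  aln
}

# alignment column indices lying inside a 0-based half-open ref interval;
# gap-in-reference (sample insertion) columns belong to the region iff they
# fall strictly between covered reference positions (terminal sample
# overhangs, which sit before the first or after the last reference
# position of the region, are outside)
region_columns <- function(cols, region) {
  if (region[2] <= region[1]) return(integer(0))
  pos <- cols$ref_pos
  # insertion columns inherit the position of the next reference column
  filled <- rev(cummin(rev(ifelse(is.na(pos), .Machine$integer.max, pos))))
  which((!is.na(pos) & pos >= region[1] & pos < region[2]) |
          (is.na(pos) & filled > region[1] & filled < region[2]))
}

# per-column compatibility: both non-gap and base sets intersect
compatible_columns <- function(cols) {
  ok <- cols$a != "-" & cols$b != "-"
  comp <- logical(length(cols$a))
  comp[ok] <- bitwAnd(iupac_masks(cols$a[ok]), iupac_masks(cols$b[ok])) > 0L
  comp
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Pairwise monomer alignment",
      if (!is.null(x$sample_id)) paste0(" (", x$sample_id, ")"), "\n",
      "  score: ", x$score,
      ", identity: ", round(100 * x$identity_fraction, 1), "%",
      ", homologous region: [", x$region[1], ", ", x$region[2], ")\n",
      sep = "")
  invisible(x)
}

#' Percent homology of an alignment
#'
#' The percent identity over the homologous region, rounded to the nearest
#' integer percent (the granularity at which BLAST-style homology figures
#' such as 93% or 98-99% are conventionally reported).
#'
#' @param aln A `pairwise_alignment`.
#' @return Integer percentage, or `NA` (with a warning) when the
#'   homologous region is empty.
#' @export
percent_homology <- function(aln) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  if (is.na(aln$identity_fraction)) {
    warning("empty homologous region: homology undefined", call. = FALSE)
    return(NA_real_)
  }
  round(100 * aln$identity_fraction)
}

#' Trim the homologous region of an alignment
#'
#' Shrinks the homologous region to exclude terminal columns attributable
#' to primer flanks or ragged fragment ends. Either rule can be used:
#' by default, columns are trimmed from each end while the identity of the
#' terminal window of `window` alignment columns is below
#' `min_flank_identity`; alternatively, explicit `flank_lengths = c(f5, f3)`
#' removes the reference span aligned to the first `f5` and last `f3`
#' sample characters exactly (for runs where primer lengths are known).
#'
#' @param aln A `pairwise_alignment`.
#' @param min_flank_identity Identity threshold for the terminal window
#'   (default 0.5).
#' @param window Terminal window size in alignment columns (default 10).
#' @param flank_lengths Optional integer pair: exact 5' and 3' flank
#'   lengths in sample characters.
#' @return The alignment with `region` and `identity_fraction` updated.
#' @export
trim_homologous_region <- function(aln, min_flank_identity = 0.5,
                                   window = 10L, flank_lengths = NULL) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  cols <- alignment_columns(aln)
  if (!is.null(flank_lengths)) {
    stopifnot(length(flank_lengths) == 2L, all(flank_lengths >= 0))
    a_ord <- cumsum(cols$a != "-")            # sample characters consumed
    n_a <- max(a_ord)
    keep <- which(cols$a != "-" & a_ord > flank_lengths[1] &
                    a_ord <= n_a - flank_lengths[2])
    rp <- cols$ref_pos[keep]
    rp <- rp[!is.na(rp)]
    if (length(rp) == 0L)
      stop("homologous region collapsed to empty",
           if (!is.null(aln$sample_id)) paste0(" for sample '", aln$sample_id, "'"),
           call. = FALSE)
    region <- c(max(min(rp), aln$region[1]), min(max(rp) + 1L, aln$region[2]))
    return(set_region(aln, region))
  }

  comp <- compatible_columns(cols)
  inside <- region_columns(cols, aln$region)
  lo <- 1L; hi <- length(inside)
  repeat {
    if (lo > hi) break
    w <- inside[lo:min(lo + window - 1L, hi)]
    if (mean(comp[w]) < min_flank_identity) { lo <- lo + 1L; next }
    w <- inside[max(hi - window + 1L, lo):hi]
    if (mean(comp[w]) < min_flank_identity) { hi <- hi - 1L; next }
    break
  }
  if (lo > hi)
    stop("homologous region collapsed to empty",
         if (!is.null(aln$sample_id)) paste0(" for sample '", aln$sample_id, "'"),
         call. = FALSE)
  rp <- cols$ref_pos[inside[lo:hi]]
  rp <- rp[!is.na(rp)]
  set_region(aln, c(min(rp), max(rp) + 1L))
}

#' Reference-anchored multiple alignment
#'
#' Projects each pairwise alignment onto reference coordinates: the result
#' has one row per sample over exactly the reference positions. Within a
#' sample's homologous region a deletion appears as `"-"`; positions
#' outside the region or never aligned are uncovered (`"."`, treated as
#' missing downstream). Sample insertions relative to the reference have no
#' reference coordinate and are dropped from the matrix; the number dropped
#' per sample is recorded in the `insertions_dropped` field and reported
#' via `message()`.
#'
#' @param alignments List of `pairwise_alignment` objects sharing one
#'   reference (named by sample, or carrying `sample_id`s).
#' @param reference The reference sequence string the alignments were
#'   built against.
#' @return An `anchored_msa` object: `reference` string, character matrix
#'   `states` (samples x reference positions), logical `coverage` mask,
#'   and `insertions_dropped`.
#' @export
build_anchored_msa <- function(alignments, reference) {
  stopifnot(length(alignments) >= 1L)
  ref_chars <- normalize_iupac(strsplit(reference, "")[[1]],
                               context = "reference")
  L <- length(ref_chars)
  ids <- names(alignments)
  if (is.null(ids))
    ids <- vapply(alignments, function(a) a$sample_id %||% NA_character_, "")
  if (anyNA(ids) || any(ids == ""))
    stop("every alignment must be named or carry a sample_id", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate accession ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)

  states <- matrix(".", nrow = length(alignments), ncol = L,
                   dimnames = list(ids, NULL))
  dropped <- setNames(integer(length(alignments)), ids)
  for (k in seq_along(alignments)) {
    aln <- alignments[[k]]
    stopifnot(inherits(aln, "pairwise_alignment"))
    cols <- alignment_columns(aln)
    if (paste(cols$b[cols$b != "-"], collapse = "") !=
        paste(ref_chars, collapse = ""))
      stop("alignment for '", ids[k],
           "' was built against a different reference", call. = FALSE)
    inside <- region_columns(cols, aln$region)
    ins <- inside[is.na(cols$ref_pos[inside])]
    dropped[k] <- length(ins)
    keep <- inside[!is.na(cols$ref_pos[inside])]
    states[k, cols$ref_pos[keep] + 1L] <- cols$a[keep]
  }
  if (any(dropped > 0))
    message("dropped sample insertions relative to the reference: ",
            paste0(names(dropped)[dropped > 0], "=",
                   dropped[dropped > 0], collapse = ", "))
  structure(list(reference = paste(ref_chars, collapse = ""),
                 states = states,
                 coverage = states != ".",
                 insertions_dropped = dropped),
            class = "anchored_msa")
}

#' @export
print.anchored_msa <- function(x, ...) {
  cat("Reference-anchored MSA: ", nrow(x$states), " samples x ",
      ncol(x$states), " reference positions\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
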
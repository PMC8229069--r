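# FASTA input/output for monomer consensus records (full IUPAC alphabet),
# via Biostrings.

#' Read per-accession monomer consensus records from FASTA
#'
#' Accepts wrapped or unwrapped standard FASTA. The accession id is the
#' first whitespace-delimited token of each header; the remainder is kept
#' as the description (typically the species label). Sequences are
#' validated against the IUPAC alphabet, upper-cased, and `U` is mapped
#' to `T`.
#'
#' @param path FASTA file path.
#' @return A data.frame with columns `accession_id`, `description`,
#'   `sequence`.
#' @export
read_monomer_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L)
    stop("no FASTA records in '", path, "'", call. = FALSE)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate accession ids in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  seqs <- as.character(set)
  seqs <- vapply(seq_along(seqs), function(i) {
    if (nchar(seqs[i]) == 0L)
      stop("empty sequence for accession '", ids[i], "'", call. = FALSE)
    paste(normalize_iupac(strsplit(seqs[i], "")[[1]], extra = c("-", "."),
                          context = paste0("record '", ids[i], "'")),
          collapse = "")
  }, "")
  data.frame(accession_id = ids, description = desc, sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Write monomer consensus records to FASTA
#'
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @param descriptions Optional named character vector appended to the
#'   headers after the accession id.
#' @return `path`, invisibly.
#' @export
write_monomer_fasta <- function(sequences, path, descriptions = NULL) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  headers <- names(sequences)
  if (!is.null(descriptions)) {
    extra <- descriptions[headers]
    headers <- ifelse(is.na(extra) | extra == "", headers,
                      paste(headers, extra))
  }
  set <- Biostrings::BStringSet(unname(sequences))
  names(set) <- headers
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a reference-anchored MSA as aligned FASTA
#'
#' The reference row is written first; uncovered sample positions appear
#' as `"."` and deletions as `"-"`.
#'
#' @param msa An `anchored_msa`.
#' @param path Output path.
#' @param reference_id Header for the reference row.
#' @return `path`, invisibly.
#' @export
write_msa_fasta <- function(msa, path, reference_id = "reference") {
  stopifnot(inherits(msa, "anchored_msa"))
  rows <- c(setNames(msa$reference, reference_id),
            setNames(apply(msa$states, 1L, paste, collapse = ""),
                     rownames(msa$states)))
  write_monomer_fasta(rows, path)
}
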
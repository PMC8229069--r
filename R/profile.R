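# Detection of single-nucleotide alteration columns in a reference-anchored
# MSA and construction of the per-sample alteration-profile matrix.

#' Detect single-nucleotide alteration columns
#'
#' An alteration column is a reference position where at least one sample's
#' called base set differs from the reference state's base set. Missing
#' states (uncovered positions, deletions, and `N`) assert no base call and
#' never trigger a column by themselves; a heterozygous call whose set
#' properly contains the reference base does (its set differs). Columns are
#' numbered 1..K in reference-position order — the "column #k" convention
#' used when reporting.
#'
#' @param msa An `anchored_msa`.
#' @return List of `alteration_column` objects, each with `index`,
#'   `reference_position` (0-based), `reference_state`, and named
#'   `states`/`zygosity` vectors over all samples. Zygosity is classified
#'   against the reference state's designated base (the alphabetically
#'   first base of its set when the reference call is itself ambiguous).
#' @export
detect_alteration_columns <- function(msa) {
  stopifnot(inherits(msa, "anchored_msa"), nrow(msa$states) >= 1L)
  ref_chars <- strsplit(msa$reference, "")[[1]]
  cols <- list()
  for (p in seq_along(ref_chars)) {
    ref_state <- ref_chars[p]
    if (is_missing_state(ref_state)) next
    st <- msa$states[, p]
    called <- !is_missing_state(st)
    if (!any(called)) next
    if (!any(st[called] != ref_state)) next   # code equality == set equality
    ref_base <- base_set(ref_state)[1]
    zyg <- vapply(st, classify_state, "", ref = ref_base)
    cols[[length(cols) + 1L]] <- structure(list(
      index = length(cols) + 1L,
      reference_position = p - 1L,
      reference_state = ref_state,
      states = st,
      zygosity = zyg), class = "alteration_column")
  }
  if (length(cols) >= 2L) {
    pos <- vapply(cols, `[[`, 0L, "reference_position")
    if (any(diff(pos) == 1L))
      message("adjacent alteration columns at reference positions ",
              paste(pos[which(diff(pos) == 1L)], collapse = ", "),
              " (reported as separate columns)")
  }
  cols
}

#' Build the alteration-profile matrix
#'
#' Assembles detected columns into a complete matrix over all samples, with
#' the reference profile carried as a distinguished row. Column indices are
#' 1..K in reference-position order.
#'
#' @param columns List of `alteration_column`s from one family's MSA.
#' @param samples Character vector of accession ids fixing the sample
#'   order; must be duplicate-free and cover every id in the columns.
#' @param family Optional family label (e.g. `"CON2"`).
#' @param reference_id Label for the reference row (default `"reference"`).
#' @return A `profile_matrix`: character matrix `states`
#'   (samples x columns, IUPAC codes with `"."`/`"-"` for missing), matrix
#'   `zygosity`, vectors `ref_positions` and `ref_states`, and metadata.
#' @export
build_profile_matrix <- function(columns, samples, family = NULL,
                                 reference_id = "reference") {
  if (anyDuplicated(samples))
    stop("duplicate accession ids: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  K <- length(columns)
  states <- matrix(".", nrow = length(samples), ncol = K,
                   dimnames = list(samples, if (K) paste0("c", seq_len(K))))
  zygosity <- matrix("MISSING", nrow = length(samples), ncol = K,
                     dimnames = dimnames(states))
  ref_positions <- integer(K)
  ref_states <- character(K)
  for (k in seq_len(K)) {
    col <- columns[[k]]
    if (!all(samples %in% names(col$states)) &&
        !all(names(col$states) %in% samples))
      stop("column sample ids do not match `samples`", call. = FALSE)
    present <- intersect(samples, names(col$states))
    states[present, k] <- col$states[present]
    zygosity[present, k] <- col$zygosity[present]
    ref_positions[k] <- col$reference_position
    ref_states[k] <- col$reference_state
  }
  structure(list(family = family,
                 reference_id = reference_id,
                 sample_ids = samples,
                 ref_positions = ref_positions,
                 ref_states = ref_states,
                 states = states,
                 zygosity = zygosity),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("Alteration-profile matrix",
      if (!is.null(x$family)) paste0(" [", x$family, "]"), ": ",
      length(x$sample_ids), " samples x ", length(x$ref_positions),
      " columns\n", sep = "")
  if (length(x$ref_positions)) {
    m <- rbind(x$ref_states, x$states)
    rownames(m) <- c(x$reference_id, x$sample_ids)
    colnames(m) <- paste0("#", seq_along(x$ref_positions))
    print(m, quote = FALSE)
  }
  invisible(x)
}

#' Write / read a profile matrix as TSV
#'
#' One row per sample (the reference row first), one column per alteration
#' index, cells holding IUPAC codes (`"."` uncovered, `"-"` deleted). The
#' header row carries the 0-based reference positions; leading `#` comment
#' lines carry the family and reference id. `read_profile_tsv()` inverts
#' `write_profile_tsv()` exactly.
#'
#' @param pm A `profile_matrix`.
#' @param path File path.
#' @return `write_profile_tsv()` returns `path` invisibly;
#'   `read_profile_tsv()` returns a `profile_matrix`.
#' @export
write_profile_tsv <- function(pm, path) {
  stopifnot(inherits(pm, "profile_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# family=", pm$family %||% "NA"),
               paste0("# reference_id=", pm$reference_id)), con)
  writeLines(paste(c("sample", pm$ref_positions), collapse = "\t"), con)
  writeLines(paste(c(pm$reference_id, pm$ref_states), collapse = "\t"), con)
  for (s in pm$sample_ids)
    writeLines(paste(c(s, pm$states[s, ]), collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  family <- sub("^# family=", "", grep("^# family=", meta, value = TRUE))
  if (identical(family, "NA") || length(family) == 0L) family <- NULL
  reference_id <- sub("^# reference_id=", "",
                      grep("^# reference_id=", meta, value = TRUE))
  cells <- strsplit(body, "\t", fixed = TRUE)
  header <- cells[[1]]
  ref_positions <- as.integer(header[-1])
  ref_row <- cells[[2]]
  stopifnot(ref_row[1] == reference_id)
  K <- length(ref_positions)
  sample_rows <- cells[-(1:2)]
  samples <- vapply(sample_rows, `[[`, "", 1L)
  states <- matrix(".", nrow = length(samples), ncol = K,
                   dimnames = list(samples, if (K) paste0("c", seq_len(K))))
  for (i in seq_along(sample_rows))
    if (K) states[i, ] <- sample_rows[[i]][-1]
  ref_states <- if (K) ref_row[-1] else character(0)
  zygosity <- matrix("MISSING", nrow = length(samples), ncol = K,
                     dimnames = dimnames(states))
  for (k in seq_len(K)) {
    ref_base <- base_set(ref_states[k])[1]
    zygosity[, k] <- vapply(states[, k], classify_state, "", ref = ref_base)
  }
  structure(list(family = family, reference_id = reference_id,
                 sample_ids = samples, ref_positions = ref_positions,
                 ref_states = ref_states, states = states,
                 zygosity = zygosity),
            class = "profile_matrix")
}
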
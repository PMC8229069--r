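# Partition of samples into alteration-profile groups and UPGMA schematic
# trees over profile distances.

#' Jaccard distance between two consensus states
#'
#' 0 iff the two base sets are equal, 1 iff they are disjoint, otherwise
#' `1 - |intersection| / |union|`. Missing states have no base set and are
#' rejected; callers exclude missing pairs from column averages.
#'
#' @param s1,s2 Single IUPAC characters.
#' @return A number in `[0, 1]`.
#' @examples
#' state_distance("A", "A")  # 0
#' state_distance("A", "G")  # 1
#' state_distance("A", "R")  # 0.5
#' @export
state_distance <- function(s1, s2) {
  if (is_missing_state(s1) || is_missing_state(s2))
    stop("state_distance is undefined for missing states", call. = FALSE)
  a <- base_set(s1); b <- base_set(s2)
  1 - length(intersect(a, b)) / length(union(a, b))
}

#' Mean Jaccard distance between two alteration profiles
#'
#' The mean of [state_distance()] over the columns where both profiles
#' carry a called (non-missing) state.
#'
#' @param p1,p2 Character vectors of IUPAC codes (with `"."`, `"-"` or
#'   `"N"` marking missing), over the same column set.
#' @param ids Optional pair of labels used in error messages.
#' @return A number in `[0, 1]`.
#' @export
profile_distance <- function(p1, p2, ids = c("p1", "p2")) {
  stopifnot(length(p1) == length(p2))
  shared <- which(!is_missing_state(p1) & !is_missing_state(p2))
  if (length(shared) == 0L)
    stop("no shared non-missing columns between '", ids[1], "' and '",
         ids[2], "'", call. = FALSE)
  mean(mapply(state_distance, p1[shared], p2[shared]))
}

#' Pairwise profile-distance matrix
#'
#' @param pm A `profile_matrix`.
#' @param include_reference Include the reference profile as an extra row?
#' @return Symmetric numeric matrix of column-averaged Jaccard distances.
#' @export
profile_distance_matrix <- function(pm, include_reference = FALSE) {
  stopifnot(inherits(pm, "profile_matrix"))
  m <- pm$states
  if (include_reference)
    m <- rbind(matrix(pm$ref_states, 1L,
                      dimnames = list(pm$reference_id)), m)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n >= 2L)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- profile_distance(m[i, ], m[j, ],
                                             rownames(m)[c(i, j)])
  d
}

# canonical per-cell key for exact profile equality: all missing marks
# compare equal, called states compare by IUPAC code (code equality is
# base-set equality)
profile_key <- function(states) {
  ifelse(is_missing_state(states), "?", states)
}

#' Partition samples into alteration-profile groups
#'
#' With the default tolerance 0, groups are the equivalence classes of
#' exact profile equality (base set, and hence zygosity, per column;
#' missing states compare equal to each other). Groups are reported in
#' order of their first-appearing member; the reference profile is not a
#' sample and is never grouped. A tolerance > 0 (maximum profile distance
#' of a member to every other member of its group, greedy first-fit) is
#' exposed for exploratory use only.
#'
#' @param pm A `profile_matrix`.
#' @param tolerance Maximum within-group profile distance (default 0).
#' @return A `profile_groups` object: list of groups, each with `members`
#'   and the representative `profile` (the first member's states).
#' @export
partition_profiles <- function(pm, tolerance = 0) {
  stopifnot(inherits(pm, "profile_matrix"), length(pm$sample_ids) >= 1L)
  groups <- list()
  if (tolerance == 0) {
    keys <- apply(pm$states, 1L, function(r)
      paste(profile_key(r), collapse = "|"))
    for (s in pm$sample_ids) {
      hit <- which(vapply(groups, function(g) g$key == keys[[s]], TRUE))
      if (length(hit)) {
        groups[[hit]]$members <- c(groups[[hit]]$members, s)
      } else {
        groups[[length(groups) + 1L]] <-
          list(members = s, profile = pm$states[s, ], key = keys[[s]])
      }
    }
  } else {
    for (s in pm$sample_ids) {
      placed <- FALSE
      for (gi in seq_along(groups)) {
        ok <- all(vapply(groups[[gi]]$members, function(m)
          profile_distance(pm$states[m, ], pm$states[s, ],
                           c(m, s)) <= tolerance, TRUE))
        if (ok) {
          groups[[gi]]$members <- c(groups[[gi]]$members, s)
          message("tolerance-merged sample '", s, "' into group ", gi)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        groups[[length(groups) + 1L]] <-
          list(members = s, profile = pm$states[s, ], key = NA_character_)
    }
  }
  groups <- lapply(groups, function(g) g[c("members", "profile")])
  structure(list(groups = groups, family = pm$family,
                 tolerance = tolerance), class = "profile_groups")
}

#' @export
print.profile_groups <- function(x, ...) {
  cat(length(x$groups), "profile groups",
      if (!is.null(x$family)) paste0("[", x$family, "]"), "\n")
  for (i in seq_along(x$groups))
    cat("  group ", i, " (n=", length(x$groups[[i]]$members), "): ",
        paste(x$groups[[i]]$members, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Group sizes of a partition
#' @param groups A `profile_groups` object.
#' @return Integer vector of group sizes in group order.
#' @export
group_sizes <- function(groups) {
  vapply(groups$groups, function(g) length(g$members), 0L)
}

#' UPGMA schematic tree from a distance matrix
#'
#' Standard unweighted pair-group agglomeration: the closest pair of
#' clusters is merged at a node of height half their distance, and
#' between-cluster distances are size-weighted averages of member
#' distances. Ties are broken deterministically: among minimal-distance
#' pairs, merge the pair whose sorted pair of lexicographically smallest
#' member labels is smallest. The result is ultrametric (all leaves
#' equidistant from the root, heights non-decreasing rootwards).
#'
#' @param d Symmetric, zero-diagonal, non-negative distance matrix with
#'   row/column names (or a `dist`).
#' @return A `schematic_tree`: leaf `labels`, `hclust`-style `merge`
#'   matrix, and node `heights`.
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (any(d < 0)) stop("distance matrix has negative entries", call. = FALSE)
  if (any(abs(d - t(d)) > 1e-12) || any(diag(d) != 0))
    stop("distance matrix must be symmetric with zero diagonal",
         call. = FALSE)
  labels <- rownames(d) %||% paste0("L", seq_len(nrow(d)))
  n <- nrow(d)
  if (n == 1L)
    return(structure(list(labels = labels,
                          merge = matrix(0L, 0L, 2L),
                          heights = numeric(0)),
                     class = "schematic_tree"))

  # active clusters: id (negative = leaf, positive = internal node row)
  act <- data.frame(id = -seq_len(n), size = 1L,
                    min_label = labels, stringsAsFactors = FALSE)
  D <- d
  merge <- matrix(0L, n - 1L, 2L)
  heights <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    m <- nrow(D)
    best <- NULL
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      key <- sort(c(act$min_label[i], act$min_label[j]))
      if (is.null(best) || D[i, j] < best$d - 1e-15 ||
          (abs(D[i, j] - best$d) <= 1e-15 &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best <- list(i = i, j = j, d = D[i, j], key = key)
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- c(act$id[i], act$id[j])
    heights[step] <- best$d / 2
    new_size <- act$size[i] + act$size[j]
    new_row <- (act$size[i] * D[i, ] + act$size[j] * D[j, ]) / new_size
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], new_row[keep]),
               c(new_row[keep], 0))
    act <- rbind(act[keep, , drop = FALSE],
                 data.frame(id = step, size = new_size,
                            min_label = min(act$min_label[c(i, j)]),
                            stringsAsFactors = FALSE))
    rownames(D) <- colnames(D) <- NULL
  }
  structure(list(labels = labels, merge = merge, heights = heights),
            class = "schematic_tree")
}

#' @export
print.schematic_tree <- function(x, ...) {
  cat("UPGMA schematic tree with", length(x$labels), "leaves; root height",
      if (length(x$heights)) max(x$heights) else 0, "\n")
  invisible(x)
}

# quote a Newick label if it contains spaces or Newick metacharacters
newick_label <- function(lab) {
  if (grepl("[][\t (),:;']", lab))
    paste0("'", gsub("'", "''", lab), "'")
  else lab
}

#' Serialize a schematic tree as Newick
#'
#' Branch lengths are height differences between a node and its parent;
#' leaf labels containing spaces are single-quoted. A single-leaf tree
#' serializes to the degenerate form `"A:0.0;"`.
#'
#' @param tree A `schematic_tree`.
#' @param digits Significant digits for branch lengths.
#' @return A Newick string terminated by `";"`.
#' @export
to_newick <- function(tree, digits = 10) {
  stopifnot(inherits(tree, "schematic_tree"))
  fmt <- function(x) format(x, digits = digits, scientific = FALSE,
                            trim = TRUE)
  if (length(tree$heights) == 0L)
    return(paste0(newick_label(tree$labels[1]), ":0.0;"))
  node <- function(id, parent_h) {
    if (id < 0) {
      paste0(newick_label(tree$labels[-id]), ":", fmt(parent_h))
    } else {
      h <- tree$heights[id]
      paste0("(", node(tree$merge[id, 1], h), ",",
             node(tree$merge[id, 2], h), "):", fmt(parent_h - h))
    }
  }
  root <- nrow(tree$merge)
  h <- tree$heights[root]
  paste0("(", node(tree$merge[root, 1], h), ",",
         node(tree$merge[root, 2], h), ");")
}

#' Convert a schematic tree to an ape phylo object
#'
#' @param tree A `schematic_tree` with at least two leaves.
#' @return An [ape::read.tree()]-parsed `phylo`.
#' @export
as_phylo <- function(tree) {
  stopifnot(inherits(tree, "schematic_tree"))
  if (length(tree$heights) == 0L)
    stop("a single-leaf tree has no phylo representation", call. = FALSE)
  ape::read.tree(text = to_newick(tree))
}

#' Test whether a set of leaves forms a clade
#'
#' @param tree A `schematic_tree`.
#' @param tips Character vector of leaf labels.
#' @return `TRUE` iff `tips` is exactly the leaf set of some node of the
#'   rooted tree.
#' @export
is_clade <- function(tree, tips) {
  stopifnot(inherits(tree, "schematic_tree"))
  if (setequal(tips, tree$labels)) return(TRUE)
  if (length(tips) == 1L) return(tips %in% tree$labels)
  phy <- as_phylo(tree)
  ape::is.monophyletic(phy, tips)
}
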
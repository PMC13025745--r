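#' Pairwise p-distance matrix of aligned proteins
#'
#' Proportion of differing columns among columns where neither sequence
#' has a gap (`-`).
#'
#' @param aln Named character vector of equal-length aligned sequences.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
pdistance_matrix <- function(aln) {
  if (length(unique(nchar(aln))) != 1) stop("aligned rows differ in length")
  chars <- do.call(rbind, strsplit(toupper(aln), ""))
  n <- length(aln)
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- chars[i, ] != "-" & chars[j, ] != "-"
    if (!any(ok)) { d[i, j] <- d[j, i] <- NA_real_; next }
    d[i, j] <- d[j, i] <- mean(chars[i, ok] != chars[j, ok])
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Thin wrapper over [ape::nj]; on additive distance matrices the
#' generating topology is recovered exactly. Used as the tree-building
#' stand-in for synthetic tests (published trees are inputs, not outputs,
#' of this pipeline).
#'
#' @param d Symmetric nonnegative distance matrix (or `dist`).
#' @return `"phylo"` tree (no supports).
#' @export
build_nj <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8) || any(d < 0))
    stop("distance matrix must be symmetric and nonnegative")
  ape::nj(stats::as.dist(d))
}

clade_tips <- function(tree) {
  # tip label set per node, accumulated child-before-parent (postorder)
  n <- length(tree$tip.label)
  sets <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) sets[[i]] <- tree$tip.label[i]
  edge <- stats::reorder(tree, "postorder")$edge
  for (k in seq_len(nrow(edge)))
    sets[[edge[k, 1]]] <- c(sets[[edge[k, 1]]], sets[[edge[k, 2]]])
  sets
}

#' Extract supported clades from a tree
#'
#' Applies the clade-retention rule used for large family phylogenies:
#' keep a clade only if its branch support is at least `min_support` and
#' it contains at least `min_size` leaves. Reported clades are *maximal*:
#' a node is reported iff it qualifies and no qualifying proper ancestor
#' exists, so the result is a set of pairwise-disjoint clades.
#'
#' @param tree A `"phylo"` with a `support` element (see [parse_newick]).
#' @param min_support Minimum branch support (0-100 scale).
#' @param min_size Minimum number of leaves.
#' @return List with `clades` (list of `list(leaves, support, size)`) and
#'   `unassigned` (leaves in no reported clade).
#' @export
extract_clades <- function(tree, min_support = 70, min_size = 5) {
  if (is.null(tree$support) || all(is.na(tree$support)))
    stop("tree carries no branch supports")
  ntip <- length(tree$tip.label)
  root <- ntip + 1
  sets <- clade_tips(tree)
  qualifies <- function(node) {
    if (node <= ntip || node == root) return(FALSE)  # root support ignored
    s <- tree$support[node - ntip]
    !is.na(s) && s >= min_support && length(sets[[node]]) >= min_size
  }
  clades <- list()
  # preorder from root: report qualifying node, do not descend into it
  recurse <- function(node) {
    if (node > ntip + tree$Nnode) return()
    if (qualifies(node)) {
      clades[[length(clades) + 1]] <<- list(
        leaves = sort(sets[[node]]),
        support = tree$support[node - ntip],
        size = length(sets[[node]]))
      return()
    }
    for (ch in tree$edge[tree$edge[, 1] == node, 2]) recurse(ch)
  }
  recurse(root)
  assigned <- unlist(lapply(clades, `[[`, "leaves"))
  list(clades = clades, unassigned = sort(setdiff(tree$tip.label, assigned)))
}

#' Taxonomic composition of extracted clades
#'
#' Counts genes and distinct species per taxonomic group in each clade and
#' flags clades whose members all come from a single group
#' (lineage-specific clades).
#'
#' @param partition Result of [extract_clades].
#' @param taxa data.frame with `leaf`, `group`, and optionally `species`.
#' @return data.frame with one row per clade x group: `clade`, `group`,
#'   `n_genes`, `n_species`, plus a `lineage_specific` logical attribute
#'   column repeated per clade.
#' @export
clade_composition <- function(partition, taxa) {
  rows <- list()
  for (ci in seq_along(partition$clades)) {
    cl <- partition$clades[[ci]]
    missing <- setdiff(cl$leaves, taxa$leaf)
    if (length(missing)) stop("unmapped leaves: ",
                              paste(missing, collapse = ", "))
    sub <- taxa[taxa$leaf %in% cl$leaves, ]
    specific <- length(unique(sub$group)) == 1
    for (g in unique(sub$group)) {
      gg <- sub[sub$group == g, ]
      rows[[length(rows) + 1]] <- data.frame(
        clade = ci, group = g, n_genes = nrow(gg),
        n_species = if ("species" %in% names(gg))
          length(unique(gg$species)) else NA_integer_,
        lineage_specific = specific)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(clade = integer(0), group = character(0),
               n_genes = integer(0), n_species = integer(0),
               lineage_specific = logical(0))
  rownames(res) <- NULL
  res
}
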
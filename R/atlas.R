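#' Filter an expression matrix to expressed genes
#'
#' Keeps genes whose maximum FPKM over samples reaches `min_max_fpkm`
#' (`>=` by default; `strict = TRUE` uses `>`, the reading of a "max above
#' zero" retention rule that actually removes silent genes).
#'
#' @param mat Numeric genes x samples matrix (FPKM, nonnegative).
#' @param min_max_fpkm Threshold on the per-gene maximum.
#' @param strict Use strict `>` instead of `>=`.
#' @return The filtered matrix.
#' @export
filter_expressed <- function(mat, min_max_fpkm = 1, strict = FALSE) {
  if (any(mat < 0)) stop("negative FPKM values")
  mx <- apply(mat, 1, max)
  keep <- if (strict) mx > min_max_fpkm else mx >= min_max_fpkm
  mat[keep, , drop = FALSE]
}

#' Dunn2 cluster-validity index
#'
#' Ratio of the minimum average between-cluster dissimilarity to the
#' maximum average within-cluster dissimilarity. Singleton clusters have
#' no within-pairs and are skipped in the denominator; if every cluster is
#' a singleton the index is undefined and an error is raised. A zero
#' within-average yields `Inf`.
#'
#' @param d Symmetric dissimilarity matrix (or `dist`).
#' @param labels Cluster label per observation (>= 2 distinct).
#' @return The Dunn2 index (possibly `Inf`).
#' @export
dunn2_index <- function(d, labels) {
  d <- as.matrix(d)
  labels <- as.character(labels)
  cl <- unique(labels)
  if (length(cl) < 2) stop("need at least two clusters")
  idx <- split(seq_along(labels), labels)
  within <- vapply(idx, function(ii) {
    if (length(ii) < 2) return(NA_real_)
    mean(d[ii, ii][upper.tri(d[ii, ii])])
  }, 0)
  if (all(is.na(within))) stop("all clusters are singletons: within-cluster average undefined")
  between <- Inf
  for (i in seq_len(length(cl) - 1)) for (j in (i + 1):length(cl)) {
    b <- mean(d[idx[[cl[i]]], idx[[cl[j]]], drop = FALSE])
    if (b < between) between <- b
  }
  mx_within <- max(within, na.rm = TRUE)
  if (mx_within == 0) return(Inf)
  between / mx_within
}

sample_cor_dist <- function(mat) {
  lg <- log2(mat + 1)
  1 - stats::cor(lg)
}

#' Group transcriptome samples by expression pattern
#'
#' Three-phase grouping of samples: (1) average-linkage hierarchical
#' clustering on `1 - Pearson correlation` of `log2(FPKM + 1)` profiles,
#' cut at the number of clusters maximizing the [dunn2_index] over
#' `k_range`; (2) clusters mixing tissue labels are subdivided by tissue;
#' (3) groups smaller than `min_group_size` are merged into the group with
#' the smallest mean cophenetic distance on the sample tree, repeatedly,
#' so every final group has at least `min_group_size` members (or a single
#' global group remains). Provenance is recorded per group.
#'
#' @param mat Genes x samples FPKM matrix.
#' @param metadata data.frame with `sample`, `tissue` covering all columns
#'   of `mat`.
#' @param k_range Candidate cluster numbers for the validity scan.
#' @param min_group_size Minimum final group size.
#' @return List: `assignment` (named sample -> group id),
#'   `groups` (data.frame `group`, `n`, `tissues`, `provenance`),
#'   `k_initial`, `dunn2`, `tree` (the hclust object).
#' @export
group_samples <- function(mat, metadata, k_range = 2:12, min_group_size = 3) {
  samples <- colnames(mat)
  stopifnot(all(samples %in% metadata$sample))
  tissue <- stats::setNames(metadata$tissue, metadata$sample)[samples]
  n <- length(samples)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (!length(k_range)) stop("k_range incompatible with sample count")
  d <- sample_cor_dist(mat)
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  vals <- vapply(k_range, function(k) {
    labs <- stats::cutree(tree, k = k)
    tryCatch(dunn2_index(d, labs), error = function(e) -Inf)
  }, 0)
  k_best <- k_range[which.max(vals)]
  labs <- stats::cutree(tree, k = k_best)

  # phase 2: subdivide tissue-mixed clusters
  grp <- character(n); names(grp) <- samples
  prov <- character(0)
  for (cl in unique(labs)) {
    ss <- samples[labs == cl]
    tt <- unique(tissue[ss])
    if (length(tt) == 1) {
      grp[ss] <- paste0("C", cl)
      prov[paste0("C", cl)] <- "initial"
    } else {
      for (t in tt) {
        id <- paste0("C", cl, ".", t)
        grp[ss[tissue[ss] == t]] <- id
        prov[id] <- "subdivided"
      }
    }
  }

  # phase 3: merge undersized groups by cophenetic proximity
  coph <- as.matrix(stats::cophenetic(tree))
  repeat {
    sizes <- table(grp)
    small <- names(sizes)[sizes < min_group_size]
    if (!length(small) || length(sizes) == 1) break
    g <- small[order(sizes[small])][1]   # smallest first, deterministic
    members <- names(grp)[grp == g]
    others <- setdiff(names(sizes), g)
    md <- vapply(others, function(o)
      mean(coph[members, names(grp)[grp == o], drop = FALSE]), 0)
    target <- others[which.min(md)]
    grp[members] <- target
    prov[target] <- "merged"
    prov <- prov[names(prov) != g]
  }

  groups <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
    ss <- names(grp)[grp == g]
    data.frame(group = g, n = length(ss),
               tissues = paste(sort(unique(tissue[ss])), collapse = ","),
               provenance = prov[g])
  }))
  rownames(groups) <- NULL
  list(assignment = grp, groups = groups, k_initial = k_best,
       dunn2 = stats::setNames(vals, k_range), tree = tree)
}

#' Build a grouped, normalized expression atlas
#'
#' Group means on the FPKM scale, a `log2(x + 1)` layer, and a per-gene
#' min-max layer scaled to \[0, 1\] (constant genes map to all zeros by
#' convention), plus the peak group per gene (argmax of the min-max layer;
#' ties resolve to the first group in column order).
#'
#' @param mat Genes x samples FPKM matrix.
#' @param grouping Result of [group_samples] (or any list with an
#'   `assignment` element).
#' @return List: `mean_fpkm`, `log2`, `minmax` (genes x groups matrices),
#'   `peak_group` (named character vector).
#' @export
build_atlas <- function(mat, grouping) {
  grp <- grouping$assignment
  stopifnot(all(colnames(mat) %in% names(grp)))
  gids <- sort(unique(grp))
  means <- vapply(gids, function(g)
    rowMeans(mat[, names(grp)[grp == g], drop = FALSE]), numeric(nrow(mat)))
  lg <- log2(means + 1)
  rng <- t(apply(lg, 1, range))
  span <- rng[, 2] - rng[, 1]
  mm <- (lg - rng[, 1]) / ifelse(span == 0, 1, span)
  mm[span == 0, ] <- 0
  peak <- gids[apply(mm, 1, which.max)]
  names(peak) <- rownames(mat)
  list(mean_fpkm = means, log2 = lg, minmax = mm, peak_group = peak)
}
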
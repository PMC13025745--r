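#' Pearson correlation with degenerate-input guard
#'
#' @param x,y Equal-length numeric vectors, length >= 3.
#' @return The Pearson estimate, or `NA` (with a warning) when either side
#'   has zero variance.
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need equal-length vectors of length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Dual-dimension co-expression filter for TF-target pairs
#'
#' A transcription factor is a candidate regulator of a target gene when
#' the Pearson correlation of their expression profiles reaches
#' `threshold` in *both* analytical dimensions: globally over all samples,
#' and within the samples of the target's peak tissue. The intra-tissue
#' dimension guards against correlations driven purely by between-tissue
#' mean shifts.
#'
#' @param tf_mat TFs x samples expression matrix.
#' @param target_mat Targets x samples matrix (same sample columns).
#' @param grouping Result of [group_samples]; its assignment defines the
#'   intra-tissue sample sets.
#' @param peak_group Named vector target -> peak group id (from
#'   [build_atlas]).
#' @param threshold PCC cutoff applied in both dimensions (`>=`).
#' @param intra Intra-tissue dimension: `"peak"` (default, the target's
#'   peak group) or `"max"` (best over all groups with >= 3 samples).
#' @return data.frame: `tf`, `target`, `pcc_global`, `pcc_intra`,
#'   `n_global`, `n_intra`.
#' @export
dual_filter <- function(tf_mat, target_mat, grouping, peak_group,
                        threshold = 0.9, intra = c("peak", "max")) {
  intra <- match.arg(intra)
  stopifnot(identical(colnames(tf_mat), colnames(target_mat)))
  grp <- grouping$assignment[colnames(tf_mat)]
  rows <- list()
  for (tg in rownames(target_mat)) {
    y <- target_mat[tg, ]
    if (stats::sd(y) == 0) next
    g_global <- stats::cor(t(tf_mat), y)[, 1]
    if (intra == "peak") {
      sel <- names(grp)[grp == peak_group[[tg]]]
      sets <- list(sel)
    } else {
      sets <- split(names(grp), grp)
      sets <- sets[lengths(sets) >= 3]
    }
    for (tf in rownames(tf_mat)) {
      if (g_global[tf] < threshold || is.na(g_global[tf])) next
      g_intra <- suppressWarnings(max(vapply(sets, function(ss) {
        if (length(ss) < 3) return(-Inf)
        x <- tf_mat[tf, ss]; yy <- y[ss]
        if (stats::sd(x) == 0 || stats::sd(yy) == 0) return(-Inf)
        stats::cor(x, yy)
      }, 0)))
      n_intra <- max(lengths(sets))
      if (is.finite(g_intra) && g_intra >= threshold)
        rows[[length(rows) + 1]] <- data.frame(
          tf = tf, target = tg, pcc_global = unname(g_global[tf]),
          pcc_intra = g_intra, n_global = ncol(tf_mat),
          n_intra = n_intra)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tf = character(0), target = character(0),
               pcc_global = numeric(0), pcc_intra = numeric(0),
               n_global = integer(0), n_intra = integer(0))
  rownames(res) <- NULL
  res[order(res$tf, res$target), , drop = FALSE]
}

#' Cluster candidate TFs by their correlation profiles
#'
#' Average-linkage hierarchical clustering on `1 - PCC` distance between
#' the TFs' correlation profiles, with the number of clusters chosen to
#' maximize the [dunn2_index] over `k_range`. TFs with identical profiles
#' everywhere collapse to a single cluster (degenerate guard).
#'
#' @param profile_mat TFs x features matrix (e.g. correlations with each
#'   family gene, or expression profiles).
#' @param k_range Candidate cluster counts.
#' @return List: `cluster` (named TF -> cluster id), `k`, `dunn2`.
#' @export
cluster_candidates <- function(profile_mat, k_range = 2:8) {
  n <- nrow(profile_mat)
  if (n < 2) stop("need at least two candidates")
  cc <- suppressWarnings(stats::cor(t(profile_mat)))
  cc[is.na(cc)] <- 1   # zero-variance rows: treat as identical
  d <- 1 - cc
  if (all(d < 1e-12)) {
    return(list(cluster = stats::setNames(rep(1L, n), rownames(profile_mat)),
                k = 1L, dunn2 = NA_real_))
  }
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (!length(k_range)) k_range <- 2
  vals <- vapply(k_range, function(k) {
    labs <- stats::cutree(tree, k = min(k, n))
    tryCatch(dunn2_index(d, labs), error = function(e) -Inf)
  }, 0)
  k <- k_range[which.max(vals)]
  list(cluster = stats::cutree(tree, k = k), k = k,
       dunn2 = stats::setNames(vals, k_range))
}

#' Map candidate TFs to binding-motif models by protein similarity
#'
#' Each TF is assigned the motif of its best local-alignment hit among the
#' motif database's representative proteins (E-value <= `evalue`); score
#' ties resolve to the lexicographically smallest motif id. TFs with no
#' qualifying hit are left unmapped with a warning.
#'
#' @param tf_proteins Named TF protein sequences.
#' @param motif_proteins Named representative protein sequences; names are
#'   motif ids.
#' @param evalue E-value cutoff.
#' @param scheme A [scoring_scheme].
#' @return Named character vector tf -> motif id (`NA` if unmapped).
#' @export
map_tf_to_motif <- function(tf_proteins, motif_proteins, evalue = 1e-5,
                            scheme = scoring_scheme()) {
  db <- sum(nchar(motif_proteins))
  out <- stats::setNames(rep(NA_character_, length(tf_proteins)),
                         names(tf_proteins))
  for (tf in names(tf_proteins)) {
    res <- local_align_many(tf_proteins[[tf]], motif_proteins, scheme)
    res$evalue <- evalue_from_score(res$score, nchar(tf_proteins[[tf]]),
                                    db, scheme)
    res <- res[res$evalue <= evalue, ]
    if (!nrow(res)) next
    res <- res[order(-res$score, res$subject), ]
    out[tf] <- res$subject[1]
  }
  if (anyNA(out))
    warning(sum(is.na(out)), " TF(s) unmapped to any motif")
  out
}

#' Cross-validate co-expression pairs with promoter binding sites
#'
#' Scans each candidate pair's target promoter (TSS at the 3' end) with
#' the TF's mapped motif on both strands. A pair is `TFBS-supported` when
#' at least one hit passes the scan p-value threshold; each supported
#' pair reports its best hit's distance to the TSS and whether any hit
#' lies within `window` bp upstream. Pairs whose TF has no mapped motif
#' are dropped with a warning.
#'
#' @param evidence data.frame from [dual_filter].
#' @param promoters Named promoter sequences (names = target gene ids).
#' @param motifs Named list of DNA [build_pwm] objects (names = motif ids).
#' @param tf2motif Mapping from [map_tf_to_motif].
#' @param p_threshold Scan p-value threshold.
#' @param window TSS-proximal window in bp.
#' @return data.frame: evidence columns plus `motif`, `status`
#'   (`"TFBS-supported"` / `"correlation-only"`), `n_hits`,
#'   `best_distance_to_tss`, `within_window`.
#' @export
tfbs_crossvalidate <- function(evidence, promoters, motifs, tf2motif,
                               p_threshold = 1e-4, window = 500) {
  tabs <- lapply(motifs, pwm_pvalues)
  rows <- list()
  for (i in seq_len(nrow(evidence))) {
    ev <- evidence[i, ]
    mid <- tf2motif[[ev$tf]]
    if (is.na(mid)) { warning("TF ", ev$tf, " has no mapped motif; dropped"); next }
    prom <- promoters[[ev$target]]
    if (is.null(prom)) stop("no promoter for target ", ev$target)
    hits <- scan_sequence(motifs[[mid]], prom, p_threshold,
                          both_strands = TRUE, tab = tabs[[mid]],
                          seq_id = ev$target, tss_at_end = TRUE)
    supported <- nrow(hits) > 0
    rows[[i]] <- cbind(ev, data.frame(
      motif = mid,
      status = if (supported) "TFBS-supported" else "correlation-only",
      n_hits = nrow(hits),
      best_distance_to_tss = if (supported)
        hits$distance_to_tss[which.min(hits$pvalue)] else NA_real_,
      within_window = supported && any(hits$distance_to_tss <= window)))
  }
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- cbind(evidence[0, ], data.frame(
      motif = character(0), status = character(0), n_hits = integer(0),
      best_distance_to_tss = numeric(0), within_window = logical(0)))
  rownames(res) <- NULL
  res
}
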
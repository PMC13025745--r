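kmer_set <- function(seq, k = 6) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1), k:n))
}

#' Find homology anchors between two ranked proteomes
#'
#' All protein pairs passing the collinearity-grade thresholds
#' (E-value <= `evalue`, identity >= `identity`, coverage >= `coverage`),
#' annotated with each gene's chromosome and gene-order rank. Self-hits
#' are excluded. A shared-k-mer prefilter skips alignment of pairs that
#' cannot plausibly pass.
#'
#' @param proteome_a,proteome_b Named protein sequence vectors; pass the
#'   same object twice for a within-genome run (`self = TRUE`).
#' @param orders_a,orders_b data.frames with `gene_id`, `chrom`, `rank`
#'   (1-based gene order index along its chromosome).
#' @param evalue,identity,coverage Anchor thresholds.
#' @param scheme A [scoring_scheme].
#' @param self Set for within-genome runs: skips self-pairs and keeps each
#'   unordered pair once.
#' @param prefilter_kmers Minimum shared 6-mers required before aligning
#'   (0 disables the prefilter).
#' @return data.frame: `gene_a`, `gene_b`, `chrom_a`, `chrom_b`, `rank_a`,
#'   `rank_b`, `score`, `identity`, `coverage`, `evalue`.
#' @export
find_anchors <- function(proteome_a, proteome_b, orders_a, orders_b,
                         evalue = 1e-10, identity = 0.30, coverage = 0.50,
                         scheme = scoring_scheme(), self = FALSE,
                         prefilter_kmers = 2) {
  stopifnot(all(names(proteome_a) %in% orders_a$gene_id),
            all(names(proteome_b) %in% orders_b$gene_id))
  db_residues <- sum(nchar(proteome_b))
  kmers_b <- if (prefilter_kmers > 0) lapply(proteome_b, kmer_set) else NULL
  rows <- list()
  for (qa in names(proteome_a)) {
    cand <- names(proteome_b)
    if (self) cand <- cand[match(cand, names(proteome_b)) >
                             match(qa, names(proteome_a))]
    if (!length(cand)) next
    if (!is.null(kmers_b)) {
      ka <- kmer_set(proteome_a[[qa]])
      shared <- vapply(cand, function(cb)
        sum(kmers_b[[cb]] %in% ka), 0L)
      cand <- cand[shared >= prefilter_kmers]
      if (!length(cand)) next
    }
    res <- local_align_many(proteome_a[[qa]], proteome_b[cand], scheme)
    res$evalue <- evalue_from_score(res$score, nchar(proteome_a[[qa]]),
                                    db_residues, scheme)
    keep <- res$evalue <= evalue & res$identity >= identity &
      res$coverage >= coverage
    if (!any(keep)) next
    res <- res[keep, ]
    rows[[qa]] <- data.frame(gene_a = qa, gene_b = res$subject,
                             score = res$score, identity = res$identity,
                             coverage = res$coverage, evalue = res$evalue)
  }
  anc <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_a = character(0), gene_b = character(0),
               score = numeric(0), identity = numeric(0),
               coverage = numeric(0), evalue = numeric(0))
  ia <- match(anc$gene_a, orders_a$gene_id)
  ib <- match(anc$gene_b, orders_b$gene_id)
  anc$chrom_a <- orders_a$chrom[ia]
  anc$rank_a <- orders_a$rank[ia]
  anc$chrom_b <- orders_b$chrom[ib]
  anc$rank_b <- orders_b$rank[ib]
  rownames(anc) <- NULL
  anc[order(anc$chrom_a, anc$rank_a, anc$chrom_b, anc$rank_b), , drop = FALSE]
}

# best monotone chain by DP over anchors of one chromosome pair and one
# orientation; returns list(score, idx)
best_chain <- function(rank_a, rank_b, orientation = c("same", "inverted"),
                       max_gap = 25, gap_penalty = 0.2) {
  orientation <- match.arg(orientation)
  rb <- if (orientation == "same") rank_b else -rank_b
  ord <- order(rank_a, rb)
  ra <- rank_a[ord]; rbo <- rb[ord]
  n <- length(ra)
  best <- rep(1, n); prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      da <- ra[i] - ra[j]; db <- rbo[i] - rbo[j]
      if (da <= 0 || db <= 0 || da > max_gap || db > max_gap) next
      cand <- best[j] + 1 - gap_penalty * ((da - 1) + (db - 1))
      if (cand > best[i] + 1e-12) { best[i] <- cand; prev[i] <- j }
    }
  }
  end <- which.max(best)
  idx <- end
  while (!is.na(prev[idx[1]])) idx <- c(prev[idx[1]], idx)
  list(score = best[end], idx = ord[idx])
}

#' Chain anchors into collinear (synteny) blocks
#'
#' Dynamic-programming chaining of homology anchors into maximal-scoring
#' monotone chains per chromosome pair, in both orientations. Chain score
#' is `anchors - gap_penalty * total rank gaps`; rank jumps larger than
#' `max_gap` break a chain; chains with fewer than `min_block_size`
#' anchors are discarded; each anchor joins at most one block (blocks are
#' peeled off best-first; equal scores prefer the chain with the smaller
#' starting rank on the first genome).
#'
#' @param anchors Anchor table from [find_anchors].
#' @param min_block_size Minimum anchors per block.
#' @param max_gap Maximum rank jump within a chain.
#' @param gap_penalty Score deduction per skipped rank.
#' @return List of blocks; each block is a list with `chrom_a`, `chrom_b`,
#'   `orientation`, `score`, and `anchors` (data.frame subset).
#' @export
chain_collinear <- function(anchors, min_block_size = 5, max_gap = 25,
                            gap_penalty = 0.2) {
  blocks <- list()
  if (!nrow(anchors)) return(blocks)
  pair_key <- paste(anchors$chrom_a, anchors$chrom_b, sep = "\r")
  for (pk in unique(pair_key)) {
    sub <- anchors[pair_key == pk, ]
    repeat {
      if (nrow(sub) < min_block_size) break
      cand <- lapply(c("same", "inverted"), function(o)
        c(list(orientation = o),
          best_chain(sub$rank_a, sub$rank_b, o, max_gap, gap_penalty)))
      sc <- vapply(cand, `[[`, 0, "score")
      st <- vapply(cand, function(cc) min(sub$rank_a[cc$idx]), 0)
      pick <- cand[[order(-sc, st)[1]]]
      if (length(pick$idx) < min_block_size) break
      blk <- sub[pick$idx, ]
      blocks[[length(blocks) + 1]] <- list(
        chrom_a = blk$chrom_a[1], chrom_b = blk$chrom_b[1],
        orientation = pick$orientation, score = pick$score,
        anchors = blk[order(blk$rank_a), ])
      sub <- sub[-pick$idx, ]
    }
  }
  # deterministic order
  if (length(blocks)) {
    ord <- order(vapply(blocks, `[[`, "", "chrom_a"),
                 vapply(blocks, `[[`, "", "chrom_b"),
                 vapply(blocks, function(b) min(b$anchors$rank_a), 0))
    blocks <- blocks[ord]
  }
  blocks
}

#' Classify duplication mode of family genes
#'
#' Each family gene receives exactly one mode with precedence
#' segmental > tandem > proximal > dispersed > singleton:
#' *segmental* - the gene sits in a collinear block; *tandem* - it has an
#' anchor partner at an adjacent gene rank on the same chromosome;
#' *proximal* - a partner within `proximal_max_rank_gap` ranks on the same
#' chromosome; *dispersed* - any other anchored partner; *singleton* - no
#' partner at all.
#'
#' @param family_genes Character vector of gene ids to classify.
#' @param anchors Within-genome anchors from [find_anchors] (`self = TRUE`).
#' @param blocks Blocks from [chain_collinear] on those anchors.
#' @param proximal_max_rank_gap Rank distance defining "proximal".
#' @return data.frame: `gene_id`, `mode`.
#' @export
classify_duplicates <- function(family_genes, anchors, blocks,
                                proximal_max_rank_gap = 10) {
  in_block <- unique(unlist(lapply(blocks, function(b)
    c(b$anchors$gene_a, b$anchors$gene_b))))
  partner_tab <- rbind(
    data.frame(gene = anchors$gene_a, chrom = anchors$chrom_a,
               rank = anchors$rank_a, p_chrom = anchors$chrom_b,
               p_rank = anchors$rank_b),
    data.frame(gene = anchors$gene_b, chrom = anchors$chrom_b,
               rank = anchors$rank_b, p_chrom = anchors$chrom_a,
               p_rank = anchors$rank_a))
  mode <- vapply(family_genes, function(g) {
    if (g %in% in_block) return("segmental")
    p <- partner_tab[partner_tab$gene == g, ]
    if (!nrow(p)) return("singleton")
    same <- p$p_chrom == p$chrom
    gap <- abs(p$p_rank - p$rank)
    if (any(same & gap == 1)) return("tandem")
    if (any(same & gap <= proximal_max_rank_gap)) return("proximal")
    "dispersed"
  }, "")
  data.frame(gene_id = family_genes, mode = unname(mode), row.names = NULL)
}

#' Collinear gene pairs and putative orthologs from inter-genome blocks
#'
#' Every anchor inside a block is a collinear pair; a pair is flagged a
#' putative ortholog when the two genes are each other's best-scoring
#' partner within their block.
#'
#' @param blocks Blocks from an inter-genome [chain_collinear] run.
#' @return data.frame: `gene_a`, `gene_b`, `score`, `putative_ortholog`.
#' @export
ortholog_pairs <- function(blocks) {
  if (!length(blocks))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0), putative_ortholog = logical(0)))
  out <- lapply(blocks, function(b) {
    a <- b$anchors
    best_for_a <- vapply(unique(a$gene_a), function(g)
      a$gene_b[a$gene_a == g][which.max(a$score[a$gene_a == g])], "")
    best_for_b <- vapply(unique(a$gene_b), function(g)
      a$gene_a[a$gene_b == g][which.max(a$score[a$gene_b == g])], "")
    a$putative_ortholog <- best_for_a[a$gene_a] == a$gene_b &
      best_for_b[a$gene_b] == a$gene_a
    a[, c("gene_a", "gene_b", "score", "putative_ortholog")]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
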
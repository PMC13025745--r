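#' Scan a protein for conserved-domain profiles
#'
#' Ungapped log-odds profile scan with exact p-values: every window whose
#' p-value falls below the threshold is a candidate, and overlapping
#' candidates for the same domain are merged keeping the best-scoring one.
#' A profile wider than the protein simply yields no hit.
#'
#' @param protein Protein sequence.
#' @param profiles Named list of protein-alphabet [build_pwm] objects, one
#'   per domain.
#' @param p_threshold Exact p-value threshold (strict `<`).
#' @param protein_id Id carried into the output.
#' @param tabs Optional precomputed list of [pwm_pvalues] tables parallel
#'   to `profiles`.
#' @return data.frame of domain hits: `protein_id`, `domain`, `start`,
#'   `end` (residues, 1-based inclusive), `score` (bits), `pvalue`.
#' @export
scan_domains <- function(protein, profiles, p_threshold = 1e-9,
                         protein_id = "protein", tabs = NULL) {
  out <- list()
  for (d in seq_along(profiles)) {
    pwm <- profiles[[d]]
    dom <- names(profiles)[d] %||% pwm$name
    if (pwm$width > nchar(protein)) next
    hits <- scan_sequence(pwm, protein, p_threshold,
                          tab = if (is.null(tabs)) NULL else tabs[[d]])
    if (!nrow(hits)) next
    hits$end <- hits$start + pwm$width - 1
    # merge overlaps, best score first
    hits <- hits[order(-hits$score), ]
    kept <- hits[0, ]
    for (i in seq_len(nrow(hits))) {
      h <- hits[i, ]
      if (!nrow(kept) || all(h$start > kept$end | h$end < kept$start))
        kept <- rbind(kept, h)
    }
    out[[dom]] <- data.frame(protein_id = protein_id, domain = dom,
                             start = kept$start, end = kept$end,
                             score = kept$score, pvalue = kept$pvalue)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(protein_id = character(0), domain = character(0),
               start = integer(0), end = integer(0),
               score = numeric(0), pvalue = numeric(0))
  rownames(res) <- NULL
  res[order(res$start), , drop = FALSE]
}

#' Best seed-protein homology hit per proteome entry
#'
#' Aligns every protein against every seed (Smith-Waterman, BLOSUM62) and
#' keeps the best-scoring seed per protein. E-values use search space
#' `m * n` = protein length x total seed residues.
#'
#' @param proteome Named character vector of protein sequences.
#' @param seeds Named character vector of seed (query-family) proteins.
#' @param scheme A [scoring_scheme].
#' @return data.frame: `protein_id`, `best_seed`, `score`, `identity`,
#'   `coverage`, `evalue`.
#' @export
best_seed_hits <- function(proteome, seeds, scheme = scoring_scheme()) {
  if (!length(seeds)) stop("empty seed set")
  db_residues <- sum(nchar(seeds))
  per_seed <- lapply(names(seeds), function(sid) {
    res <- local_align_many(seeds[[sid]], proteome, scheme)
    res$seed <- sid
    res
  })
  all <- do.call(rbind, per_seed)
  best <- do.call(rbind, lapply(split(all, all$subject), function(d)
    d[which.max(d$score), ]))
  data.frame(protein_id = best$subject, best_seed = best$seed,
             score = best$score, identity = best$identity,
             coverage = best$coverage,
             evalue = evalue_from_score(
               best$score, nchar(proteome[best$subject]), db_residues, scheme),
             row.names = NULL)
}

#' Identify family members by dual evidence
#'
#' A gene joins the family only if its protein (1) has a qualifying local
#' alignment to at least one seed protein (E-value at or below
#' `evalue_threshold`) and (2) carries *both* conserved domain profiles at
#' the domain-scan p-value threshold. Evidence is retained per member.
#'
#' @param proteome Named character vector of protein sequences.
#' @param seeds Named character vector of seed proteins.
#' @param profiles Named list of exactly two protein [build_pwm] domain
#'   profiles.
#' @param evalue_threshold Homology cutoff (default 1e-5, `<=`).
#' @param domain_p Domain-scan p-value threshold (default 1e-9, `<`).
#' @param scheme A [scoring_scheme].
#' @return data.frame of members: `gene_id`, `best_seed`, `evalue`,
#'   `identity`, `coverage`, plus per-domain start/end columns.
#' @export
identify_family <- function(proteome, seeds, profiles,
                            evalue_threshold = 1e-5, domain_p = 1e-9,
                            scheme = scoring_scheme()) {
  stopifnot(length(profiles) == 2)
  if (!length(seeds)) stop("empty seed set")
  hom <- best_seed_hits(proteome, seeds, scheme)
  hom_ok <- hom[hom$evalue <= evalue_threshold, ]
  tabs <- lapply(profiles, pwm_pvalues)
  dom_names <- names(profiles)
  rows <- list()
  for (pid in hom_ok$protein_id) {
    dh <- scan_domains(proteome[[pid]], profiles, domain_p, pid, tabs)
    if (!all(dom_names %in% dh$domain)) next
    h <- hom_ok[hom_ok$protein_id == pid, ]
    best_dom <- do.call(rbind, lapply(dom_names, function(d) {
      dd <- dh[dh$domain == d, ]
      dd[which.min(dd$pvalue), c("start", "end")]
    }))
    rows[[pid]] <- data.frame(
      gene_id = pid, best_seed = h$best_seed, evalue = h$evalue,
      identity = h$identity, coverage = h$coverage,
      d1_start = best_dom$start[1], d1_end = best_dom$end[1],
      d2_start = best_dom$start[2], d2_end = best_dom$end[2])
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), best_seed = character(0),
               evalue = numeric(0), identity = numeric(0),
               coverage = numeric(0), d1_start = integer(0),
               d1_end = integer(0), d2_start = integer(0),
               d2_end = integer(0))
  rownames(res) <- NULL
  res[order(res$gene_id), , drop = FALSE]
}

genome_letter <- function(chrom) {
  ifelse(grepl("Un$", chrom, ignore.case = TRUE), "Un",
         sub(".*?[0-9]+([A-Za-z])$", "\\1", chrom))
}

chrom_number <- function(chrom) {
  num <- suppressWarnings(as.numeric(sub(".*?([0-9]+)[A-Za-z]*$", "\\1", chrom)))
  ifelse(is.na(num), Inf, num)   # unplaced sorts last
}

#' Assign positional family names
#'
#' Names follow the convention used for polyploid gene families:
#' `{prefix}{NN}-{genome letter}` where NN is shared by homoeologs (copies
#' of the same gene on the A/B/D subgenomes), the letter comes from the
#' chromosome name (`"Un"` for unplaced scaffolds), and additional tandem
#' copies of a numbered member on the same subgenome get an `L` suffix
#' (`{prefix}{NN}L-{letter}`). Numbering follows chromosome then
#' coordinate order of each homoeolog group's first member.
#'
#' Homoeolog groups may be supplied; otherwise they are inferred as
#' connected components of the reciprocal-best-hit graph across genome
#' letters (requires `proteome`).
#'
#' @param members data.frame with `gene_id`, `chrom`, `start`.
#' @param prefix Name prefix, e.g. `"TaWSD"`.
#' @param groups Optional list of character vectors of gene ids (homoeolog
#'   groups); ungrouped genes form singleton groups.
#' @param proteome Named protein sequences for RBH inference when `groups`
#'   is `NULL`.
#' @param scheme A [scoring_scheme].
#' @return Named character vector: gene_id -> assigned name.
#' @export
assign_names <- function(members, prefix = "WSD", groups = NULL,
                         proteome = NULL, scheme = scoring_scheme()) {
  if (anyDuplicated(members$gene_id)) stop("duplicate gene ids")
  members$letter <- genome_letter(members$chrom)
  members$chrnum <- chrom_number(members$chrom)

  if (is.null(groups)) {
    if (is.null(proteome)) stop("need homoeolog groups or a proteome")
    groups <- rbh_groups(members, proteome, scheme)
  }
  in_group <- unlist(groups)
  singles <- setdiff(members$gene_id, in_group)
  groups <- c(groups, as.list(singles))

  # order groups by chromosome then coordinate of their earliest member
  key <- t(vapply(groups, function(g) {
    m <- members[members$gene_id %in% g, ]
    c(min(m$chrnum), min(m$start[m$chrnum == min(m$chrnum)]))
  }, numeric(2)))
  groups <- groups[order(key[, 1], key[, 2])]

  names_out <- character(0)
  for (gi in seq_along(groups)) {
    nn <- sprintf("%02d", gi)
    m <- members[members$gene_id %in% groups[[gi]], ]
    for (let in unique(m$letter[order(m$chrnum, m$start)])) {
      sub <- m[m$letter == let, ]
      sub <- sub[order(sub$start), ]
      for (k in seq_len(nrow(sub))) {
        suffix <- if (k == 1) "" else if (k == 2) "L" else paste0("L", k - 1)
        names_out[sub$gene_id[k]] <-
          paste0(prefix, nn, suffix, "-", let)
      }
    }
  }
  names_out[members$gene_id]
}

# connected components of the cross-subgenome reciprocal-best-hit graph
rbh_groups <- function(members, proteome, scheme = scoring_scheme()) {
  ids <- members$gene_id
  letters_ <- members$letter
  score_mat <- matrix(-Inf, length(ids), length(ids),
                      dimnames = list(ids, ids))
  for (i in seq_along(ids)) {
    others <- ids[letters_ != letters_[i]]
    if (!length(others)) next
    res <- local_align_many(proteome[[ids[i]]], proteome[others], scheme)
    score_mat[ids[i], others] <- res$score
  }
  # best hit per (gene, other letter)
  edges <- list()
  for (i in seq_along(ids)) {
    for (let in setdiff(unique(letters_), letters_[i])) {
      cand <- ids[letters_ == let]
      if (!length(cand)) next
      sc <- score_mat[ids[i], cand]
      if (all(!is.finite(sc))) next
      best <- cand[which.max(sc)]
      # reciprocal?
      back <- ids[letters_ == letters_[i]]
      if (ids[i] == back[which.max(score_mat[best, back])])
        edges[[length(edges) + 1]] <- c(ids[i], best)
    }
  }
  comp <- stats::setNames(seq_along(ids), ids)
  for (e in edges) {
    ca <- comp[e[1]]; cb <- comp[e[2]]
    if (ca != cb) comp[comp == cb] <- ca
  }
  unname(split(ids, comp[ids]))
}
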
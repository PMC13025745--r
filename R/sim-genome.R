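random_protein <- function(n) {
  paste(sample(PROTEIN_ALPHABET, n, replace = TRUE), collapse = "")
}

mutate_protein <- function(seq, rate) {
  if (rate <= 0) return(seq)
  res <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(res)) < rate
  res[hit] <- vapply(res[hit], function(r)
    sample(setdiff(PROTEIN_ALPHABET, r), 1), "")
  paste(res, collapse = "")
}

#' Build the pair of conserved-domain profiles used by the simulator
#'
#' Two high-information protein profiles analogous to the N-terminal
#' catalytic and C-terminal domains of WS/DGAT proteins: each position
#' puts probability `info` on a consensus residue and spreads the rest
#' uniformly. At these settings a profile scan separates planted domains
#' from background comfortably at a 1e-9 exact p-value.
#'
#' @param widths Widths of the two domains (residues).
#' @param info Consensus-residue probability per position.
#' @param seed RNG seed fixing the consensus sequences.
#' @return List: `profiles` (named list of two protein [build_pwm]),
#'   `consensus` (named character vector).
#' @export
make_domain_profiles <- function(widths = c(45, 55), info = 0.85,
                                 seed = 104729) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  nm <- c("WSD_cat", "WSD_Cterm")
  profiles <- list(); consensus <- character(0)
  for (i in 1:2) {
    cons <- strsplit(random_protein(widths[i]), "")[[1]]
    prob <- matrix((1 - info) / 19, nrow = widths[i], ncol = 20,
                   dimnames = list(NULL, PROTEIN_ALPHABET))
    prob[cbind(seq_len(widths[i]), match(cons, PROTEIN_ALPHABET))] <- info
    profiles[[nm[i]]] <- build_pwm(prob, alphabet = "protein", name = nm[i])
    consensus[nm[i]] <- paste(cons, collapse = "")
  }
  list(profiles = profiles, consensus = consensus)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Configuration for the synthetic annotated genome
#'
#' The defaults emulate, at desk scale, a polyploid-crop genome carrying
#' a two-domain acyltransferase family: several chromosomes of a single
#' subgenome, a 13-member family realizing a duplication plan of 6
#' segmental, 4 tandem, 1 proximal and 2 dispersed genes (the published
#' 28/11/1/3 mix scaled down), plus single-domain, homology-only and
#' random decoys.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param genes_per_chromosome Genes per chromosome.
#' @param duplication_plan Named counts over
#'   `c("segmental", "tandem", "proximal", "dispersed")`; `tandem` must be
#'   even, `segmental` even, and `proximal > 0` requires `tandem >= 2`
#'   (proximal genes are planted as satellites of a tandem array).
#' @param n_singletons Family members with no duplicate partner.
#' @param n_decoy_single_domain,n_decoy_homology,n_decoy_random Decoy
#'   counts (one-domain, seed-backbone-sharing, and unrelated proteins).
#' @param protein_length Family protein length (residues).
#' @param n_exons Exons per gene.
#' @param mutation_rate Per-residue substitution probability applied to
#'   every duplicated copy.
#' @param genome_letter Subgenome letter used in chromosome names.
#' @param core_motif Catalytic heptapeptide planted in every family
#'   protein.
#' @param seed RNG seed; fixes all randomness.
#' @return A `genome_sim_config` list.
#' @export
genome_sim_config <- function(n_chromosomes = 3, genes_per_chromosome = 60,
                              duplication_plan = c(segmental = 6, tandem = 4,
                                                   proximal = 1, dispersed = 2),
                              n_singletons = 0,
                              n_decoy_single_domain = 2,
                              n_decoy_homology = 3,
                              n_decoy_random = NULL,
                              protein_length = 500, n_exons = 7,
                              mutation_rate = 0, genome_letter = "A",
                              core_motif = "HHSLVDG", seed = 1) {
  plan <- duplication_plan
  for (m in c("segmental", "tandem", "proximal", "dispersed"))
    if (is.na(plan[m])) plan[m] <- 0
  plan <- plan[c("segmental", "tandem", "proximal", "dispersed")]
  if (any(plan < 0)) stop("negative duplication counts")
  if (plan["tandem"] %% 2 != 0) stop("tandem count must be even (adjacent pairs)")
  if (plan["segmental"] %% 2 != 0) stop("segmental count must be even (source + copy)")
  if (plan["proximal"] > 0 && plan["tandem"] < 2)
    stop("proximal genes are satellites of a tandem array: need tandem >= 2")
  if (mutation_rate < 0 || mutation_rate >= 1) stop("mutation rate in [0,1)")
  n_family <- sum(plan) + n_singletons
  # duplicated non-family genes padding the collinear segment to block size
  n_filler <- if (plan["segmental"] > 0)
    2 * max(0, 5 - plan["segmental"] / 2) else 0
  if (is.null(n_decoy_random))
    n_decoy_random <- n_chromosomes * genes_per_chromosome - n_family -
      n_filler - n_decoy_single_domain - n_decoy_homology
  if (n_decoy_random < 0)
    stop("duplication plan infeasible for chromosome sizes")
  structure(list(n_chromosomes = n_chromosomes,
                 genes_per_chromosome = genes_per_chromosome,
                 plan = plan, n_singletons = n_singletons,
                 n_decoy_single_domain = n_decoy_single_domain,
                 n_decoy_homology = n_decoy_homology,
                 n_decoy_random = n_decoy_random,
                 protein_length = protein_length, n_exons = n_exons,
                 mutation_rate = mutation_rate,
                 genome_letter = genome_letter,
                 core_motif = core_motif, seed = seed),
            class = "genome_sim_config")
}

# family protein: backbone with domain1 .. core motif .. domain2 planted
make_family_protein <- function(cfg, dom) {
  w1 <- nchar(dom$consensus[1]); w2 <- nchar(dom$consensus[2])
  core <- cfg$core_motif
  L <- cfg$protein_length
  spare <- L - w1 - w2 - nchar(core)
  pre <- sample(30:60, 1)
  mid1 <- sample(20:40, 1)
  mid2 <- sample(40:80, 1)
  post <- spare - pre - mid1 - mid2
  stopifnot(post > 0)
  paste0(random_protein(pre), dom$consensus[1], random_protein(mid1),
         core, random_protein(mid2), dom$consensus[2],
         random_protein(post))
}

#' Generate an annotated genome with a planted gene family
#'
#' Emits a proteome, per-gene models (GFF3-ready), and a machine-readable
#' truth table. Family members carry both conserved-domain profiles and
#' the catalytic core motif; decoys carry at most one domain. The
#' duplication plan is realized exactly under the classification rules of
#' [classify_duplicates]: distinct subfamilies are used so that, at zero
#' mutation, homology anchors form only within a planted unit.
#'
#' @param config A [genome_sim_config].
#' @param domains Result of [make_domain_profiles] (shared between
#'   simulation and identification).
#' @return List: `proteome` (named sequences), `models` (list of
#'   [gene_model]), `orders` (gene_id/chrom/rank data.frame), `truth`
#'   (data.frame `gene_id`, `is_family`, `mode`, `subfamily`,
#'   `decoy_type`), `seeds` (seed proteins for family identification),
#'   `config`.
#' @export
generate_family_genome <- function(config = genome_sim_config(),
                                   domains = make_domain_profiles()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  cfg <- config
  n_chr <- cfg$n_chromosomes
  gpc <- cfg$genes_per_chromosome
  chroms <- paste0("Chr", seq_len(n_chr), cfg$genome_letter)
  dom <- list(consensus = domains$consensus)

  # seed proteins: independent backbones around the same domains
  seeds <- stats::setNames(
    vapply(1:2, function(i) make_family_protein(cfg, dom), ""),
    c("SEED1", "SEED2"))

  # slot grid: (chrom, rank); fill family units first, then decoys
  slots <- expand.grid(rank = seq_len(gpc), chrom = chroms,
                       stringsAsFactors = FALSE)[, c("chrom", "rank")]
  taken <- rep(FALSE, nrow(slots))
  slot_at <- function(chrom, rank) which(slots$chrom == chrom & slots$rank == rank)
  claim <- function(idx) {
    if (length(idx) != 1 || taken[idx])
      stop("duplication plan infeasible for chromosome sizes")
    taken[idx] <<- TRUE
  }

  placements <- list()  # gene_id -> list(chrom, rank, protein, truth fields)
  gene_no <- 0
  add_gene <- function(chrom, rank, protein, is_family, mode, subfam, decoy) {
    gene_no <<- gene_no + 1
    id <- sprintf("SIM%s%03d", cfg$genome_letter, gene_no)
    claim(slot_at(chrom, rank))
    placements[[id]] <<- list(chrom = chrom, rank = rank, protein = protein,
                              is_family = is_family, mode = mode,
                              subfamily = subfam, decoy_type = decoy)
  }

  subfam_no <- 0
  new_subfam <- function() { subfam_no <<- subfam_no + 1; sprintf("F%02d", subfam_no) }
  mut <- function(p) mutate_protein(p, cfg$mutation_rate)

  # --- segmental: s/2 subfamilies in one segment, copied to another chrom
  s <- cfg$plan["segmental"]
  if (s > 0) {
    if (n_chr < 2) stop("segmental plan needs >= 2 chromosomes")
    n_fam_seg <- s / 2
    n_fill <- max(0, 5 - n_fam_seg)   # duplicated decoys to reach block size
    seg_len <- n_fam_seg + n_fill
    if (seg_len + 2 > gpc) stop("segment too long for chromosome")
    src_start <- 3
    dst_start <- 10
    seg_prot <- list(); seg_fam <- logical(seg_len); seg_sub <- character(seg_len)
    pos_fam <- sort(sample(seg_len, n_fam_seg))
    for (k in seq_len(seg_len)) {
      if (k %in% pos_fam) {
        seg_sub[k] <- new_subfam()
        seg_prot[[k]] <- make_family_protein(cfg, dom)
        seg_fam[k] <- TRUE
      } else {
        seg_sub[k] <- NA_character_
        seg_prot[[k]] <- random_protein(cfg$protein_length)
      }
    }
    for (k in seq_len(seg_len)) {
      add_gene(chroms[1], src_start + k - 1, seg_prot[[k]],
               seg_fam[k], if (seg_fam[k]) "segmental" else NA, seg_sub[k],
               if (seg_fam[k]) NA else "segmental_filler")
      add_gene(chroms[2], dst_start + k - 1, mut(seg_prot[[k]]),
               seg_fam[k], if (seg_fam[k]) "segmental" else NA, seg_sub[k],
               if (seg_fam[k]) NA else "segmental_filler")
    }
  }

  # --- tandem pairs (+ proximal satellites on the first array)
  t <- cfg$plan["tandem"]; px <- cfg$plan["proximal"]
  if (t > 0) {
    n_pairs <- t / 2
    base_rank <- min(30, gpc - 8)
    if (base_rank < 3) stop("duplication plan infeasible for chromosome sizes")
    for (p in seq_len(n_pairs)) {
      sf <- new_subfam()
      prot <- make_family_protein(cfg, dom)
      chrom <- chroms[(p - 1) %% n_chr + 1]
      r0 <- base_rank + 8 * ((p - 1) %/% n_chr)
      add_gene(chrom, r0, prot, TRUE, "tandem", sf, NA)
      add_gene(chrom, r0 + 1, mut(prot), TRUE, "tandem", sf, NA)
      if (p == 1 && px > 0) {
        for (q in seq_len(px))
          add_gene(chrom, r0 + 2 + q, mut(prot), TRUE, "proximal", sf, NA)
      }
    }
  } else if (px > 0) stop("proximal without tandem array")

  # --- dispersed: pairs on different chromosomes, far from blocks
  d <- cfg$plan["dispersed"]
  if (d > 0) {
    n_pairs <- floor(d / 2)
    for (p in seq_len(n_pairs)) {
      sf <- new_subfam()
      prot <- make_family_protein(cfg, dom)
      add_gene(chroms[1], gpc - 2 * p, prot, TRUE, "dispersed", sf, NA)
      add_gene(chroms[n_chr], gpc - 2 * p, mut(prot), TRUE, "dispersed", sf, NA)
    }
    if (d %% 2 == 1) {
      # odd remainder: satellite copy of the tandem subfamily, far away
      if (t == 0) stop("odd dispersed count needs a tandem array to attach to")
      tand <- Filter(function(x) identical(x$mode, "tandem"), placements)
      prot <- mut(tand[[1]]$protein)
      add_gene(chroms[n_chr], 2, prot, TRUE, "dispersed",
               tand[[1]]$subfamily, NA)
    }
  }

  # --- singletons
  for (i in seq_len(cfg$n_singletons)) {
    free <- which(!taken)
    pick <- free[sample(length(free), 1)]
    add_gene(slots$chrom[pick], slots$rank[pick],
             make_family_protein(cfg, dom), TRUE, "singleton",
             new_subfam(), NA)
  }

  # --- decoys
  place_decoy <- function(protein, type) {
    free <- which(!taken)
    pick <- free[sample(length(free), 1)]
    add_gene(slots$chrom[pick], slots$rank[pick], protein, FALSE, NA, NA, type)
  }
  for (i in seq_len(cfg$n_decoy_single_domain)) {
    L <- cfg$protein_length
    w1 <- nchar(dom$consensus[1])
    prot <- paste0(random_protein(50), dom$consensus[1],
                   random_protein(L - 50 - w1))
    place_decoy(prot, "single_domain")
  }
  for (i in seq_len(cfg$n_decoy_homology)) {
    # shares a long stretch of a seed's backbone but carries no domain
    seed <- seeds[[(i - 1) %% 2 + 1]]
    backbone <- substr(seed, nchar(seed) - 180, nchar(seed))
    backbone <- gsub("HH...D[GA]", "", backbone)
    prot <- paste0(random_protein(120), backbone,
                   random_protein(max(20, cfg$protein_length - 120 -
                                        nchar(backbone))))
    place_decoy(prot, "homology_only")
  }
  for (i in seq_len(cfg$n_decoy_random))
    place_decoy(random_protein(sample(300:550, 1)), "random")

  # --- realize gene models along each chromosome
  ids <- names(placements)
  pl <- placements
  ord <- order(vapply(pl, `[[`, "", "chrom"), vapply(pl, `[[`, 0, "rank"))
  ids <- ids[ord]; pl <- pl[ord]
  models <- list(); pos <- stats::setNames(rep(1, n_chr), chroms)
  for (i in seq_along(ids)) {
    p <- pl[[i]]
    cds_len <- 3 * nchar(p$protein) + 3
    g <- simulate_gene_model(ids[i], p$chrom, pos[p$chrom], cds_len,
                             cfg$n_exons)
    pos[p$chrom] <- g$end + sample(500:2000, 1)
    models[[ids[i]]] <- g
  }

  truth <- data.frame(
    gene_id = ids,
    chrom = vapply(pl, `[[`, "", "chrom"),
    rank = vapply(pl, function(x) as.integer(x$rank), 0L),
    is_family = vapply(pl, `[[`, NA, "is_family"),
    mode = vapply(pl, function(x) as.character(x$mode)[1], ""),
    subfamily = vapply(pl, function(x) as.character(x$subfamily)[1], ""),
    decoy_type = vapply(pl, function(x) as.character(x$decoy_type)[1], ""),
    row.names = NULL)

  orders <- data.frame(gene_id = ids,
                       chrom = truth$chrom, rank = truth$rank)
  list(proteome = stats::setNames(vapply(pl, `[[`, "", "protein"), ids),
       models = models, orders = orders, truth = truth,
       seeds = seeds, config = cfg)
}

# one gene model at a left coordinate: n exons carrying the CDS plus
# short UTRs at both ends
simulate_gene_model <- function(id, chrom, left, cds_len, n_exons) {
  u5 <- sample(80:200, 1); u3 <- sample(80:250, 1)
  tx_len <- u5 + cds_len + u3
  cuts <- sort(sample(seq_len(tx_len - 1), n_exons - 1))
  exon_tx <- cbind(c(1, cuts + 1), c(cuts, tx_len))
  introns <- sample(100:800, n_exons - 1, replace = TRUE)
  starts <- numeric(n_exons); ends <- numeric(n_exons)
  at <- left
  for (e in seq_len(n_exons)) {
    len <- exon_tx[e, 2] - exon_tx[e, 1] + 1
    starts[e] <- at; ends[e] <- at + len - 1
    at <- ends[e] + 1 + if (e < n_exons) introns[e] else 0
  }
  # map transcript intervals to genomic intervals
  tx2gen <- function(a, b) {
    out <- matrix(numeric(0), ncol = 2)
    for (e in seq_len(n_exons)) {
      lo <- max(a, exon_tx[e, 1]); hi <- min(b, exon_tx[e, 2])
      if (lo > hi) next
      out <- rbind(out, c(starts[e] + lo - exon_tx[e, 1],
                          starts[e] + hi - exon_tx[e, 1]))
    }
    out
  }
  strand <- sample(c("+", "-"), 1)
  utr5 <- tx2gen(1, u5); utr3 <- tx2gen(tx_len - u3 + 1, tx_len)
  if (strand == "-") { tmp <- utr5; utr5 <- utr3; utr3 <- tmp }
  gene_model(id, chrom, starts[1], ends[n_exons], strand,
             exons = cbind(starts, ends), utr5 = utr5, utr3 = utr3)
}

#' Derive an orthologous genome from a simulated one
#'
#' Copies gene content and order onto a new subgenome letter, mutating
#' every protein at `mutation_rate`; the returned truth maps each new
#' gene to its source ortholog.
#'
#' @param genome Result of [generate_family_genome].
#' @param letter New subgenome letter.
#' @param mutation_rate Per-residue substitution probability.
#' @param seed RNG seed.
#' @return Same shape as [generate_family_genome] plus
#'   `ortholog_truth` (data.frame `gene_a`, `gene_b`).
#' @export
generate_ortholog_genome <- function(genome, letter = "B",
                                     mutation_rate = 0.02, seed = 2) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  src <- genome
  new_ids <- sub(paste0("^SIM", src$config$genome_letter),
                 paste0("SIM", letter), names(src$proteome))
  proteome <- stats::setNames(
    vapply(src$proteome, mutate_protein, "", rate = mutation_rate), new_ids)
  chrom_map <- function(ch) sub(paste0(src$config$genome_letter, "$"),
                                letter, ch)
  models <- lapply(seq_along(src$models), function(i) {
    g <- src$models[[i]]
    g$gene_id <- new_ids[match(names(src$models)[i], names(src$proteome))]
    g$chrom <- chrom_map(g$chrom)
    g
  })
  names(models) <- vapply(models, `[[`, "", "gene_id")
  orders <- src$orders
  orders$gene_id <- new_ids[match(orders$gene_id, names(src$proteome))]
  orders$chrom <- chrom_map(orders$chrom)
  truth <- src$truth
  truth$gene_id <- new_ids[match(truth$gene_id, names(src$proteome))]
  truth$chrom <- chrom_map(truth$chrom)
  list(proteome = proteome, models = models, orders = orders,
       truth = truth, seeds = src$seeds, config = src$config,
       ortholog_truth = data.frame(gene_a = names(src$proteome),
                                   gene_b = new_ids))
}
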
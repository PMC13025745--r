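toy_orders <- function(ids, chrom = "c1") {
  data.frame(gene_id = ids, chrom = chrom, rank = seq_along(ids))
}

test_that("identical proteomes anchor along the diagonal", {
  set.seed(51)
  prots <- stats::setNames(replicate(5, random_peptide(120)),
                           paste0("g", 1:5))
  ord <- toy_orders(names(prots))
  anc <- find_anchors(prots, prots, ord, ord, prefilter_kmers = 0)
  # every gene pairs with itself (self = FALSE keeps the diagonal)
  expect_true(all(paste0("g", 1:5) %in%
                    anc$gene_a[anc$gene_a == anc$gene_b]))
  diag_hits <- anc[anc$gene_a == anc$gene_b, ]
  expect_true(all(diag_hits$identity == 1))
  # within-genome run drops self-pairs
  anc_self <- find_anchors(prots, prots, ord, ord, self = TRUE,
                           prefilter_kmers = 0)
  expect_false(any(anc_self$gene_a == anc_self$gene_b))
})

test_that("anchors below the identity threshold are excluded", {
  set.seed(52)
  a <- random_peptide(150)
  # mutate 80% of residues: far below 30% identity over any long alignment
  b <- wsdfam:::mutate_protein(a, 0.8)
  prots <- c(g1 = a, g2 = b)
  ord <- toy_orders(names(prots))
  anc <- find_anchors(prots, prots, ord, ord, self = TRUE,
                      prefilter_kmers = 0)
  expect_equal(nrow(anc), 0)
})

test_that("perfectly collinear anchors chain into one block", {
  anc <- data.frame(gene_a = paste0("a", 1:6), gene_b = paste0("b", 1:6),
                    score = 100, identity = 1, coverage = 1, evalue = 0,
                    chrom_a = "c1", rank_a = 1:6,
                    chrom_b = "c2", rank_b = 11:16)
  blocks <- chain_collinear(anc)
  expect_length(blocks, 1)
  expect_equal(nrow(blocks[[1]]$anchors), 6)
  expect_equal(blocks[[1]]$orientation, "same")
  # four anchors are below the minimum block size
  expect_length(chain_collinear(anc[1:4, ]), 0)
  expect_length(chain_collinear(anc[1:4, ], min_block_size = 4), 1)
})

test_that("inverted collinearity is chained with decreasing subject ranks", {
  anc <- data.frame(gene_a = paste0("a", 1:5), gene_b = paste0("b", 1:5),
                    score = 100, identity = 1, coverage = 1, evalue = 0,
                    chrom_a = "c1", rank_a = 1:5,
                    chrom_b = "c2", rank_b = 20:16)
  blocks <- chain_collinear(anc)
  expect_length(blocks, 1)
  expect_equal(blocks[[1]]$orientation, "inverted")
})

test_that("chaining equals exhaustive monotone-subsequence search", {
  set.seed(53)
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    anc <- data.frame(gene_a = paste0("a", 1:n), gene_b = paste0("b", 1:n),
                      score = 1, identity = 1, coverage = 1, evalue = 0,
                      chrom_a = "c1", rank_a = sample(1:30, n),
                      chrom_b = "c2", rank_b = sample(1:30, n))
    blocks <- chain_collinear(anc, min_block_size = 1)
    got <- max(vapply(blocks, `[[`, 0, "score"))
    expect_equal(got, chain_oracle(anc$rank_a, anc$rank_b),
                 tolerance = 1e-9)
  }
})

test_that("adding anchors never decreases the best chain score", {
  set.seed(54)
  n <- 10
  anc <- data.frame(gene_a = paste0("a", 1:n), gene_b = paste0("b", 1:n),
                    score = 1, identity = 1, coverage = 1, evalue = 0,
                    chrom_a = "c1", rank_a = sample(1:25, n),
                    chrom_b = "c2", rank_b = sample(1:25, n))
  base <- max(vapply(chain_collinear(anc[1:7, ], min_block_size = 1),
                     `[[`, 0, "score"))
  grown <- max(vapply(chain_collinear(anc, min_block_size = 1),
                      `[[`, 0, "score"))
  expect_gte(grown, base)
})

test_that("duplication modes follow the declared precedence", {
  # two adjacent identical genes, no block: both tandem
  anc <- data.frame(gene_a = "g1", gene_b = "g2", score = 10,
                    identity = 1, coverage = 1, evalue = 0,
                    chrom_a = "c1", rank_a = 1, chrom_b = "c1", rank_b = 2)
  cls <- classify_duplicates(c("g1", "g2"), anc, list())
  expect_equal(cls$mode, c("tandem", "tandem"))

  # a gene inside a block outranks its tandem relationship
  blk <- list(list(anchors = data.frame(gene_a = "g1", gene_b = "g9")))
  cls2 <- classify_duplicates(c("g1", "g2"), anc, blk)
  expect_equal(cls2$mode[cls2$gene_id == "g1"], "segmental")
  expect_equal(cls2$mode[cls2$gene_id == "g2"], "tandem")

  # proximal vs dispersed vs singleton
  anc3 <- data.frame(gene_a = c("p1", "d1"), gene_b = c("p2", "d2"),
                     score = 10, identity = 1, coverage = 1, evalue = 0,
                     chrom_a = "c1", rank_a = c(1, 1),
                     chrom_b = c("c1", "c2"), rank_b = c(5, 40))
  cls3 <- classify_duplicates(c("p1", "p2", "d1", "d2", "s1"), anc3, list())
  expect_equal(cls3$mode, c("proximal", "proximal", "dispersed",
                            "dispersed", "singleton"))
})

test_that("the planted duplication plan is recovered exactly at zero mutation", {
  gen <- sim_genome_cached()
  anc <- find_anchors(gen$proteome, gen$proteome, gen$orders, gen$orders,
                      self = TRUE)
  blocks <- chain_collinear(anc)
  fam <- gen$truth[gen$truth$is_family, ]
  cls <- classify_duplicates(fam$gene_id, anc, blocks)
  expect_equal(stats::setNames(cls$mode, cls$gene_id)[fam$gene_id],
               stats::setNames(fam$mode, fam$gene_id))
  # classification is a partition over the family
  expect_equal(nrow(cls), nrow(fam))
  expect_false(anyNA(cls$mode))
})

test_that("ortholog flagging is reciprocal-best within blocks", {
  anc <- data.frame(gene_a = c("a1", "a2", "a3", "a4", "a5"),
                    gene_b = c("b1", "b2", "b3", "b4", "b5"),
                    score = c(90, 80, 70, 60, 50),
                    identity = 1, coverage = 1, evalue = 0,
                    chrom_a = "c1", rank_a = 1:5,
                    chrom_b = "c2", rank_b = 1:5)
  blocks <- chain_collinear(anc)
  op <- ortholog_pairs(blocks)
  expect_equal(nrow(op), 5)
  expect_true(all(op$putative_ortholog))
  expect_equal(nrow(ortholog_pairs(list())), 0)
})

test_that("orthologs between simulated genomes are recovered at zero mutation", {
  gen <- sim_genome_cached()
  genB <- generate_ortholog_genome(gen, "B", mutation_rate = 0, seed = 8)
  anc <- find_anchors(gen$proteome, genB$proteome, gen$orders, genB$orders)
  blocks <- chain_collinear(anc)
  op <- ortholog_pairs(blocks)
  flagged <- op[op$putative_ortholog, ]
  truth <- genB$ortholog_truth
  got <- merge(flagged, truth, by = c("gene_a", "gene_b"))
  expect_equal(nrow(got), nrow(truth))
})
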
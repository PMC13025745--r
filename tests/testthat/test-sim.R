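test_that("generators are deterministic under a fixed seed", {
  dom <- sim_domains()
  cfg <- genome_sim_config(seed = 77)
  g1 <- generate_family_genome(cfg, dom)
  g2 <- generate_family_genome(cfg, dom)
  expect_identical(g1$proteome, g2$proteome)
  expect_identical(g1$truth, g2$truth)

  e1 <- generate_expression(expression_sim_config(seed = 77))
  e2 <- generate_expression(expression_sim_config(seed = 77))
  expect_identical(e1$fpkm, e2$fpkm)

  m <- build_pwm(c("ACGTACGT", "ACGTACGT"), "DNA", pseudocount = 0.1,
                 name = "m")
  p1 <- generate_promoters("g", list(m = m),
                           data.frame(target = "g", motif = "m",
                                      distance = 50, strand = "+"),
                           seed = 77)
  p2 <- generate_promoters("g", list(m = m),
                           data.frame(target = "g", motif = "m",
                                      distance = 50, strand = "+"),
                           seed = 77)
  expect_identical(p1$promoters, p2$promoters)
})

test_that("infeasible genome plans fail before emission", {
  expect_error(genome_sim_config(duplication_plan = c(tandem = 3)),
               "even")
  expect_error(genome_sim_config(duplication_plan = c(proximal = 2)),
               "tandem")
  expect_error(genome_sim_config(genes_per_chromosome = 3),
               "infeasible")
  expect_error(genome_sim_config(mutation_rate = 1), "mutation rate")
})

test_that("a zero-mutation tandem plan yields two identical adjacent genes", {
  dom <- sim_domains()
  g <- generate_family_genome(
    genome_sim_config(duplication_plan = c(tandem = 2),
                      n_decoy_single_domain = 0, n_decoy_homology = 0,
                      genes_per_chromosome = 20, n_chromosomes = 1,
                      seed = 5),
    dom)
  fam <- g$truth[g$truth$is_family, ]
  expect_equal(nrow(fam), 2)
  expect_equal(fam$mode, c("tandem", "tandem"))
  expect_equal(diff(fam$rank), 1)
  expect_identical(g$proteome[[fam$gene_id[1]]],
                   g$proteome[[fam$gene_id[2]]])
})

test_that("planted correlations are realized within tolerance", {
  # pcc = 1 with zero noise must give exactly 1
  exact <- generate_expression(expression_sim_config(
    tf_plan = data.frame(tf = "TF01", target = "FAM01", pcc = 1),
    dispersion = 0, libsize_sd = 0, seed = 21))
  expect_equal(stats::cor(exact$fpkm["TF01", ], exact$fpkm["FAM01", ]), 1)

  # moderate planted pcc: empirical intra-tissue and global correlations
  # land within +/- 0.05 with >= 30 samples per tissue
  ex <- generate_expression(expression_sim_config(
    tissues = c("Root", "LJ"), samples_per_tissue = 40,
    family_ids = "FAM01",
    peak_tissue = c(FAM01 = "LJ"),
    tf_plan = data.frame(tf = "TF01", target = "FAM01", pcc = 0.9),
    n_background = 5, n_null_tfs = 0, seed = 22))
  lj <- ex$metadata$sample[ex$metadata$tissue == "LJ"]
  r_intra <- stats::cor(ex$fpkm["TF01", lj], ex$fpkm["FAM01", lj])
  expect_equal(r_intra, 0.9, tolerance = 0.05 / 0.9)
  r_global <- stats::cor(ex$fpkm["TF01", ], ex$fpkm["FAM01", ])
  expect_gte(r_global, 0.85)
})

test_that("peak-tissue planting drives the maximal group mean", {
  ex <- generate_expression(expression_sim_config(seed = 23))
  for (g in names(ex$truth$peak_tissue)) {
    mu <- tapply(ex$fpkm[g, ], ex$truth$tissue_of_sample, mean)
    expect_equal(names(which.max(mu)), unname(ex$truth$peak_tissue[g]))
  }
})

test_that("promoter planting respects position, strand and bounds", {
  m <- build_pwm(c("TTGACCGATTCGAT", "TTGACCGATTCGAT"), "DNA",
                 pseudocount = 0.1, name = "m")
  pr <- generate_promoters("g", list(m = m),
                           data.frame(target = "g", motif = "m",
                                      distance = 250, strand = "-"),
                           promoter_length = 1000, seed = 24)
  hits <- scan_sequence(m, pr$promoters[["g"]], 1e-6, both_strands = TRUE,
                        tss_at_end = TRUE)
  expect_true(any(hits$distance_to_tss == 250 & hits$strand == "-"))
  expect_error(generate_promoters("g", list(m = m),
                                  data.frame(target = "g", motif = "m",
                                             distance = 2000,
                                             strand = "+"),
                                  promoter_length = 1000, seed = 1),
               "outside promoter")
})

test_that("two indistinguishable tissues are a null for sample grouping", {
  set.seed(25)
  # identical tissue means: grouping cannot recover the labels
  mat <- matrix(5 * exp(rnorm(10 * 12, 0, 0.2)), nrow = 10)
  colnames(mat) <- paste0("s", 1:12)
  rownames(mat) <- paste0("g", 1:10)
  meta <- data.frame(sample = colnames(mat),
                     tissue = rep(c("A", "B"), each = 6))
  gr <- group_samples(mat, meta, k_range = 2:4, min_group_size = 3)
  # any recovered split mixes the two labels before subdivision
  agreement <- vapply(split(meta$tissue, gr$assignment[meta$sample]),
                      function(tt) max(table(tt)) / length(tt), 0)
  expect_true(any(gr$groups$provenance != "initial") ||
                mean(agreement) < 1)
})
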
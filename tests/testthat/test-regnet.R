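test_that("Pearson estimates match a hand-rolled covariance oracle", {
  expect_equal(pcc(1:10, 2 * (1:10) + 1), 1.0)
  expect_equal(pcc(1:10, -(1:10)), -1.0)
  set.seed(91)
  for (i in 1:5) {
    x <- rnorm(10); y <- rnorm(10)
    oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(pcc(x, y), oracle, tolerance = 1e-12)
  }
  expect_warning(r <- pcc(rep(1, 5), rnorm(5)), "zero variance")
  expect_true(is.na(r))
  expect_error(pcc(1:2, 1:2), "length >= 3")
})

two_tissue_fixture <- function() {
  # two tissues with shifted means; within-tissue noise independent,
  # so the global PCC is confounded but the intra-tissue PCC is ~0
  set.seed(92)
  n <- 20
  tissue <- rep(c("T1", "T2"), each = n)
  shift <- ifelse(tissue == "T1", 0, 50)
  tfv <- shift + rnorm(2 * n)
  tgv <- shift + rnorm(2 * n)
  samples <- paste0("s", seq_along(tfv))
  mat_tf <- matrix(tfv, 1, dimnames = list("TFX", samples))
  mat_tg <- matrix(tgv, 1, dimnames = list("GY", samples))
  grouping <- list(assignment = stats::setNames(tissue, samples))
  list(tf = mat_tf, tg = mat_tg, grouping = grouping,
       peak = c(GY = "T2"))
}

test_that("the dual filter rejects correlations driven by tissue means", {
  fx <- two_tissue_fixture()
  expect_gt(stats::cor(fx$tf[1, ], fx$tg[1, ]), 0.9)   # global confound
  ev <- dual_filter(fx$tf, fx$tg, fx$grouping, fx$peak, threshold = 0.9)
  expect_equal(nrow(ev), 0)
})

test_that("planted co-expressed pairs pass and thresholds are monotone", {
  ex <- generate_expression(expression_sim_config(seed = 11))
  gr <- group_samples(ex$fpkm, ex$metadata)
  at <- build_atlas(ex$fpkm, gr)
  tfs <- unique(ex$config$tf_plan$tf)
  nulls <- grep("^NULLTF", rownames(ex$fpkm), value = TRUE)
  tf_mat <- ex$fpkm[c(tfs, nulls), , drop = FALSE]
  tg_mat <- ex$fpkm[ex$config$family_ids, , drop = FALSE]
  ev85 <- dual_filter(tf_mat, tg_mat, gr, at$peak_group, threshold = 0.85)
  ev95 <- dual_filter(tf_mat, tg_mat, gr, at$peak_group, threshold = 0.95)
  key <- function(d) paste(d$tf, d$target)
  expect_true(all(key(ev95) %in% key(ev85)))
  # an unattainable threshold empties the result
  ev_imposs <- dual_filter(tf_mat, tg_mat, gr, at$peak_group,
                           threshold = 1.01)
  expect_equal(nrow(ev_imposs), 0)
})

test_that("candidate clustering recovers planted TF modules", {
  set.seed(93)
  base1 <- rnorm(30); base2 <- rnorm(30)
  prof <- rbind(
    tfA1 = base1 + rnorm(30, 0, 0.05), tfA2 = base1 + rnorm(30, 0, 0.05),
    tfA3 = base1 + rnorm(30, 0, 0.05),
    tfB1 = base2 + rnorm(30, 0, 0.05), tfB2 = base2 + rnorm(30, 0, 0.05))
  cl <- cluster_candidates(prof, k_range = 2:4)
  expect_equal(cl$k, 2)
  expect_length(unique(cl$cluster[c("tfA1", "tfA2", "tfA3")]), 1)
  expect_length(unique(cl$cluster[c("tfB1", "tfB2")]), 1)
  expect_false(cl$cluster[["tfA1"]] == cl$cluster[["tfB1"]])

  # identical profiles collapse to one cluster
  same <- rbind(a = base1, b = base1, c = base1)
  cl2 <- cluster_candidates(same)
  expect_equal(unname(cl2$cluster), rep(1L, 3))

  # small instances: chosen k matches exhaustive search over k_range
  small <- prof[1:5, ]
  d <- 1 - stats::cor(t(small))
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  ks <- 2:4
  oracle <- ks[which.max(vapply(ks, function(k)
    dunn2_index(d, stats::cutree(tree, k)), 0))]
  expect_equal(cluster_candidates(small, k_range = ks)$k, oracle)
})

test_that("TF-motif mapping is best-hit with deterministic tie handling", {
  set.seed(94)
  p1 <- random_peptide(80); p2 <- random_peptide(80)
  db <- c(M2 = p1, M1 = p1, M9 = p2)   # M1/M2 identical on purpose
  got <- map_tf_to_motif(c(tf1 = p1), db)
  expect_equal(unname(got["tf1"]), "M1")   # lexicographic tie-break
  got2 <- map_tf_to_motif(c(tf2 = p2), db)
  expect_equal(unname(got2["tf2"]), "M9")
  expect_warning(map_tf_to_motif(c(tfX = random_peptide(60)), db),
                 "unmapped")
})

test_that("promoter binding sites confirm planted regulatory pairs", {
  m <- build_pwm(rep("TTGACCGATTCGAT", 3), "DNA",
                 pseudocount = 0.2, name = "MOT1")
  motifs <- list(MOT1 = m)
  pr <- generate_promoters(c("tgt1", "tgt2", "tgt3"), motifs,
                           data.frame(target = c("tgt1", "tgt3"),
                                      motif = "MOT1",
                                      distance = c(100, 1500),
                                      strand = c("+", "-")),
                           promoter_length = 2000, seed = 12)
  ev <- data.frame(tf = "tfZ", target = c("tgt1", "tgt2", "tgt3"),
                   pcc_global = 0.95, pcc_intra = 0.95,
                   n_global = 60, n_intra = 10)
  rp <- tfbs_crossvalidate(ev, pr$promoters, motifs, c(tfZ = "MOT1"),
                           p_threshold = 1e-6)
  expect_equal(rp$status[rp$target == "tgt1"], "TFBS-supported")
  expect_equal(rp$best_distance_to_tss[rp$target == "tgt1"], 100)
  expect_true(rp$within_window[rp$target == "tgt1"])
  # background-only promoter: correlation-only
  expect_equal(rp$status[rp$target == "tgt2"], "correlation-only")
  # distal hit: supported but outside the 500 bp window
  expect_equal(rp$status[rp$target == "tgt3"], "TFBS-supported")
  expect_false(rp$within_window[rp$target == "tgt3"])
})
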
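test_that("expression filtering keeps genes by their maximum FPKM", {
  mat <- rbind(on = c(0, 5, 0), low = c(0.9, 0.4, 0), silent = c(0, 0, 0))
  colnames(mat) <- paste0("s", 1:3)
  expect_equal(rownames(filter_expressed(mat, 0)), rownames(mat))
  expect_equal(rownames(filter_expressed(mat, 1)), "on")
  expect_equal(rownames(filter_expressed(mat, 0, strict = TRUE)),
               c("on", "low"))
  expect_error(filter_expressed(mat - 1, 0), "negative")
})

test_that("Dunn2 matches hand computation and the brute-force oracle", {
  x <- c(0, 0.1, 10, 10.1)
  d <- abs(outer(x, x, "-"))
  expect_equal(dunn2_index(d, c(1, 1, 2, 2)), 100)
  # identical clusters at one point: zero within-average
  d0 <- matrix(0, 4, 4)
  expect_equal(dunn2_index(d0, c(1, 1, 2, 2)), Inf)
  expect_error(dunn2_index(d, c(1, 2, 3, 4)), "singleton")

  set.seed(71)
  for (rep in 1:10) {
    n <- sample(5:8, 1)
    pts <- stats::runif(n, 0, 10)
    dd <- abs(outer(pts, pts, "-"))
    labs <- sample(1:3, n, replace = TRUE)
    if (length(unique(labs)) < 2 || all(table(labs) == 1)) next
    expect_equal(dunn2_index(dd, labs), dunn2_oracle(dd, labs))
  }
})

test_that("sample grouping recovers planted tissues without subdivision", {
  ex <- generate_expression(expression_sim_config(
    tissues = c("Root", "Leaf", "LJ"), samples_per_tissue = 5,
    family_ids = sprintf("FAM%02d", 1:9),
    tf_plan = data.frame(tf = character(0), target = character(0),
                         pcc = numeric(0)),
    n_background = 20, n_null_tfs = 0, seed = 5))
  gr <- group_samples(ex$fpkm, ex$metadata, k_range = 2:8)
  expect_equal(nrow(gr$groups), 3)
  expect_true(all(gr$groups$provenance == "initial"))
  # each group is tissue-pure
  expect_false(any(grepl(",", gr$groups$tissues)))
})

test_that("undersized groups are merged until the minimum size holds", {
  set.seed(72)
  # 2 strong tissues plus one 2-sample outlier tissue
  mat <- cbind(matrix(rep(c(50, 2, 2), 5) , nrow = 3),
               matrix(rep(c(2, 50, 2), 5), nrow = 3),
               matrix(rep(c(2, 2, 50), 2), nrow = 3))
  mat <- mat * matrix(exp(rnorm(length(mat), 0, 0.05)), nrow = 3)
  mat <- rbind(mat, matrix(stats::runif(12 * 5, 0, 5), nrow = 5))
  colnames(mat) <- paste0("s", 1:12)
  rownames(mat) <- paste0("g", 1:8)
  meta <- data.frame(sample = colnames(mat),
                     tissue = rep(c("A", "B", "C"), c(5, 5, 2)))
  gr <- group_samples(mat, meta, k_range = 2:6, min_group_size = 3)
  expect_true(all(gr$groups$n >= 3))
  expect_true(any(gr$groups$provenance == "merged"))
})

test_that("tissue-mixed clusters are split by tissue label", {
  set.seed(73)
  # two tissues with identical expression: one cluster, mixed labels
  mat <- matrix(rep(c(10, 30, 5), 8), nrow = 3) *
    matrix(exp(rnorm(24, 0, 0.02)), nrow = 3)
  # add a distinct third tissue so k = 2 separates it
  mat <- cbind(mat, matrix(rep(c(50, 1, 1), 4), nrow = 3) *
                 matrix(exp(rnorm(12, 0, 0.02)), nrow = 3))
  colnames(mat) <- paste0("s", 1:12)
  rownames(mat) <- paste0("g", 1:3)
  meta <- data.frame(sample = colnames(mat),
                     tissue = rep(c("A", "B", "C"), each = 4))
  gr <- group_samples(mat, meta, k_range = 2:2, min_group_size = 2)
  expect_true(any(gr$groups$provenance == "subdivided"))
  expect_false(any(grepl(",", gr$groups$tissues)))
})

test_that("atlas layers follow the declared normalization conventions", {
  mat <- rbind(g1 = c(0, 0, 3, 3), konst = c(2, 2, 2, 2))
  colnames(mat) <- paste0("s", 1:4)
  grouping <- list(assignment = stats::setNames(
    c("G1", "G1", "G2", "G2"), colnames(mat)))
  at <- build_atlas(mat, grouping)
  expect_equal(unname(at$mean_fpkm["g1", ]), c(0, 3))
  expect_equal(unname(at$log2["g1", ]), c(0, 2))
  expect_equal(unname(at$minmax["g1", ]), c(0, 1))
  # constant genes map to all zeros
  expect_equal(unname(at$minmax["konst", ]), c(0, 0))
  expect_equal(unname(at$peak_group["g1"]), "G2")
  # min-max bounds and idempotence
  expect_true(all(at$minmax >= 0 & at$minmax <= 1))
  rescale <- function(x) {
    s <- max(x) - min(x)
    if (s == 0) x * 0 else (x - min(x)) / s
  }
  expect_equal(t(apply(at$minmax, 1, rescale)), at$minmax)
})

test_that("planted peak tissues surface as atlas peak groups", {
  ex <- generate_expression(expression_sim_config(seed = 9))
  gr <- group_samples(ex$fpkm, ex$metadata)
  at <- build_atlas(ex$fpkm, gr)
  tissue_of_group <- vapply(split(
    ex$truth$tissue_of_sample[names(gr$assignment)], gr$assignment),
    function(x) paste(unique(x), collapse = ","), "")
  fam <- names(ex$truth$peak_tissue)
  expect_equal(unname(tissue_of_group[at$peak_group[fam]]),
               unname(ex$truth$peak_tissue))
})

test_that("silent genes drop out of a filtered synthetic atlas", {
  ex <- generate_expression(expression_sim_config(seed = 10))
  mat <- ex$fpkm
  mat <- rbind(mat, silent1 = 0, silent2 = 0)
  filtered <- filter_expressed(mat, 1)
  expect_equal(setdiff(rownames(mat), rownames(filtered)),
               c("silent1", "silent2"))
})
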
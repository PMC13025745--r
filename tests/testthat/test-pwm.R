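test_that("PWM columns follow the pseudocount-smoothed counts", {
  p0 <- build_pwm(c("ACGT"), "DNA", pseudocount = 0)
  expect_equal(unname(p0$prob[1, ]), c(1, 0, 0, 0))
  expect_equal(unname(p0$prob[2, ]), c(0, 1, 0, 0))

  p <- build_pwm(c("AA", "AC"), "DNA", pseudocount = 0)
  expect_equal(unname(p$prob[2, c("A", "C")]), c(0.5, 0.5))

  # pseudocount -> infinity pulls every column to the background
  pbig <- build_pwm(c("AA", "AC"), "DNA", pseudocount = 1e9)
  expect_equal(unname(pbig$prob[1, ]), rep(0.25, 4), tolerance = 1e-6)

  expect_error(build_pwm(character(0)), "at least one")
  expect_error(build_pwm(c("AA", "ACG")), "equal length")
  expect_error(build_pwm("AA", "DNA", background = c(A = 0.5, C = 0.5,
                                                     G = 0, T = 0)),
               "strictly positive")
})

test_that("exact p-value tables equal exhaustive enumeration", {
  set.seed(31)
  # DNA up to width 5
  for (w in c(1, 2, 3, 5)) {
    inst <- replicate(3, paste(sample(c("A", "C", "G", "T"), w,
                                      replace = TRUE), collapse = ""))
    pwm <- build_pwm(inst, "DNA", pseudocount = 0.3)
    tab <- pwm_pvalues(pwm)
    enum <- pwm_enum_oracle(pwm)
    for (s in tab$score)
      expect_equal(pwm_pvalue_of(tab, s), pwm_enum_pvalue(enum, s),
                   tolerance = 1e-12)
    # total probability at the minimum achievable score
    expect_equal(pwm_pvalue_of(tab, min(tab$score)), 1.0)
  }
  # protein up to width 3
  for (w in c(2, 3)) {
    inst <- replicate(2, random_peptide(w))
    pwm <- build_pwm(inst, "protein", pseudocount = 0.5)
    tab <- pwm_pvalues(pwm)
    enum <- pwm_enum_oracle(pwm)
    for (s in sample(tab$score, min(20, length(tab$score))))
      expect_equal(pwm_pvalue_of(tab, s), pwm_enum_pvalue(enum, s),
                   tolerance = 1e-12)
  }
})

test_that("a width-1 uniform-background PWM has max-score p-value 1/4", {
  pwm <- build_pwm("A", "DNA", pseudocount = 0.1)
  tab <- pwm_pvalues(pwm)
  expect_equal(pwm_pvalue_of(tab, max(tab$score)), 0.25)
})

test_that("scanning finds planted instances on both strands", {
  set.seed(32)
  pwm <- build_pwm(c("TTGACCGATT", "TTGACCGATT", "TTGACTGATT"), "DNA",
                   pseudocount = 0.2, name = "m")
  bg <- random_dna_str(300)
  planted <- paste0(substr(bg, 1, 99), "TTGACCGATT", substr(bg, 110, 300))
  hits <- scan_sequence(pwm, planted, 1e-4)
  expect_true(100 %in% hits$start)

  rc <- wsdfam:::revcomp("TTGACCGATT")
  planted_m <- paste0(substr(bg, 1, 49), rc, substr(bg, 60, 300))
  plus_only <- scan_sequence(pwm, planted_m, 1e-4, both_strands = FALSE)
  both <- scan_sequence(pwm, planted_m, 1e-4, both_strands = TRUE)
  expect_false(50 %in% plus_only$start)
  expect_true(any(both$start == 50 & both$strand == "-"))
})

test_that("scanning a concatenation yields the union of shifted hits", {
  set.seed(33)
  pwm <- build_pwm(c("TTGACCGATT", "TTGACCGATT"), "DNA",
                   pseudocount = 0.2)
  s1 <- paste0(random_dna_str(40), "TTGACCGATT", random_dna_str(40))
  s2 <- paste0(random_dna_str(20), "TTGACCGATT", random_dna_str(60))
  tab <- pwm_pvalues(pwm)
  h1 <- scan_sequence(pwm, s1, 1e-4, tab = tab)
  h2 <- scan_sequence(pwm, s2, 1e-4, tab = tab)
  cat12 <- paste0(s1, s2)
  h12 <- scan_sequence(pwm, cat12, 1e-4, tab = tab)
  # all original hits appear at their original / shifted positions
  expect_true(all(h1$start %in% h12$start))
  expect_true(all((h2$start + nchar(s1)) %in% h12$start))
})

test_that("promoter hits report distance upstream of the TSS", {
  pwm <- build_pwm(c("TTGACCGATT", "TTGACCGATT"), "DNA", pseudocount = 0.2)
  set.seed(34)
  pr <- generate_promoters("g1", list(m = pwm),
                           data.frame(target = "g1", motif = "m",
                                      distance = 100, strand = "+"),
                           promoter_length = 500, seed = 3)
  hits <- scan_sequence(pwm, pr$promoters[["g1"]], 1e-4,
                        both_strands = TRUE, tss_at_end = TRUE)
  expect_true(100 %in% hits$distance_to_tss)
})

test_that("IUPAC scanning honors degeneracy and strand", {
  cat <- data.frame(element = "e", pattern = "TGACG")
  h <- scan_iupac(cat, "AATGACGA", both_strands = FALSE)
  expect_equal(h$start, 3)
  # reverse complement of TGACG is CGTCA
  h2 <- scan_iupac(cat, "ACGTCAAA", both_strands = TRUE)
  expect_true(any(h2$strand == "-"))
  h2p <- scan_iupac(cat, "ACGTCAAA", both_strands = FALSE)
  expect_equal(nrow(h2p), 0)

  deg <- data.frame(element = "r", pattern = "RGTCA")
  expect_equal(nrow(scan_iupac(deg, "AGTCA", both_strands = FALSE)), 1)
  expect_equal(nrow(scan_iupac(deg, "GGTCA", both_strands = FALSE)), 1)
  expect_equal(nrow(scan_iupac(deg, "CGTCA", both_strands = FALSE)), 0)
  expect_error(scan_iupac(data.frame(element = "z", pattern = "TGAZG"),
                          "AAAA"), "invalid IUPAC")
})

test_that("catalytic heptapeptide detection reports canonical and variant forms", {
  expect_equal(check_catalytic_motif("MKHHSLVDGRR")$status, "present")
  expect_equal(check_catalytic_motif("MKHHSLVDARR")$status, "variant")
  expect_equal(check_catalytic_motif("MKHASLVDGRR")$status, "absent")
  r <- check_catalytic_motif("MKHHSLVDGRR")
  expect_equal(r$position, 3L)
  expect_equal(r$segment, "HHSLVDG")
})
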
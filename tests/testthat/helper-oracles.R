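# Independent brute-force oracles used to pin expected values.

# Gotoh local alignment, naive O(nm) three-matrix DP; a gap of length L
# costs open + L * ext (matching the package's scoring convention).
sw_oracle <- function(a, b, scheme = scoring_scheme()) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  mat <- scheme$matrix
  open <- scheme$gap_open; ext <- scheme$gap_extend
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
    F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
    s <- mat[A[i - 1], B[j - 1]]
    H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
    if (H[i, j] > best) best <- H[i, j]
  }
  best
}

random_peptide <- function(n)
  paste(sample(wsdfam:::PROTEIN_ALPHABET, n, replace = TRUE), collapse = "")

random_dna_str <- function(n) wsdfam:::random_dna(n)

# exhaustive enumeration of the PWM score distribution
pwm_enum_oracle <- function(pwm) {
  combos <- expand.grid(rep(list(seq_along(pwm$alphabet)), pwm$width))
  sc <- apply(combos, 1, function(ix)
    sum(pwm$int[cbind(seq_len(pwm$width), ix)]))
  pr <- apply(combos, 1, function(ix)
    prod(pwm$background[ix]))
  list(score = sc, prob = pr)
}

pwm_enum_pvalue <- function(enum, s) sum(enum$prob[enum$score >= s])

# exhaustive best monotone chain over all anchor subsets
chain_oracle <- function(rank_a, rank_b, max_gap = 25, gap_penalty = 0.2) {
  n <- length(rank_a)
  best <- -Inf
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    o <- order(rank_a[idx])
    ia <- rank_a[idx][o]
    for (orient in c(1, -1)) {
      ib <- orient * rank_b[idx][o]
      da <- diff(ia); db <- diff(ib)
      if (length(idx) > 1 &&
          (any(da <= 0) || any(db <= 0) ||
           any(da > max_gap) || any(db > max_gap))) next
      sc <- length(idx) -
        if (length(idx) > 1) gap_penalty * sum((da - 1) + (db - 1)) else 0
      if (sc > best) best <- sc
      if (orient == -1 && length(idx) == 1) break
    }
  }
  best
}

# double-loop Dunn2
dunn2_oracle <- function(d, labels) {
  d <- as.matrix(d)
  cl <- unique(labels)
  min_between <- Inf; max_within <- -Inf
  for (a in seq_along(cl)) {
    ii <- which(labels == cl[a])
    if (length(ii) > 1) {
      tot <- 0; np <- 0
      for (x in ii) for (y in ii) if (x < y) { tot <- tot + d[x, y]; np <- np + 1 }
      max_within <- max(max_within, tot / np)
    }
    for (b in seq_along(cl)) {
      if (b <= a) next
      jj <- which(labels == cl[b])
      tot <- 0; np <- 0
      for (x in ii) for (y in jj) { tot <- tot + d[x, y]; np <- np + 1 }
      min_between <- min(min_between, tot / np)
    }
  }
  if (max_within == -Inf) stop("all singletons")
  if (max_within == 0) return(Inf)
  min_between / max_within
}

# brute-force qualifying-clade filter: every internal non-root node with
# support >= min_support and >= min_size tips and no qualifying ancestor
clades_oracle <- function(tree, min_support, min_size) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1
  desc <- function(node) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    if (!length(kids)) return(tree$tip.label[node])
    unlist(lapply(kids, desc))
  }
  parent_of <- function(node) {
    p <- tree$edge[tree$edge[, 2] == node, 1]
    if (length(p)) p else NA
  }
  nodes <- (ntip + 1):(ntip + tree$Nnode)
  qual <- vapply(nodes, function(nd) {
    if (nd == root) return(FALSE)
    s <- tree$support[nd - ntip]
    !is.na(s) && s >= min_support && length(desc(nd)) >= min_size
  }, NA)
  names(qual) <- nodes
  keep <- vapply(nodes, function(nd) {
    if (!qual[as.character(nd)]) return(FALSE)
    p <- parent_of(nd)
    while (!is.na(p)) {
      if (p > ntip && p != root && qual[as.character(p)]) return(FALSE)
      p <- parent_of(p)
    }
    TRUE
  }, NA)
  lapply(nodes[keep], function(nd) sort(desc(nd)))
}

# small shared fixtures -------------------------------------------------

sim_domains <- function() {
  if (is.null(.wsdfam_test_env$domains))
    .wsdfam_test_env$domains <- make_domain_profiles()
  .wsdfam_test_env$domains
}

sim_genome_cached <- function() {
  if (is.null(.wsdfam_test_env$genome))
    .wsdfam_test_env$genome <-
      generate_family_genome(genome_sim_config(seed = 7), sim_domains())
  .wsdfam_test_env$genome
}

.wsdfam_test_env <- new.env(parent = emptyenv())
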
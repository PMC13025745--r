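DNA_ALPHABET <- c("A", "C", "G", "T")
PROTEIN_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

IUPAC_DNA <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
               S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT",
               D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

revcomp <- function(seq) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(seq, function(s)
           paste(rev(strsplit(s, "")[[1]]), collapse = ""), ""))
}

#' Build a position weight matrix from aligned instances
#'
#' Column probabilities are `(count + pseudocount * background) /
#' (n + pseudocount)`; log-odds are taken against the background and
#' integerized at 1/1000-bit granularity for exact p-value computation.
#' Letters with zero probability get a `-Inf` log-odds (only possible with
#' `pseudocount = 0`); windows containing them score `-Inf`.
#'
#' @param instances Character vector of equal-length sequences over the
#'   alphabet, or a probability matrix (width x alphabet) passed directly.
#' @param alphabet `"DNA"`, `"protein"`, or a character vector of letters.
#' @param pseudocount Total pseudocount distributed by background frequency.
#' @param background Named probability vector over the alphabet (default
#'   uniform); must be strictly positive.
#' @param name Optional motif name.
#' @return Object of class `pwm`: `alphabet`, `width`, `prob`
#'   (width x alphabet), `background`, `logodds` (bits), `int` (integer
#'   log-odds, 1/1000 bit), `scale`, `name`.
#' @export
build_pwm <- function(instances, alphabet = "DNA", pseudocount = 0.1,
                      background = NULL, name = NULL) {
  letters_ <- switch(alphabet[1],
                     DNA = DNA_ALPHABET, protein = PROTEIN_ALPHABET, alphabet)
  if (is.null(background))
    background <- stats::setNames(rep(1 / length(letters_), length(letters_)),
                                  letters_)
  background <- background[letters_]
  if (any(is.na(background)) || any(background <= 0))
    stop("background must be strictly positive over the full alphabet")
  background <- background / sum(background)

  if (is.matrix(instances)) {
    prob <- instances
    colnames(prob) <- letters_
    if (any(abs(rowSums(prob) - 1) > 1e-9))
      stop("probability rows must sum to 1")
  } else {
    if (!length(instances)) stop("need at least one instance")
    w <- unique(nchar(instances))
    if (length(w) != 1) stop("instances must have equal length")
    if (w == 0) stop("zero-width motif")
    chars <- do.call(rbind, strsplit(toupper(instances), ""))
    bad <- !chars %in% letters_
    if (any(bad)) stop("instance letter outside alphabet: ",
                       paste(unique(chars[bad]), collapse = ","))
    prob <- t(apply(chars, 2, function(col) {
      cnt <- table(factor(col, levels = letters_))
      (as.numeric(cnt) + pseudocount * background) /
        (length(col) + pseudocount)
    }))
    colnames(prob) <- letters_
  }
  lo <- log2(sweep(prob, 2, background, "/"))
  int <- round(lo * 1000)
  int[is.infinite(int)] <- -Inf
  structure(list(alphabet = letters_, width = nrow(prob), prob = prob,
                 background = background, logodds = lo, int = int,
                 scale = 1000, name = name %||% "motif"),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s: width %d over %d-letter alphabet\n",
              x$name, x$width, length(x$alphabet)))
  invisible(x)
}

#' Exact score distribution and p-values of a PWM
#'
#' Computes, by position-wise convolution under the i.i.d. background, the
#' exact probability of every achievable integerized score, and the upper
#' tail `P(score >= s)`. Exact to the integerization grid (1/1000 bit).
#'
#' @param pwm A [build_pwm] object.
#' @return List with `score` (sorted achievable integer scores), `prob`,
#'   `pvalue` (`P(score >= score[i])`), and `neginf_mass` (background mass
#'   of windows containing a zero-probability letter).
#' @export
pwm_pvalues <- function(pwm) {
  if (pwm$width == 0) stop("zero-width PWM")
  int <- pwm$int
  # offset-indexed distribution over the cumulative integer score
  cur_lo <- 0; cur_hi <- 0
  dist <- 1                      # start: score 0 with prob 1
  neginf <- 0
  for (i in seq_len(pwm$width)) {
    row <- int[i, ]
    ok <- is.finite(row)
    if (!any(ok)) stop("PWM position ", i, " has no finite log-odds")
    neginf <- neginf + sum(dist) * sum(pwm$background[!ok])
    new_lo <- cur_lo + min(row[ok])
    new_hi <- cur_hi + max(row[ok])
    new <- numeric(new_hi - new_lo + 1)
    for (j in which(ok)) {
      s <- row[j]
      idx <- (cur_lo + s - new_lo + 1):(cur_hi + s - new_lo + 1)
      new[idx] <- new[idx] + dist * pwm$background[j]
    }
    dist <- new
    cur_lo <- new_lo; cur_hi <- new_hi
  }
  nz <- dist > 0
  scores <- (cur_lo:cur_hi)[nz]
  probs <- dist[nz]
  pval <- rev(cumsum(rev(probs)))
  list(score = scores, prob = probs, pvalue = pval, neginf_mass = neginf)
}

#' P-value of integer scores under a PWM's exact null
#'
#' @param tab Table from [pwm_pvalues].
#' @param score Integerized score(s); `-Inf` allowed.
#' @return `P(score' >= score)` for each score.
#' @export
pwm_pvalue_of <- function(tab, score) {
  # smallest tabulated score >= s; scores below the minimum have p = 1
  out <- numeric(length(score))
  for (k in seq_along(score)) {
    s <- score[k]
    if (!is.finite(s) || s <= tab$score[1]) { out[k] <- 1; next }
    i <- findInterval(s - 1, tab$score) + 1   # first index with score >= s
    out[k] <- if (i > length(tab$score)) 0 else tab$pvalue[i]
  }
  out
}

window_scores <- function(pwm, seq) {
  res <- strsplit(toupper(seq), "")[[1]]
  L <- length(res)
  w <- pwm$width
  if (L < w) return(numeric(0))
  code <- match(res, pwm$alphabet)
  if (anyNA(code)) stop("sequence letter outside PWM alphabet: ",
                        paste(unique(res[is.na(code)]), collapse = ","))
  n_win <- L - w + 1
  sc <- numeric(n_win)
  for (i in seq_len(w)) sc <- sc + pwm$int[cbind(i, code[i:(i + n_win - 1)])]
  sc
}

#' Scan a sequence with a PWM at an exact p-value threshold
#'
#' All windows with `P(score >= s) < p_threshold` under the exact null are
#' reported. For DNA, `both_strands = TRUE` also scans the reverse
#' complement; minus-strand hits are reported in forward coordinates.
#'
#' @param pwm A [build_pwm] object.
#' @param seq Sequence string over the PWM alphabet.
#' @param p_threshold Exact p-value threshold (strict `<`).
#' @param both_strands Scan the reverse complement as well (DNA only).
#' @param tab Optional precomputed [pwm_pvalues] table.
#' @param seq_id Sequence id to carry in the output.
#' @param tss_at_end If `TRUE`, the sequence is a promoter whose 3' end
#'   abuts the transcription start site; each hit gets `distance_to_tss` =
#'   `length - (start + width - 1) + 1` bp upstream.
#' @return data.frame of hits: `seq_id`, `motif`, `start` (1-based),
#'   `strand`, `score` (bits), `pvalue`, and optionally `distance_to_tss`.
#' @export
scan_sequence <- function(pwm, seq, p_threshold = 1e-4, both_strands = FALSE,
                          tab = NULL, seq_id = "seq", tss_at_end = FALSE) {
  if (is.null(tab)) tab <- pwm_pvalues(pwm)
  strands <- if (both_strands) c("+", "-") else "+"
  L <- nchar(seq)
  out <- list()
  for (st in strands) {
    s <- if (st == "+") seq else revcomp(seq)
    sc <- window_scores(pwm, s)
    if (!length(sc)) next
    pv <- pwm_pvalue_of(tab, sc)
    hit <- which(pv < p_threshold)
    if (!length(hit)) next
    start_fwd <- if (st == "+") hit else L - (hit + pwm$width - 1) + 1
    out[[st]] <- data.frame(seq_id = seq_id, motif = pwm$name,
                            start = start_fwd, strand = st,
                            score = sc[hit] / pwm$scale, pvalue = pv[hit])
  }
  hits <- if (length(out)) do.call(rbind, out) else
    data.frame(seq_id = character(0), motif = character(0),
               start = integer(0), strand = character(0),
               score = numeric(0), pvalue = numeric(0))
  rownames(hits) <- NULL
  if (tss_at_end)
    hits$distance_to_tss <- L - (hits$start + pwm$width - 1) + 1
  hits[order(hits$start), , drop = FALSE]
}

iupac_to_regex <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- !chars %in% names(IUPAC_DNA)
  if (any(bad)) stop("invalid IUPAC code: ",
                     paste(unique(chars[bad]), collapse = ","))
  paste(vapply(chars, function(c) {
    opts <- IUPAC_DNA[[c]]
    if (nchar(opts) == 1) opts else paste0("[", opts, "]")
  }, ""), collapse = "")
}

#' Scan a sequence for IUPAC cis-element patterns
#'
#' Exact (possibly overlapping) matches of each catalog pattern; with
#' `both_strands`, minus-strand matches are reported at the forward-strand
#' start of the matched window.
#'
#' @param catalog data.frame with columns `element`, `pattern` (IUPAC DNA),
#'   and optionally `category`.
#' @param seq DNA sequence.
#' @param both_strands Also scan the minus strand.
#' @param seq_id Sequence id carried in the output.
#' @return data.frame of hits: `seq_id`, `element`, `category`, `start`,
#'   `strand`.
#' @export
scan_iupac <- function(catalog, seq, both_strands = TRUE, seq_id = "seq") {
  out <- list()
  for (i in seq_len(nrow(catalog))) {
    pat <- catalog$pattern[i]
    for (st in if (both_strands) c("+", "-") else "+") {
      target <- if (st == "+") pat else revcomp(pat)
      rx2 <- paste0("(?=", iupac_to_regex(target), ")")
      m <- gregexpr(rx2, toupper(seq), perl = TRUE)[[1]]
      pos <- m[m > 0]
      if (!length(pos)) next
      out[[length(out) + 1]] <- data.frame(
        seq_id = seq_id, element = catalog$element[i],
        category = if ("category" %in% names(catalog)) catalog$category[i]
                   else NA_character_,
        start = pos, strand = st)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(seq_id = character(0), element = character(0),
               category = character(0), start = integer(0),
               strand = character(0))
  rownames(res) <- NULL
  res[order(res$element, res$start), , drop = FALSE]
}

#' Per-promoter cis-element count matrix
#'
#' @param catalog IUPAC element catalog, see [scan_iupac].
#' @param promoters Named character vector of promoter sequences.
#' @param both_strands Scan both strands.
#' @return Integer matrix promoters x elements.
#' @export
cis_element_counts <- function(catalog, promoters, both_strands = TRUE) {
  counts <- matrix(0L, nrow = length(promoters), ncol = nrow(catalog),
                   dimnames = list(names(promoters), catalog$element))
  for (p in seq_along(promoters)) {
    hits <- scan_iupac(catalog, promoters[[p]], both_strands,
                       seq_id = names(promoters)[p])
    if (nrow(hits)) {
      t <- table(factor(hits$element, levels = catalog$element))
      counts[p, ] <- as.integer(t)
    }
  }
  counts
}

#' Check a protein for the WS/DGAT catalytic heptapeptide
#'
#' The catalytic core of wax ester synthase / DGAT enzymes is the motif
#' HHXXXDG (H-H-any-any-any-D-G). Some family members carry a G-to-A
#' substitution at the final position; these are reported as `"variant"`.
#'
#' @param protein Protein sequence.
#' @return List: `status` (`"present"`, `"variant"`, `"absent"`),
#'   `position` (1-based start of the match or `NA`), `segment` (matched
#'   7-mer or `NA`).
#' @export
check_catalytic_motif <- function(protein) {
  protein <- toupper(protein)
  m <- regexpr("HH...DG", protein)
  if (m > 0)
    return(list(status = "present", position = as.integer(m),
                segment = substr(protein, m, m + 6)))
  m <- regexpr("HH...DA", protein)
  if (m > 0)
    return(list(status = "variant", position = as.integer(m),
                segment = substr(protein, m, m + 6)))
  list(status = "absent", position = NA_integer_, segment = NA_character_)
}
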
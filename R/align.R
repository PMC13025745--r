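#' Scoring scheme for protein local alignment
#'
#' BLOSUM62 substitution scores with affine gap penalties and the
#' Karlin-Altschul parameters used to convert raw scores to E-values
#' (`E = K * m * n * exp(-lambda * S)`). The defaults are the standard
#' published constants for gapped BLOSUM62 (gap open 11 / extend 1):
#' lambda = 0.267, K = 0.041. `X` is treated as an ambiguity residue and
#' scored 0 against everything.
#'
#' @param gap_open,gap_extend Positive gap penalties; a gap of length L
#'   costs `gap_open + L * gap_extend`.
#' @param lambda,K Karlin-Altschul parameters.
#' @return List with the substitution matrix and parameters.
#' @export
scoring_scheme <- function(gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041) {
  stopifnot(lambda > 0, K > 0, gap_open >= 0, gap_extend > 0)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  mat <- BLOSUM62
  mat["X", ] <- 0L
  mat[, "X"] <- 0L
  list(matrix = mat, gap_open = gap_open, gap_extend = gap_extend,
       lambda = lambda, K = K)
}

evalue_from_score <- function(score, m, n, scheme) {
  scheme$K * m * n * exp(-scheme$lambda * score)
}

#' Optimal local alignment of two proteins
#'
#' Smith-Waterman local alignment with affine gaps under BLOSUM62 (via the
#' Biostrings alignment engine), returning the hit statistics used
#' throughout the pipeline: raw score, identity over alignment columns,
#' coverage of the shorter sequence, and the Karlin-Altschul E-value.
#'
#' @param a,b Protein sequences (single strings).
#' @param scheme A [scoring_scheme].
#' @param mn Search-space size `m * n` for the E-value; defaults to
#'   `nchar(a) * nchar(b)`. For a database search pass query length times
#'   total database residues.
#' @return data.frame with `score`, `aln_length` (columns incl. gaps),
#'   `identity`, `coverage`, `evalue`.
#' @export
local_align <- function(a, b, scheme = scoring_scheme(), mn = NULL) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  res <- local_align_many(a, b, scheme, mn = mn)
  res[, setdiff(names(res), "subject"), drop = FALSE]
}

#' Local alignment of one query against many subjects
#'
#' Vectorized form of [local_align]; the alignment engine is called once
#' for the whole subject set.
#'
#' @param a Query protein sequence.
#' @param subjects Character vector (optionally named) of subject sequences.
#' @inheritParams local_align
#' @return data.frame with one row per subject (`subject` column carries
#'   names) and the same statistics as [local_align].
#' @export
local_align_many <- function(a, subjects, scheme = scoring_scheme(), mn = NULL) {
  if (!nzchar(a) || any(!nzchar(subjects))) stop("empty sequence")
  pat <- Biostrings::AAStringSet(rep(a, length(subjects)))
  sub <- Biostrings::AAStringSet(unname(subjects))
  aln <- Biostrings::pairwiseAlignment(
    pat, sub, type = "local", substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  score <- Biostrings::score(aln)
  cols <- Biostrings::nchar(aln)
  ident <- Biostrings::nmatch(aln) / cols
  pat_aln <- Biostrings::aligned(Biostrings::pattern(aln))
  sub_aln <- Biostrings::aligned(Biostrings::subject(aln))
  gaps_pat <- Biostrings::vcountPattern("-", pat_aln)
  gaps_sub <- Biostrings::vcountPattern("-", sub_aln)
  len_a <- nchar(a)
  len_b <- nchar(subjects)
  shorter_is_a <- len_a <= len_b
  cov_cols <- ifelse(shorter_is_a, cols - gaps_pat, cols - gaps_sub)
  coverage <- cov_cols / pmin(len_a, len_b)
  if (is.null(mn)) mn <- len_a * len_b
  data.frame(subject = names(subjects) %||% as.character(seq_along(subjects)),
             score = score, aln_length = cols, identity = ident,
             coverage = coverage,
             evalue = scheme$K * mn * exp(-scheme$lambda * score),
             row.names = NULL)
}
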
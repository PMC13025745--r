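#' Gene-structure summary for a gene set
#'
#' Per-gene length (bp, 1-based inclusive), exon count and UTR presence,
#' plus family-level aggregates: the exon-count histogram, the number of
#' genes below a length threshold (strict `<`), and the number with both
#' UTRs annotated.
#'
#' @param genes List of [gene_model] objects.
#' @param length_threshold Length cutoff in bp (default 10 kb).
#' @return List with `per_gene` (data.frame: `gene_id`, `length_bp`,
#'   `n_exons`, `has_utr5`, `has_utr3`), `exon_histogram` (named integer
#'   vector), `n_below_threshold`, `n_both_utrs`, `length_range_bp`.
#' @export
structure_summary <- function(genes, length_threshold = 10000) {
  if (!length(genes)) stop("no genes to summarize")
  per <- data.frame(
    gene_id = vapply(genes, `[[`, "", "gene_id"),
    length_bp = vapply(genes, gene_length, 0),
    n_exons = vapply(genes, function(g) nrow(g$exons), 0L),
    has_utr5 = vapply(genes, function(g) nrow(g$utr5) > 0, NA),
    has_utr3 = vapply(genes, function(g) nrow(g$utr3) > 0, NA),
    row.names = NULL)
  hist <- table(per$n_exons)
  list(per_gene = per,
       exon_histogram = stats::setNames(as.integer(hist), names(hist)),
       n_below_threshold = sum(per$length_bp < length_threshold),
       n_both_utrs = sum(per$has_utr5 & per$has_utr3),
       length_range_bp = range(per$length_bp))
}
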
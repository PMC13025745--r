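#' Load the packaged wheat WSD family table
#'
#' The published genome-wide characterization of the wheat WSD (wax ester
#' synthase / diacylglycerol acyltransferase) family ships with the package
#' as a plain-text fixture: 43 family members with chromosomal coordinates,
#' strand, transcript counts, protein length, molecular weight (kDa),
#' isoelectric point, grand-average hydropathicity, and membrane type.
#'
#' @return A data.frame with 43 rows and columns `gene_name`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `n_transcripts`, `aa_length`,
#'   `mw` (kDa), `pi`, `hydropathicity`, `membrane_type`.
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1_wsd_wheat.tsv", package = "wsdfam")
  if (path == "" || !file.exists(path))
    stop("packaged family table fixture is missing; reinstall the package")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("gene_name", "gene_id", "chrom", "start", "end", "strand",
              "n_transcripts", "aa_length", "mw", "pi", "hydropathicity",
              "membrane_type")
  if (!identical(names(tab), needed))
    stop("family table fixture is corrupt: unexpected columns")
  if (nrow(tab) != 43L)
    stop("family table fixture is corrupt: expected 43 records, got ", nrow(tab))
  stopifnot(all(tab$aa_length >= 1), all(tab$pi > 0 & tab$pi < 14),
            all(tab$start <= tab$end), all(tab$strand %in% c("+", "-")))
  tab
}
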
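#' Parse a Newick tree with branch supports
#'
#' Wraps [ape::read.tree] and interprets numeric internal-node labels as
#' branch supports. Both common dialects are accepted: supports given as
#' percentages (values > 1) are kept as-is, and proportions (values in
#' \[0, 1\]) are rescaled to 0-100.
#'
#' @param text Newick string, or `NULL` when `file` is given.
#' @param file Optional path to a Newick file.
#' @return An [ape::read.tree] `"phylo"` object with an extra numeric element
#'   `support` (length `Nnode`, `NA` where a node carries no numeric label),
#'   on the 0-100 scale.
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  tr <- tryCatch(
    if (is.null(file)) ape::read.tree(text = text) else ape::read.tree(file),
    error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error: unbalanced or empty input")
  if (anyDuplicated(tr$tip.label)) stop("leaf labels are not unique")
  supp <- rep(NA_real_, tr$Nnode)
  if (!is.null(tr$node.label)) {
    num <- suppressWarnings(as.numeric(tr$node.label))
    supp <- ifelse(!is.na(num) & num >= 0 & num <= 1 & num != 0, num * 100, num)
    # exact 0 is a genuine 0% support in either dialect
    supp[!is.na(num) & num == 0] <- 0
  }
  if (any(supp > 100, na.rm = TRUE))
    stop("branch supports above 100 are not a recognized dialect")
  tr$support <- supp
  tr
}
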
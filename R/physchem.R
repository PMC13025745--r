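# Average residue masses (Da); peptide mass = sum(residues) + one water.
AA_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
             C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
             H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
             M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
             T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.0153

# Kyte-Doolittle hydropathy index.
KD_INDEX <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

# Ionizable-group pKa sets. Positive groups: N-terminus, H, K, R;
# negative: C-terminus, D, E, C, Y.
PKA_SETS <- list(
  emboss = c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
             H = 6.5, K = 10.8, R = 12.5, Y = 10.1),
  lehninger = c(Nterm = 9.69, Cterm = 2.34, C = 8.33, D = 3.65, E = 4.25,
                H = 6.0, K = 10.53, R = 12.48, Y = 10.07))

split_residues <- function(seq, strict = TRUE, allowed = names(AA_MASS)) {
  if (!nzchar(seq)) stop("empty protein sequence")
  res <- strsplit(toupper(seq), "")[[1]]
  unknown <- !res %in% allowed
  if (any(unknown)) {
    if (strict) stop("unknown residue(s): ",
                     paste(unique(res[unknown]), collapse = ", "))
    warning("skipping ", sum(unknown), " unknown residue(s)")
    res <- res[!unknown]
    if (!length(res)) stop("no standard residues left in sequence")
  }
  res
}

#' Protein molecular weight
#'
#' Sum of average residue masses plus one water, reported in kDa.
#'
#' @param seq Protein sequence (single string, 20 standard residues).
#' @param strict Error on unknown residues (default); otherwise skip them
#'   with a warning.
#' @return Molecular weight in kDa.
#' @export
molecular_weight <- function(seq, strict = TRUE) {
  res <- split_residues(seq, strict)
  unname(sum(AA_MASS[res]) + WATER_MASS) / 1000
}

#' Net protein charge at a given pH
#'
#' Henderson-Hasselbalch sum over the N-/C-termini and the ionizable side
#' chains (D, E, C, Y negative; H, K, R positive).
#'
#' @param seq Protein sequence.
#' @param pH pH value (may be a vector).
#' @param pka Named pKa set or the name of a packaged set
#'   (`"emboss"`, `"lehninger"`).
#' @return Net charge (same length as `pH`).
#' @export
net_charge <- function(seq, pH, pka = "emboss") {
  if (is.character(pka)) pka <- PKA_SETS[[match.arg(pka, names(PKA_SETS))]]
  res <- split_residues(seq)
  n <- table(factor(res, levels = names(AA_MASS)))
  pos_counts <- c(Nterm = 1, H = unname(n["H"]), K = unname(n["K"]),
                  R = unname(n["R"]))
  neg_counts <- c(Cterm = 1, D = unname(n["D"]), E = unname(n["E"]),
                  C = unname(n["C"]), Y = unname(n["Y"]))
  vapply(pH, function(p) {
    pos <- sum(pos_counts / (1 + 10^(p - pka[names(pos_counts)])))
    neg <- sum(neg_counts / (1 + 10^(pka[names(neg_counts)] - p)))
    pos - neg
  }, 0)
}

#' Protein isoelectric point
#'
#' pH at which the net charge crosses zero, found by bisection on
#' \[0, 14\] to `|charge| < tol`.
#'
#' @inheritParams net_charge
#' @param tol Convergence tolerance on the net charge.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(seq, pka = "emboss", tol = 1e-6) {
  lo <- 0; hi <- 14
  # net_charge is strictly decreasing in pH
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    q <- net_charge(seq, mid, pka)
    if (abs(q) < tol) break
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Grand average of hydropathicity (GRAVY)
#'
#' Mean Kyte-Doolittle index over the residues. Proteins with GRAVY > 0 are
#' classed hydrophobic, otherwise hydrophilic (a GRAVY of exactly 0 counts
#' as hydrophilic).
#'
#' @inheritParams molecular_weight
#' @return GRAVY value in \[-4.5, 4.5\].
#' @export
gravy <- function(seq, strict = TRUE) {
  res <- split_residues(seq, strict)
  unname(mean(KD_INDEX[res]))
}

#' @rdname gravy
#' @param g A GRAVY value.
#' @export
hydro_class <- function(g) ifelse(g > 0, "hydrophobic", "hydrophilic")

#' Physicochemical profile of protein sequences
#'
#' @param seqs Named character vector of protein sequences.
#' @param pka pKa set for the isoelectric point, see [net_charge].
#' @return data.frame with `id`, `aa_length`, `mw` (kDa), `pi`, `gravy`,
#'   `hydro_class`.
#' @export
physchem_profile <- function(seqs, pka = "emboss") {
  stopifnot(length(seqs) > 0)
  g <- vapply(seqs, gravy, 0)
  data.frame(id = names(seqs) %||% as.character(seq_along(seqs)),
             aa_length = nchar(seqs),
             mw = vapply(seqs, molecular_weight, 0),
             pi = vapply(seqs, isoelectric_point, 0, pka = pka),
             gravy = g, hydro_class = hydro_class(g),
             row.names = NULL)
}

#' Family-level physicochemical summary
#'
#' Reproduces the headline counts reported for the wheat WSD family: how many
#' members are basic (pI > 7), hydrophobic (GRAVY > 0) or transmembrane, and
#' the ranges of protein length, molecular weight, pI and gene length.
#'
#' @param records data.frame in the layout of [load_table1] (columns
#'   `aa_length`, `mw`, `pi`, `hydropathicity`, `membrane_type`, `start`,
#'   `end`).
#' @param length_threshold Gene-length cutoff in bp for the "short genes"
#'   count (strict `<`).
#' @return Named list of summary statistics.
#' @export
summarize_properties <- function(records, length_threshold = 10000) {
  if (!nrow(records)) stop("no records to summarize")
  n <- nrow(records)
  glen <- records$end - records$start + 1
  list(
    n = n,
    pi_gt7_count = sum(records$pi > 7),
    pi_gt7_pct = round(100 * sum(records$pi > 7) / n, 2),
    hydrophobic_count = sum(records$hydropathicity > 0),
    transmembrane_count = sum(records$membrane_type == "Transmembrane"),
    aa_length_range = range(records$aa_length),
    mw_range = range(records$mw),
    pi_range = range(records$pi),
    gene_length_range_kb = round(range(glen) / 1000, 2),
    genes_below_threshold = sum(glen < length_threshold))
}
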
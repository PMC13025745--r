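#' Configuration for the synthetic expression atlas
#'
#' Defaults emulate, at desk scale, a multi-tissue crop transcriptome:
#' 6 tissues x 10 samples (60 samples standing in for the hundreds of
#' public samples such an atlas draws on), tissue-specific lognormal
#' FPKM with mild library-size variation, planted peak-tissue genes and
#' planted TF-target pairs at a stated Pearson correlation.
#'
#' @param tissues Tissue labels; the lamina joint (`"LJ"`) is included by
#'   default as the focal tissue.
#' @param samples_per_tissue Samples per tissue.
#' @param family_ids Ids of the focal family genes.
#' @param peak_tissue Named vector family gene -> tissue; unnamed genes
#'   get a random peak tissue.
#' @param tf_plan data.frame `tf`, `target`, `pcc`: planted regulator
#'   pairs; each TF tracks its target's profile at the stated sample PCC.
#' @param n_background Unrelated background genes.
#' @param n_null_tfs TFs with no planted target (negative controls).
#' @param peak_fpkm,base_fpkm Mean FPKM in the peak and non-peak tissues.
#' @param dispersion Lognormal sigma of biological noise (0 = none).
#' @param libsize_sd Lognormal sigma of per-sample library-size factors.
#' @param seed RNG seed.
#' @return An `expression_sim_config` list.
#' @export
expression_sim_config <- function(tissues = c("Root", "Leaf", "Stem",
                                              "Spike", "LJ", "Grain"),
                                  samples_per_tissue = 10,
                                  family_ids = sprintf("FAM%02d", 1:12),
                                  peak_tissue = NULL,
                                  tf_plan = data.frame(
                                    tf = c("TF01", "TF02", "TF03"),
                                    target = sprintf("FAM%02d", 1:3),
                                    pcc = c(0.95, 0.95, 0.95)),
                                  n_background = 30, n_null_tfs = 5,
                                  peak_fpkm = 50, base_fpkm = 2,
                                  dispersion = 0.2, libsize_sd = 0.1,
                                  seed = 1) {
  if (samples_per_tissue < 1) stop("need >= 1 sample per tissue")
  if (nrow(tf_plan) && (any(tf_plan$pcc < -1) || any(tf_plan$pcc > 1)))
    stop("planted PCC must lie in [-1, 1]")
  if (!all(tf_plan$target %in% family_ids))
    stop("tf_plan targets must be family genes")
  structure(list(tissues = tissues,
                 samples_per_tissue = samples_per_tissue,
                 family_ids = family_ids, peak_tissue = peak_tissue,
                 tf_plan = tf_plan, n_background = n_background,
                 n_null_tfs = n_null_tfs, peak_fpkm = peak_fpkm,
                 base_fpkm = base_fpkm, dispersion = dispersion,
                 libsize_sd = libsize_sd, seed = seed),
            class = "expression_sim_config")
}

#' Generate a tissue-structured FPKM matrix with planted truth
#'
#' Family and background genes get tissue-specific lognormal expression;
#' each planted TF's profile is an affine copy of its target's realized
#' profile plus Gaussian noise sized (from the realized target variance)
#' so the empirical sample PCC lands near the planted value; at zero
#' planted-noise (`pcc = 1`) the correlation is exactly 1.
#'
#' @param config An [expression_sim_config].
#' @return List: `fpkm` (genes x samples matrix), `metadata` (`sample`,
#'   `tissue`), `truth` (list: `peak_tissue` named vector, `tf_pairs`
#'   data.frame, `tissue_of_sample`), `config`.
#' @export
generate_expression <- function(config = expression_sim_config()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  cfg <- config
  tissues <- cfg$tissues
  n_t <- length(tissues)
  samples <- unlist(lapply(tissues, function(t)
    sprintf("%s_S%02d", t, seq_len(cfg$samples_per_tissue))))
  tissue_of <- rep(tissues, each = cfg$samples_per_tissue)
  names(tissue_of) <- samples
  n_s <- length(samples)

  peak <- cfg$peak_tissue
  if (is.null(peak))
    peak <- stats::setNames(sample(tissues, length(cfg$family_ids),
                                   replace = TRUE), cfg$family_ids)
  missing <- setdiff(cfg$family_ids, names(peak))
  if (length(missing))
    peak[missing] <- sample(tissues, length(missing), replace = TRUE)

  lib <- if (cfg$libsize_sd > 0)
    exp(stats::rnorm(n_s, 0, cfg$libsize_sd)) else rep(1, n_s)

  tissue_profile <- function(peak_t) {
    mu <- stats::setNames(rep(cfg$base_fpkm, n_t), tissues)
    mu[peak_t] <- cfg$peak_fpkm
    mu
  }
  draw_gene <- function(mu_by_tissue) {
    mu <- mu_by_tissue[tissue_of]
    noise <- if (cfg$dispersion > 0)
      exp(stats::rnorm(n_s, -cfg$dispersion^2 / 2, cfg$dispersion))
    else rep(1, n_s)
    mu * noise * lib
  }

  gene_ids <- c(cfg$family_ids,
                unique(cfg$tf_plan$tf),
                if (cfg$n_null_tfs > 0)
                  sprintf("NULLTF%02d", seq_len(cfg$n_null_tfs)),
                if (cfg$n_background > 0)
                  sprintf("BG%03d", seq_len(cfg$n_background)))
  fpkm <- matrix(0, nrow = length(gene_ids), ncol = n_s,
                 dimnames = list(gene_ids, samples))
  for (g in cfg$family_ids) fpkm[g, ] <- draw_gene(tissue_profile(peak[g]))
  for (g in grep("^NULLTF", gene_ids, value = TRUE))
    fpkm[g, ] <- draw_gene(tissue_profile(sample(tissues, 1)))
  for (g in grep("^BG", gene_ids, value = TRUE))
    fpkm[g, ] <- draw_gene(tissue_profile(sample(tissues, 1)))

  # planted TFs: affine tracker of the realized target plus noise
  # calibrated per tissue, so the correlation holds both globally and
  # within each tissue (exact at pcc = 1)
  for (i in seq_len(nrow(cfg$tf_plan))) {
    tf <- cfg$tf_plan$tf[i]; tg <- cfg$tf_plan$target[i]
    rho <- cfg$tf_plan$pcc[i]
    y <- fpkm[tg, ]
    sig <- 0.8 * (if (rho >= 0) y else -y)
    if (abs(rho) >= 1 - 1e-12) {
      x <- sig
    } else {
      fac <- sqrt(1 / rho^2 - 1)
      e <- numeric(n_s)
      for (t in tissues) {
        ss <- tissue_of == t
        sd_w <- stats::sd(sig[ss])
        if (!is.finite(sd_w) || sd_w < 1e-9) sd_w <- stats::sd(sig)
        e[ss] <- stats::rnorm(sum(ss), 0, sd_w * fac)
      }
      x <- sig + e
    }
    fpkm[tf, ] <- x - min(x, 0) + 0.5   # shift into nonnegative FPKM range
  }

  list(fpkm = fpkm,
       metadata = data.frame(sample = samples, tissue = tissue_of,
                             row.names = NULL),
       truth = list(peak_tissue = peak, tf_pairs = cfg$tf_plan,
                    tissue_of_sample = tissue_of),
       config = cfg)
}
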
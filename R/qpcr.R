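#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged within each biological replicate;
#' `dCt = Ct_target - Ct_reference` per biological replicate;
#' `ddCt = mean dCt(group) - mean dCt(calibrator)`; fold change is
#' `2^-ddCt`. Shifting the reference Ct uniformly leaves folds unchanged.
#'
#' @param qpcr data.frame with columns `group`, `bio_rep`, `ct_target`,
#'   `ct_reference` (one row per technical replicate).
#' @param calibrator Group used as the fold-change baseline.
#' @return List: `fold` (named per-group fold change), `dct_reps`
#'   (data.frame of per-biological-replicate dCt values, for statistics),
#'   `rep_fold` (per-replicate 2^-ddCt values).
#' @export
ddct <- function(qpcr, calibrator) {
  stopifnot(all(c("group", "bio_rep", "ct_target", "ct_reference") %in%
                  names(qpcr)))
  if (!calibrator %in% qpcr$group) stop("calibrator group not in table")
  if (any(qpcr$ct_target <= 0 | qpcr$ct_reference <= 0))
    stop("Ct values must be positive")
  key <- paste(qpcr$group, qpcr$bio_rep, sep = "\r")
  dct <- tapply(qpcr$ct_target - qpcr$ct_reference, key, mean)
  grp <- vapply(strsplit(names(dct), "\r", fixed = TRUE), `[`, "", 1)
  reps <- data.frame(group = grp, dct = as.numeric(dct), row.names = NULL)
  base <- mean(reps$dct[reps$group == calibrator])
  gm <- c(tapply(reps$dct, reps$group, mean))
  fold <- 2^-(gm - base)
  reps$fold <- 2^-(reps$dct - base)
  list(fold = fold[order(names(fold))], dct_reps = reps,
       rep_fold = stats::setNames(reps$fold, paste(reps$group)))
}

# Piepho-style insert-and-absorb compact letter display from a logical
# "significantly different" matrix (groups x groups)
letter_display <- function(sig) {
  groups <- rownames(sig)
  cols <- list(groups)
  pairs <- which(sig & upper.tri(sig), arr.ind = TRUE)
  for (p in seq_len(nrow(pairs))) {
    a <- groups[pairs[p, 1]]; b <- groups[pairs[p, 2]]
    for (ci in seq_along(cols)) {
      if (all(c(a, b) %in% cols[[ci]])) {
        cols[[length(cols) + 1]] <- setdiff(cols[[ci]], a)
        cols[[ci]] <- setdiff(cols[[ci]], b)
      }
    }
    # absorb duplicated / contained columns
    keep <- rep(TRUE, length(cols))
    for (i in seq_along(cols)) for (j in seq_along(cols)) {
      if (i != j && keep[i] && keep[j] &&
          all(cols[[i]] %in% cols[[j]])) keep[i] <- FALSE
    }
    cols <- cols[keep]
  }
  cols <- cols[order(vapply(cols, function(cc) min(match(cc, groups)), 0))]
  out <- stats::setNames(rep("", length(groups)), groups)
  for (ci in seq_along(cols))
    out[cols[[ci]]] <- paste0(out[cols[[ci]]], letters[ci])
  out
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Groups sharing a letter are not significantly different at level
#' `alpha` under Tukey's studentized-range pairwise test.
#'
#' @param values Numeric response vector.
#' @param groups Group label per value (>= 2 groups, >= 2 replicates each).
#' @param alpha Family-wise significance level.
#' @return List: `anova_p`, `pairwise` (data.frame `pair`, `diff`,
#'   `p_adj`), `letters` (named per-group letter string).
#' @export
tukey_letters <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("need at least two replicates per group")
  fit <- stats::aov(values ~ groups)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
  lv <- levels(groups)
  sig <- matrix(FALSE, nlevels(groups), nlevels(groups),
                dimnames = list(lv, lv))
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(pairs)) {
    a <- pairs[[i]][1]; b <- pairs[[i]][2]
    sig[a, b] <- sig[b, a] <- tk[i, "p adj"] < alpha
  }
  list(anova_p = anova_p,
       pairwise = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                             p_adj = tk[, "p adj"], row.names = NULL),
       letters = letter_display(sig))
}
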
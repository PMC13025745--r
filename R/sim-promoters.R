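random_dna <- function(n, composition = c(A = 0.25, C = 0.25,
                                          G = 0.25, T = 0.25)) {
  paste(sample(names(composition), n, replace = TRUE,
               prob = composition), collapse = "")
}

pwm_consensus <- function(pwm) {
  paste(pwm$alphabet[apply(pwm$prob, 1, which.max)], collapse = "")
}

#' Generate promoter sequences with planted binding sites
#'
#' Each target gets a promoter of i.i.d. background of the stated base
#' composition, with its transcription start site at the 3' end. Motif
#' consensus instances are planted at the stated distances upstream of
#' the TSS (the distance convention matches [scan_sequence] with
#' `tss_at_end = TRUE`: a site planted at distance `d` is reported with
#' `distance_to_tss = d`), on the stated strand.
#'
#' @param targets Character vector of target gene ids.
#' @param motifs Named list of DNA [build_pwm] objects.
#' @param plan data.frame `target`, `motif`, `distance` (bp upstream of
#'   the TSS), `strand` (`"+"`/`"-"`); targets absent from the plan get
#'   background-only promoters.
#' @param promoter_length Promoter length in bp (default 2000, the usual
#'   upstream window taken for plant cis-element analysis).
#' @param composition Background base probabilities.
#' @param seed RNG seed.
#' @return List: `promoters` (named sequences), `truth` (the plan with a
#'   `start` column of planted 1-based forward-strand positions),
#'   `promoter_length`.
#' @export
generate_promoters <- function(targets, motifs, plan =
                                 data.frame(target = character(0),
                                            motif = character(0),
                                            distance = numeric(0),
                                            strand = character(0)),
                               promoter_length = 2000,
                               composition = c(A = 0.25, C = 0.25,
                                               G = 0.25, T = 0.25),
                               seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  proms <- stats::setNames(
    vapply(targets, function(t) random_dna(promoter_length, composition), ""),
    targets)
  plan$start <- NA_integer_
  for (i in seq_len(nrow(plan))) {
    m <- motifs[[plan$motif[i]]]
    if (is.null(m)) stop("unknown motif: ", plan$motif[i])
    w <- m$width
    d <- plan$distance[i]
    start <- promoter_length - d - w + 2   # so distance_to_tss == d
    if (start < 1 || start + w - 1 > promoter_length)
      stop("planted position outside promoter for ", plan$target[i])
    inst <- pwm_consensus(m)
    if (plan$strand[i] == "-") inst <- revcomp(inst)
    s <- proms[[plan$target[i]]]
    substr(s, start, start + w - 1) <- inst
    proms[[plan$target[i]]] <- s
    plan$start[i] <- start
  }
  list(promoters = proms, truth = plan, promoter_length = promoter_length)
}
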
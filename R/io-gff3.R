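#' Gene model
#'
#' A minimal representation of one annotated gene: 1-based inclusive
#' coordinates (GFF3 dialect), strand, and the exon/UTR intervals of a single
#' representative transcript.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome / contig name.
#' @param start,end 1-based inclusive gene span (bp).
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix of exon `(start, end)` intervals, bp.
#' @param utr5,utr3 Two-column matrices of UTR intervals (may have 0 rows).
#' @param n_transcripts Number of annotated transcripts for the gene.
#'
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, start, end, strand,
                       exons = cbind(start, end),
                       utr5 = matrix(numeric(0), ncol = 2),
                       utr3 = matrix(numeric(0), ncol = 2),
                       n_transcripts = 1L) {
  exons <- matrix(as.numeric(exons), ncol = 2)
  utr5 <- matrix(as.numeric(utr5), ncol = 2)
  utr3 <- matrix(as.numeric(utr3), ncol = 2)
  if (start > end) stop("gene ", gene_id, ": start > end")
  if (!strand %in% c("+", "-")) stop("gene ", gene_id, ": bad strand ", strand)
  if (nrow(exons) == 0) stop("gene ", gene_id, ": no exons")
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (any(exons[, 1] > exons[, 2])) stop("gene ", gene_id, ": exon start > end")
  if (nrow(exons) > 1 && any(exons[-1, 1] <= exons[-nrow(exons), 2]))
    stop("gene ", gene_id, ": overlapping exons")
  for (iv in list(exons, utr5, utr3)) {
    if (nrow(iv) && (any(iv[, 1] < start) || any(iv[, 2] > end)))
      stop("gene ", gene_id, ": interval outside gene span")
  }
  structure(list(gene_id = gene_id, chrom = chrom,
                 start = as.numeric(start), end = as.numeric(end),
                 strand = strand, exons = exons, utr5 = utr5, utr3 = utr3,
                 n_transcripts = as.integer(n_transcripts)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d(%s), %d exon(s)\n",
              x$gene_id, x$chrom, x$start, x$end, x$strand, nrow(x$exons)))
  invisible(x)
}

#' Gene length in bp (1-based inclusive)
#'
#' @param g A `gene_model`, or anything with `start`/`end` fields
#'   (e.g. one row of the packaged family table coerced to a list).
#' @return Length in bp, `end - start + 1`.
#' @export
gene_length <- function(g) {
  as.numeric(g$end) - as.numeric(g$start) + 1
}

parse_gff3_attrs <- function(attr, lineno) {
  if (is.na(attr) || attr == "" || !grepl("=", attr, fixed = TRUE))
    stop("GFF3 line ", lineno, ": malformed attribute column: ", attr)
  parts <- strsplit(attr, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  kv <- strsplit(parts, "=", fixed = TRUE)
  if (any(lengths(kv) != 2))
    stop("GFF3 line ", lineno, ": malformed attribute column: ", attr)
  stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
}

#' Parse a GFF3 annotation into gene models
#'
#' Reads gene / mRNA / exon / CDS / UTR features linked by `ID`/`Parent`
#' attributes and returns one [gene_model] per gene. For multi-transcript
#' genes a single representative transcript is kept.
#'
#' @param path Path to a GFF3 file (may be gzipped).
#' @param representative How to pick the representative transcript of a
#'   multi-transcript gene: `"longest_cds"` (default, total CDS bp) or
#'   `"first"` (first mRNA encountered).
#' @return Named list of `gene_model` objects (names = gene ids), ordered by
#'   chromosome then start coordinate.
#' @export
parse_gff3 <- function(path, representative = c("longest_cds", "first")) {
  representative <- match.arg(representative)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  if (!length(lineno)) stop("no features in GFF3 file: ", path)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (any(lengths(fields) != 9))
    stop("GFF3 line ", lineno[which(lengths(fields) != 9)[1]],
         ": expected 9 tab-separated columns")
  tab <- data.frame(
    chrom = vapply(fields, `[`, "", 1),
    type = vapply(fields, `[`, "", 3),
    start = as.numeric(vapply(fields, `[`, "", 4)),
    end = as.numeric(vapply(fields, `[`, "", 5)),
    strand = vapply(fields, `[`, "", 7),
    attr = vapply(fields, `[`, "", 9),
    lineno = lineno)
  bad <- which(tab$start > tab$end)
  if (length(bad))
    stop("GFF3 line ", tab$lineno[bad[1]], ": end < start")

  attrs <- mapply(parse_gff3_attrs, tab$attr, tab$lineno, SIMPLIFY = FALSE)
  get_attr <- function(a, key) if (key %in% names(a)) a[[key]] else NA_character_
  tab$id <- vapply(attrs, get_attr, "", "ID")
  tab$parent <- vapply(attrs, get_attr, "", "Parent")

  genes <- tab[tab$type == "gene", ]
  mrnas <- tab[tab$type %in% c("mRNA", "transcript"), ]
  parts <- tab[tab$type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR"), ]
  if (anyNA(genes$id)) stop("gene feature without ID attribute")
  if (anyNA(mrnas$parent) || !all(mrnas$parent %in% genes$id))
    stop("mRNA without a parent gene")
  if (anyNA(parts$parent) || !all(parts$parent %in% mrnas$id))
    stop("exon/CDS/UTR feature without a parent mRNA")

  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    tx <- mrnas[mrnas$parent == g$id, ]
    if (!nrow(tx)) stop("gene ", g$id, ": no transcripts")
    cds_len <- vapply(tx$id, function(t) {
      p <- parts[parts$parent == t & parts$type == "CDS", ]
      sum(p$end - p$start + 1)
    }, 0)
    rep_id <- if (representative == "longest_cds") tx$id[which.max(cds_len)] else tx$id[1]
    pick <- function(what) {
      p <- parts[parts$parent == rep_id & parts$type == what, ]
      p <- p[order(p$start), ]
      cbind(p$start, p$end)
    }
    gene_model(g$id, g$chrom, g$start, g$end, g$strand,
               exons = pick("exon"), utr5 = pick("five_prime_UTR"),
               utr3 = pick("three_prime_UTR"), n_transcripts = nrow(tx))
  })
  names(out) <- genes$id
  out[order(vapply(out, `[[`, "", "chrom"), vapply(out, `[[`, 0, "start"))]
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA (one representative transcript per gene), exon and UTR
#' features; inverse of [parse_gff3] for generator output.
#'
#' @param models List of [gene_model] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in models) {
    line <- function(type, s, e, attr)
      sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, "wsdfam", type, as.integer(s), as.integer(e), g$strand, attr)
    tid <- paste0(g$gene_id, ".1")
    writeLines(line("gene", g$start, g$end, paste0("ID=", g$gene_id)), con)
    writeLines(line("mRNA", g$start, g$end,
                    paste0("ID=", tid, ";Parent=", g$gene_id)), con)
    emit <- function(iv, type) {
      for (k in seq_len(nrow(iv)))
        writeLines(line(type, iv[k, 1], iv[k, 2], paste0("Parent=", tid)), con)
    }
    emit(g$exons, "exon")
    cds <- coding_intervals(g)
    emit(cds, "CDS")
    emit(g$utr5, "five_prime_UTR")
    emit(g$utr3, "three_prime_UTR")
  }
  invisible(path)
}

# exon intervals minus UTR intervals = CDS (intervals are exact in our models)
coding_intervals <- function(g) {
  utr <- rbind(g$utr5, g$utr3)
  cds <- g$exons
  for (k in seq_len(nrow(utr))) {
    keep <- matrix(numeric(0), ncol = 2)
    for (j in seq_len(nrow(cds))) {
      a <- cds[j, 1]; b <- cds[j, 2]; u1 <- utr[k, 1]; u2 <- utr[k, 2]
      if (u2 < a || u1 > b) { keep <- rbind(keep, c(a, b)); next }
      if (u1 > a) keep <- rbind(keep, c(a, u1 - 1))
      if (u2 < b) keep <- rbind(keep, c(u2 + 1, b))
    }
    cds <- keep
  }
  cds
}

`%||%` <- function(a, b) if (is.null(a)) b else a
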
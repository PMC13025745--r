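#!/usr/bin/env Rscript
# Within-genome collinearity and duplication-mode classification of the
# simulated family, plus inter-genome synteny and putative orthologs
# between the A genome and its B/D relatives.

library(wsdfam)
dir.create("results", showWarnings = FALSE)

dom <- make_domain_profiles()
genA <- generate_family_genome(
  genome_sim_config(n_chromosomes = 3, genes_per_chromosome = 67,
                    genome_letter = "A", seed = 1), dom)
genB <- generate_ortholog_genome(genA, "B", mutation_rate = 0.02, seed = 2)

## within-genome: blocks and duplication modes ---------------------------
anc <- find_anchors(genA$proteome, genA$proteome, genA$orders, genA$orders,
                    self = TRUE)
blocks <- chain_collinear(anc)
fam <- genA$truth[genA$truth$is_family, ]
cls <- classify_duplicates(fam$gene_id, anc, blocks)
cls$truth_mode <- fam$mode[match(cls$gene_id, fam$gene_id)]
write.table(cls, "results/duplication_modes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("within-genome: ", nrow(anc), " anchors, ", length(blocks),
        " collinear block(s); modes called: ",
        paste(names(table(cls$mode)), table(cls$mode), sep = "=",
              collapse = ", "),
        "; agreement with truth ", mean(cls$mode == cls$truth_mode))

## inter-genome: collinear pairs and orthologs --------------------------
ancAB <- find_anchors(genA$proteome, genB$proteome, genA$orders,
                      genB$orders)
blocksAB <- chain_collinear(ancAB)
op <- ortholog_pairs(blocksAB)
write.table(op, "results/collinear_pairs_AB.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
truth <- genB$ortholog_truth
hit <- merge(op[op$putative_ortholog, ], truth,
             by = c("gene_a", "gene_b"))
message("A-B synteny: ", length(blocksAB), " blocks, ", nrow(op),
        " collinear pairs, ", sum(op$putative_ortholog),
        " flagged putative orthologs; truth recovered ",
        nrow(hit), "/", nrow(truth))
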
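#!/usr/bin/env Rscript
# Simulate three related annotated genomes (subgenomes A, B, D) carrying a
# planted two-domain acyltransferase family with a known duplication plan
# (6 segmental, 4 tandem, 1 proximal, 2 dispersed members) plus decoys,
# and write the sequences, annotation and truth tables used by the rest
# of the workflow.

library(wsdfam)

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

dom <- make_domain_profiles()
cfg <- genome_sim_config(n_chromosomes = 3, genes_per_chromosome = 67,
                         genome_letter = "A", seed = 1)
genA <- generate_family_genome(cfg, dom)
genB <- generate_ortholog_genome(genA, "B", mutation_rate = 0.02, seed = 2)
genD <- generate_ortholog_genome(genA, "D", mutation_rate = 0.02, seed = 3)

write_fasta <- function(seqs, path) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
}

for (g in list(A = genA, B = genB, D = genD)) {
  letter <- substr(g$truth$gene_id[1], 4, 4)
  write_fasta(g$proteome, file.path(out, paste0("proteome_", letter, ".faa")))
  write_gff3(g$models, file.path(out, paste0("genome_", letter, ".gff3")))
  write.table(g$truth, file.path(out, paste0("truth_", letter, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
write_fasta(genA$seeds, file.path(out, "seed_proteins.faa"))
write.table(genB$ortholog_truth, file.path(out, "ortholog_truth_AB.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(genD$ortholog_truth, file.path(out, "ortholog_truth_AD.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

fam <- sum(genA$truth$is_family)
message("simulated 3 genomes of ", length(genA$proteome), " genes; ",
        fam, " planted family members per genome (modes: ",
        paste(names(table(genA$truth$mode)), table(genA$truth$mode),
              sep = "=", collapse = ", "), ")")
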
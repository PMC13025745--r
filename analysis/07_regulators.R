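#!/usr/bin/env Rscript
# Regulator inference: dual-dimension co-expression filtering (global and
# intra-peak-tissue PCC >= 0.9), candidate TF clustering, TF-to-motif
# mapping by protein similarity, and promoter TFBS cross-validation with
# TSS-distance reporting.

library(wsdfam)
dir.create("results", showWarnings = FALSE)

plan <- data.frame(tf = sprintf("TF%02d", 1:3),
                   target = sprintf("FAM%02d", 1:3), pcc = 0.97)
ex <- generate_expression(expression_sim_config(tf_plan = plan, seed = 7))
gr <- group_samples(ex$fpkm, ex$metadata)
at <- build_atlas(ex$fpkm, gr)

tfs <- c(plan$tf, grep("^NULLTF", rownames(ex$fpkm), value = TRUE))
ev <- dual_filter(ex$fpkm[tfs, , drop = FALSE],
                  ex$fpkm[ex$config$family_ids, , drop = FALSE],
                  gr, at$peak_group, threshold = 0.9)
write.table(ev, "results/tf_candidates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(nrow(ev), " candidate pair(s) pass the dual PCC >= 0.9 filter (",
        length(unique(ev$tf)), " TF(s) of ", length(tfs), " tested)")

if (length(unique(ev$tf)) >= 2) {
  cl <- cluster_candidates(ex$fpkm[unique(ev$tf), , drop = FALSE])
  message("candidate TFs fall into ", cl$k, " expression cluster(s)")
}

## promoter cross-validation --------------------------------------------
motif <- build_pwm(rep("TTGACCGATTCGAT", 3), "DNA", pseudocount = 0.1,
                   name = "MOT1")
set.seed(8)
tf_prot <- stats::setNames(
  replicate(length(plan$tf),
            paste(sample(c("A","C","D","E","G","K","L","R","S","V"), 80,
                         replace = TRUE), collapse = "")), plan$tf)
prom <- generate_promoters(ex$config$family_ids, list(MOT1 = motif),
                           data.frame(target = plan$target, motif = "MOT1",
                                      distance = c(120, 300, 450),
                                      strand = c("+", "-", "+")),
                           seed = 9)
tf2m <- map_tf_to_motif(tf_prot, stats::setNames(tf_prot, rep("MOT1", 3)))
rp <- tfbs_crossvalidate(ev[ev$tf %in% plan$tf, ], prom$promoters,
                         list(MOT1 = motif), tf2m, p_threshold = 1e-6)
write.table(rp, "results/regulatory_pairs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
ok <- rp[rp$status == "TFBS-supported" & rp$within_window, ]
message(nrow(ok), " pair(s) TFBS-supported within 500 bp of the TSS (",
        "distances: ", paste(ok$best_distance_to_tss, collapse = ", "), ")")
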
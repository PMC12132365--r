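#!/usr/bin/env Rscript

# The two derived gene sets: (1) shared SASP genes - per senescent
# cluster, the top 50 of the SASP leading-edge list by ranking score,
# intersected across clusters; (2) the etoposide-induced senescence
# signature - top 100 of the pooled senescent-vs-rest DGE united with the
# top 50 of the weakly-identified cluster, minus genes elevated in
# untreated G0/G1 cells. Both are audited against the planted programs.

suppressPackageStartupMessages({
  library(senotyper)
  library(SingleCellExperiment)
})

out <- "results/06_gene_sets"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

st <- readRDS("scratch/clustered.rds")
dg <- readRDS("scratch/dge.rds")
m <- st$m
cfg <- synthetic_study_config()
truth <- read.csv("results/01_simulate/cell_truth.csv")
truth <- truth[match(colnames(m), truth$cell_id), ]
genes <- read.csv("results/01_simulate/gene_truth.csv")

shared <- shared_sasp_genes(dg$sasp_leading, dg$dge[dg$sen_clusters],
                            top_n = cfg$top_sasp)
uni <- genes$gene_id[genes$program == "sasp_universal"]
brg <- genes$gene_id[genes$program == "sasp_branch"]
cat(sprintf(
  "shared SASP set: %d genes; %.0f%% of planted universal genes, %d branch-specific leaks\n",
  length(shared$genes), 100 * mean(uni %in% shared$genes),
  sum(brg %in% shared$genes)))

clusters <- colData(m)$cluster
cells <- colnames(m)
sen_cells <- cells[clusters %in% as.integer(dg$sen_clusters)]
n_sig <- vapply(dg$sen_clusters, function(cl) {
  sum(dg$dge[[cl]]$p_adj_bonferroni < 0.05 & dg$dge[[cl]]$avg_log2FC > 0)
}, numeric(1))
weak <- dg$sen_clusters[which.min(n_sig)]
ut_g0g1 <- cells[colData(m)$dose == "UT" & colData(m)$phase == "G0/G1"]

signature <- derive_senescence_signature(
  dg$dge$combined, dg$dge[[weak]], m,
  senescent_cells = sen_cells, untreated_g0g1_cells = ut_g0g1,
  top_combined = cfg$top_combined, top_weak = cfg$top_weak,
  background_ratio = cfg$background_ratio)
pan <- genes$gene_id[genes$program == "pan_senescence"]
qui <- genes$gene_id[genes$program == "quiescence_only"]
cat(sprintf(
  "senescence signature: %d genes (weak cluster %s, %d background removals);\n",
  length(signature$genes), weak, length(signature$trace$removed)))
cat(sprintf(
  "  recovers %.0f%% of planted pan-senescence markers, %d quiescence-only leaks\n",
  100 * mean(pan %in% signature$genes),
  sum(qui %in% signature$genes)))

write_gmt(list(shared_sasp = shared$genes,
               etoposide_senescence = signature$genes),
          file.path(out, "derived_gene_sets.gmt"))
jsonlite::write_json(list(shared_sasp = shared$trace,
                          signature = signature$trace),
                     file.path(out, "derivation_traces.json"),
                     auto_unbox = TRUE, digits = NA)

# per-cell and per-cluster signature scores; dose-robustness check:
# the score should track arrest depth within every dose separately
sc <- score_gene_set(m, intersect(signature$genes, rownames(m)),
                     clusters = clusters, n_bins = cfg$score_bins,
                     n_ctrl = cfg$score_ctrl, seed = cfg$seeds$score)
write.csv(data.frame(cell_id = cells, score = unname(sc$score)),
          file.path(out, "signature_scores.csv"), row.names = FALSE)
write.csv(sc$by_cluster, file.path(out, "signature_scores_by_cluster.csv"),
          row.names = FALSE)
arrested <- truth$branch != "cycling"
for (d in unique(truth$dose)) {
  i <- arrested & truth$dose == d
  if (sum(i) > 10) {
    cat(sprintf("  score vs depth within %s: Spearman %.2f (n=%d)\n", d,
                cor(sc$score[i], truth$depth[i], method = "spearman"),
                sum(i)))
  }
}
cat("outputs under", out, "\n")
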
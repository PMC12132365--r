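#!/usr/bin/env Rscript

# Wilcoxon differential expression for every senescent-like cluster
# against all other cells (plus the pooled comparison), the ranking score
# avg_log2FC x -log10(adjusted p), and native preranked GSEA over the
# gene-set collection, with leading-edge extraction for the SASP-related
# sets.

suppressPackageStartupMessages({
  library(senotyper)
  library(SingleCellExperiment)
})

out <- "results/04_dge_enrichment"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

st <- readRDS("scratch/clustered.rds")
m <- st$m
labels <- st$labels
cfg <- synthetic_study_config()
sets <- read_gmt("results/01_simulate/gene_sets.gmt")
sasp_sets <- grep("^SASP", names(sets), value = TRUE)

clusters <- colData(m)$cluster
cells <- colnames(m)
sen_clusters <- names(labels)[labels == "senescent-like"]

dge <- list()
gsea <- list()
sasp_leading <- character(0)
for (cl in sen_clusters) {
  in_cl <- cells[clusters == as.integer(cl)]
  dge[[cl]] <- ranking_scores(
    wilcoxon_dge(m, in_cl, setdiff(cells, in_cl),
                 min_pct = cfg$dge_min_pct,
                 min_logfc = cfg$dge_min_logfc),
    adjust = cfg$rank_adjust, eps = cfg$rank_eps)
  write.csv(dge[[cl]], file.path(out, paste0("dge_cluster_", cl, ".csv")),
            row.names = FALSE)
  scores <- setNames(dge[[cl]]$ranking_score, dge[[cl]]$gene_id)
  gsea[[cl]] <- gsea_preranked(scores, sets, weight = cfg$gsea_weight,
                               n_perm = cfg$gsea_nperm,
                               min_size = cfg$gsea_min_size,
                               max_size = cfg$gsea_max_size,
                               seed = cfg$seeds$gsea)
  write.csv(gsea[[cl]][, setdiff(names(gsea[[cl]]), "leading_edge")],
            file.path(out, paste0("gsea_cluster_", cl, ".csv")),
            row.names = FALSE)
  sig_up <- gsea[[cl]]$set[gsea[[cl]]$p_adj_bh < 0.05 &
                             gsea[[cl]]$es > 0]
  cat(sprintf("cluster %s: %d genes tested, enriched (up): %s\n", cl,
              nrow(dge[[cl]]),
              paste(sig_up, collapse = ", ")))
  present <- intersect(sasp_sets, gsea[[cl]]$set)
  sasp_leading <- union(sasp_leading,
                        leading_edge_union(gsea[[cl]], present, scores))
}

sen_cells <- cells[clusters %in% as.integer(sen_clusters)]
dge$combined <- ranking_scores(
  wilcoxon_dge(m, sen_cells, setdiff(cells, sen_cells),
               min_pct = cfg$dge_min_pct,
               min_logfc = cfg$dge_min_logfc),
  adjust = cfg$rank_adjust, eps = cfg$rank_eps)
write.csv(dge$combined, file.path(out, "dge_combined.csv"),
          row.names = FALSE)

cat(sprintf("SASP leading-edge union across senescent clusters: %d genes\n",
            length(sasp_leading)))
writeLines(sasp_leading, file.path(out, "sasp_leading_edge.txt"))

saveRDS(list(dge = dge, gsea = gsea, sasp_leading = sasp_leading,
             sen_clusters = sen_clusters),
        "scratch/dge.rds")
cat("outputs under", out, "\n")
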
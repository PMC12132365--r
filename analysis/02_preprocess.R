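#!/usr/bin/env Rscript

# Quality control, log-normalization, HVG selection and PCA on the
# simulated study. The QC thresholds follow the study design (the
# detected-genes cutoff scaled to the 1,500-gene universe); planted
# low-quality cells (high mitochondrial load, collapsed libraries) should
# be the ones removed.

suppressPackageStartupMessages({
  library(senotyper)
  library(SingleCellExperiment)
})

out <- "results/02_preprocess"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sce <- read_10x("results/01_simulate/counts_10x")
truth <- read.csv("results/01_simulate/cell_truth.csv")
idx <- match(colnames(sce), truth$cell_id)
colData(sce)$dose <- truth$dose[idx]
colData(sce)$dna_content <- truth$dna_content[idx]  # Hoechst-like readout

cfg <- synthetic_study_config()
qc <- qc_filter(sce, cfg)
write.csv(qc$report, file.path(out, "qc_report.csv"), row.names = FALSE)
removed <- attr(qc$report, "removed")
cat(sprintf("QC: kept %d of %d cells (removed: %s)\n",
            ncol(qc$matrix), ncol(sce),
            paste(names(removed), unlist(removed), collapse = ", ")))

planted_bad <- truth$cell_id[truth$planted_high_mito |
                               truth$planted_low_lib]
dropped <- qc$report$cell_id[!qc$report$pass]
cat(sprintf("planted low-quality cells removed: %.0f%%\n",
            100 * mean(planted_bad %in% dropped)))

m <- log_normalize(qc$matrix, cfg$scale_factor)
err <- max(abs(Matrix::colSums(expm1(assay(m, "logcounts"))) -
                 cfg$scale_factor)) / cfg$scale_factor
cat(sprintf("normalization identity max relative error: %.2e\n", err))

hvg <- select_hvg(m, cfg$n_hvg)
write.csv(data.frame(gene_id = as.character(hvg)),
          file.path(out, "hvg.csv"), row.names = FALSE)
m <- scale_and_pca(m, hvg, n_pcs = cfg$n_pcs, clip = cfg$scale_clip)
pca <- reducedDim(m, "PCA")
cat(sprintf("PCA: %d components; PC1+PC2 explain %.1f%% of variance\n",
            ncol(pca), sum(attr(pca, "percentVar")[1:2])))
write.csv(data.frame(cell_id = rownames(pca), pca),
          file.path(out, "pca.csv"), row.names = FALSE)

saveRDS(m, "scratch/processed.rds")  # scratch hand-off between scripts
cat("outputs under", out, "\n")
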
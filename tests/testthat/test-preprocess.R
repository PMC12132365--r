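test_that("qc_filter applies the strict boundary rules", {
  # c1: 3499 genes detected -> removed ("fewer than 3,500"); c2: 3500
  # genes, 15.0% mito exactly -> retained (only "greater than 15%" is
  # removed); c3: 3500 genes but 16.7% mito -> removed
  n_genes <- 4000
  counts <- matrix(0L, n_genes, 3)
  rownames(counts) <- c("MT-1", sprintf("g%04d", seq_len(n_genes - 1)))
  colnames(counts) <- c("c1", "c2", "c3")
  counts[2:3500, "c1"] <- 1L                     # 3499 detected
  counts[2:3500, "c2"] <- 1L
  counts["MT-1", "c2"] <- 617L                   # 617/(3499+617) = 0.14990
  counts[2:3500, "c3"] <- 1L
  counts["MT-1", "c3"] <- 700L                   # 700/4199 = 0.1667
  sce <- make_sce(counts)
  res <- qc_filter(sce, pipeline_config())
  expect_identical(colnames(res$matrix), "c2")
  expect_equal(res$report$reason[res$report$cell_id == "c1"],
               "n_genes_detected")
  expect_equal(res$report$reason[res$report$cell_id == "c3"],
               "mito_fraction")
})

test_that("mito fraction at exactly the threshold is retained", {
  counts <- matrix(1L, 20, 2)
  rownames(counts) <- c("MT-1", sprintf("g%02d", 1:19))
  # cell1: mito = 15% of total exactly: 19 non-mito counts = 85% -> mito
  # = 19 * 15/85... use counts: non-mito 17, mito 3 -> 3/20 = 0.15
  counts[, 1] <- 0L
  counts[2:18, 1] <- 1L
  counts["MT-1", 1] <- 3L
  sce <- make_sce(counts)
  res <- qc_filter(sce, pipeline_config(min_genes_per_cell = 1))
  expect_true("c001" %in% colnames(res$matrix))
  # no mito genes at all -> fraction 0, nothing removed by the mito rule
  counts2 <- matrix(1L, 5, 3)
  rownames(counts2) <- sprintf("x%d", 1:5)
  res2 <- qc_filter(make_sce(counts2),
                    pipeline_config(min_genes_per_cell = 1))
  expect_equal(ncol(res2$matrix), 3)
  expect_true(all(res2$report$mito_fraction == 0))
})

test_that("qc_filter is idempotent and drops empty genes", {
  sim <- get_small_sim()
  cfg <- small_cfg()
  once <- qc_filter(sim$matrix, cfg)
  twice <- qc_filter(once$matrix, cfg)
  expect_identical(dim(once$matrix), dim(twice$matrix))
  expect_identical(colnames(once$matrix), colnames(twice$matrix))
  counts <- SummarizedExperiment::assay(once$matrix, "counts")
  expect_true(all(Matrix::rowSums(counts) > 0))
  # planted low-quality cells are the ones removed
  tt <- sim$cell_truth
  removed <- tt$cell_id[!tt$cell_id %in% colnames(once$matrix)]
  planted <- tt$planted_high_mito | tt$planted_low_lib
  expect_gt(mean(tt$cell_id[planted] %in% removed), 0.8)
})

test_that("qc_filter with an impossible threshold errors informatively", {
  sim <- get_small_sim()
  expect_error(qc_filter(sim$matrix,
                         pipeline_config(min_genes_per_cell = 1,
                                         max_mito_fraction = 0)),
               "removed every cell")
})

test_that("log_normalize matches direct evaluation and its identity", {
  counts <- matrix(c(1, 0, 3), nrow = 3, ncol = 1)
  sce <- log_normalize(make_sce(counts), scale_factor = 10000)
  x <- as.matrix(SummarizedExperiment::assay(sce, "logcounts"))[, 1]
  expect_equal(unname(x), c(log(2501), 0, log(7501)), tolerance = 1e-12)
  expect_equal(unname(x[1]), 7.824446, tolerance = 1e-6)
  expect_equal(unname(x[3]), 8.922792, tolerance = 1e-6)
  # identity: sum(expm1(x)) = scale factor for every cell
  sim <- get_small_sim()
  m <- log_normalize(qc_filter(sim$matrix, small_cfg())$matrix, 10000)
  e <- SummarizedExperiment::assay(m, "logcounts")
  expect_lt(max(abs(Matrix::colSums(expm1(e)) - 10000)) / 10000, 1e-6)
  # zero total errors
  z <- make_sce(matrix(0, 3, 2))
  expect_error(log_normalize(z), "zero total")
})

test_that("select_hvg ranks a planted high-variance gene first", {
  set.seed(21)
  n <- 300
  lambda <- seq(0.5, 50, length.out = 100)
  base <- matrix(rpois(100 * n, lambda = rep(lambda, n)), 100, n)
  rownames(base) <- sprintf("g%03d", 1:100)
  # one gene with ~50x the Poisson variance at the same mean
  base["g050", ] <- rnbinom(n, mu = lambda[50], size = 0.5)
  sce <- make_sce(base)
  hvg <- select_hvg(sce, 10)
  expect_equal(hvg[1], "g050")
  # n_hvg = all genes returns all
  expect_length(select_hvg(sce, 100), 100)
  expect_error(select_hvg(sce, 101), "exceeds")
})

test_that("constant genes tie at zero and break ties lexicographically", {
  counts <- matrix(5, 20, 30)
  rownames(counts) <- sprintf("g%02d", 20:1)  # reversed names
  sce <- make_sce(counts)
  hvg <- select_hvg(sce, 5)
  expect_identical(as.character(hvg), sprintf("g%02d", 1:5))
})

test_that("scale_and_pca z-scores, clips, and orders components", {
  sim <- get_small_sim()
  cfg <- small_cfg()
  m <- log_normalize(qc_filter(sim$matrix, cfg)$matrix)
  hvg <- select_hvg(m, 300)
  m <- scale_and_pca(m, hvg, n_pcs = 15, clip = 10)
  scaled <- S4Vectors::metadata(m)$scaled
  expect_lt(max(abs(rowMeans(scaled))), 1e-8 + 0.2)  # post-clip means
  pre_clip_sd <- apply(scaled, 1, sd)
  expect_true(all(abs(scaled) <= 10))
  pca <- SingleCellExperiment::reducedDim(m, "PCA")
  pv <- attr(pca, "percentVar")
  expect_equal(ncol(pca), 15)
  expect_true(all(diff(pv) <= 1e-10))  # decreasing explained variance
  # sign convention: largest-|loading| positive => deterministic repeat
  m2 <- scale_and_pca(m, hvg, n_pcs = 15, clip = 10)
  expect_identical(SingleCellExperiment::reducedDim(m2, "PCA"), pca)
})

test_that("scaling without clipping gives exact row moments", {
  set.seed(3)
  counts <- matrix(rpois(50 * 40, 10), 50, 40)
  sce <- log_normalize(make_sce(counts))
  hvg <- rownames(sce)[1:30]
  out <- scale_and_pca(sce, hvg, n_pcs = 5, clip = 1e9)
  scaled <- S4Vectors::metadata(out)$scaled
  expect_lt(max(abs(rowMeans(scaled))), 1e-8)
  expect_lt(max(abs(apply(scaled, 1, sd) - 1)), 1e-6)
})

test_that("exact rank-2 data puts zero variance on components 3+", {
  set.seed(11)
  n_cells <- 100
  u <- matrix(rnorm(40 * 2), 40, 2)
  v <- matrix(rnorm(2 * n_cells), 2, n_cells)
  sce <- make_sce(matrix(1L, 40, n_cells))
  # plant an exact 2-dimensional latent factor as the expression matrix;
  # z-scoring preserves rank <= 2, so PCs 3+ must carry ~0 variance
  SummarizedExperiment::assay(sce, "logcounts",
                              withDimnames = FALSE) <- u %*% v
  out <- scale_and_pca(sce, rownames(sce), n_pcs = 10, clip = 1e9)
  pv <- attr(SingleCellExperiment::reducedDim(out, "PCA"), "percentVar")
  expect_gt(sum(pv[1:2]), 100 - 1e-8)
  expect_lt(sum(pv[3:10]), 1e-8)
})

test_that("PCA reconstruction error is non-increasing in n_pcs", {
  set.seed(5)
  counts <- matrix(rpois(60 * 50, 20), 60, 50)
  sce <- log_normalize(make_sce(counts))
  errs <- vapply(c(2, 5, 10, 20), function(k) {
    out <- scale_and_pca(sce, rownames(sce), n_pcs = k, clip = 1e9)
    scaled <- S4Vectors::metadata(out)$scaled
    pc <- prcomp(t(scaled), center = TRUE)
    recon <- pc$x[, 1:k] %*% t(pc$rotation[, 1:k])
    recon <- sweep(recon, 2, pc$center, "+")
    sum((t(scaled) - recon)^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
})
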
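# Shared fixtures and independent oracles used across the test files.

suppressPackageStartupMessages({
  library(Matrix)
  library(SingleCellExperiment)
})

# Small SingleCellExperiment from a dense counts matrix
make_sce <- function(counts, gene_names = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("c%03d", seq_len(ncol(counts)))
  }
  SingleCellExperiment(
    assays = list(counts = as(counts, "CsparseMatrix")),
    rowData = S4Vectors::DataFrame(
      gene_id = rownames(counts),
      gene_name = gene_names %||% rownames(counts),
      row.names = rownames(counts))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One small simulation reused by several test files (built lazily once)
small_sim_cache <- new.env(parent = emptyenv())
get_small_sim <- function() {
  if (is.null(small_sim_cache$sim)) {
    small_sim_cache$sim <- simulate_counts(continuum_params(
      n_cells_per_dose = c(UT = 150, dose_2.5 = 150, dose_10 = 150,
                           dose_25 = 150),
      n_genes = 800, n_senotype = 40, n_biosynthesis = 40, seed = 5))
  }
  small_sim_cache$sim
}

small_cfg <- function(...) {
  pipeline_config(min_genes_per_cell = 200, n_hvg = 400,
                  dge_min_pct = 0, dge_min_logfc = 0.1, ...)
}

# Normalized small matrix with PCA, phase, clusters (lazily built once)
get_small_processed <- function() {
  if (is.null(small_sim_cache$proc)) {
    sim <- get_small_sim()
    cfg <- small_cfg()
    qc <- qc_filter(sim$matrix, cfg)
    m <- log_normalize(qc$matrix, cfg$scale_factor)
    hvg <- select_hvg(m, cfg$n_hvg)
    m <- scale_and_pca(m, hvg, n_pcs = cfg$n_pcs, clip = cfg$scale_clip)
    truth <- sim$cell_truth[match(colnames(m), sim$cell_truth$cell_id), ]
    small_sim_cache$proc <- list(m = m, truth = truth,
                                 genes = sim$gene_truth, cfg = cfg)
  }
  small_sim_cache$proc
}

# ---- independent oracles ------------------------------------------------

# Exhaustive-enumeration two-sided Wilcoxon rank-sum p-value
oracle_wilcoxon_p <- function(x, y) {
  nx <- length(x)
  n <- nx + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  combs <- utils::combn(n, nx)
  ws <- apply(combs, 2, function(idx) sum(r[idx]))
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Brute-force weighted running-sum enrichment score
oracle_es <- function(scores, hit, weight = 1) {
  n <- length(scores)
  nh <- sum(hit)
  if (nh == 0 || nh == n) return(0)
  denom <- sum(abs(scores[hit])^weight)
  running <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (hit[i]) {
      inc <- if (denom > 0) abs(scores[i])^weight / denom else 1 / nh
      running <- running + inc
    } else {
      running <- running - 1 / (n - nh)
    }
    if (abs(running) > abs(best) + 1e-12) best <- running
  }
  best
}

# Direct tricube weighted-least-squares fit at one grid point
oracle_wls_tricube <- function(x, y, x0, span = 1, degree = 1) {
  d <- abs(x - x0)
  q <- max(2, floor(span * length(x)))
  dq <- sort(d)[min(q, length(x))]
  w <- (1 - pmin(d / dq, 1)^3)^3
  X <- stats::poly(x - x0, degree = degree, raw = TRUE, simple = TRUE)
  X <- cbind(1, X)
  fit <- stats::lm.wfit(X, y, w)
  unname(fit$coefficients[1])
}

# Brute-force module score mirroring the seeded control sampling
oracle_module_score <- function(sce, genes, n_bins, n_ctrl, seed,
                                exclude = genes) {
  expr <- as.matrix(SummarizedExperiment::assay(sce, "logcounts"))
  present <- sort(intersect(unique(genes), rownames(expr)))
  avg <- rowMeans(expr)
  rk <- rank(avg, ties.method = "first")
  bins <- cut(rk, breaks = n_bins, labels = FALSE, include.lowest = TRUE)
  names(bins) <- rownames(expr)
  excluded <- union(exclude, present)
  set.seed(seed)
  ctrl <- character(0)
  for (g in present) {
    pool <- setdiff(names(bins)[bins == bins[[g]]], excluded)
    if (length(pool) == 0) next
    ctrl <- c(ctrl, pool[sample.int(length(pool),
                                    min(n_ctrl, length(pool)))])
  }
  set_mean <- colMeans(expr[present, , drop = FALSE])
  ctrl_mean <- colMeans(expr[ctrl, , drop = FALSE])
  set_mean - ctrl_mean
}
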
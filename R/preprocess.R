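# Quality control, log-normalization, highly-variable-gene selection,
# scaling and PCA.

#' Per-cell QC statistics
#'
#' @param sce A `SingleCellExperiment` with a `counts` assay.
#' @param mito_pattern Case-insensitive regex on gene names identifying
#'   mitochondrial genes.
#' @return Data frame with `cell_id`, `n_genes_detected`, `total_counts`,
#'   `mito_fraction`.
#' @export
qc_metrics <- function(sce, mito_pattern = "^MT-") {
  counts <- SummarizedExperiment::assay(sce, "counts")
  rd <- SummarizedExperiment::rowData(sce)
  gene_names <- rd$gene_name %||% rownames(sce)
  mito <- grepl(mito_pattern, gene_names, ignore.case = TRUE)
  totals <- Matrix::colSums(counts)
  data.frame(
    cell_id = colnames(sce),
    n_genes_detected = Matrix::colSums(counts > 0),
    total_counts = totals,
    mito_fraction = ifelse(totals > 0,
                           Matrix::colSums(counts[mito, , drop = FALSE]) /
                             totals, 0),
    stringsAsFactors = FALSE
  )
}

#' Filter low-quality cells
#'
#' Keeps cells with at least `min_genes_per_cell` detected genes and at most
#' `max_mito_fraction` mitochondrial counts (strict inequalities remove:
#' fewer detected genes than the minimum, or a greater mitochondrial
#' fraction than the maximum). Optional total-count bounds are applied when
#' configured. Genes detected in zero retained cells are dropped. The first
#' failing rule (genes, mito, counts, in that order) is recorded per removed
#' cell.
#'
#' @param sce A `SingleCellExperiment` with raw counts.
#' @param config A [pipeline_config()].
#' @return List with `matrix` (filtered `SingleCellExperiment`, QC columns
#'   added to `colData`) and `report` (per-cell QC table with `pass` and
#'   `reason`, plus a `removed` attribute tabulating removal reasons).
#' @export
qc_filter <- function(sce, config = pipeline_config()) {
  qc <- qc_metrics(sce, config$mito_pattern)
  reason <- rep(NA_character_, nrow(qc))
  fail_genes <- qc$n_genes_detected < config$min_genes_per_cell
  fail_mito <- qc$mito_fraction > config$max_mito_fraction
  fail_counts <- rep(FALSE, nrow(qc))
  if (!is.null(config$min_total_counts)) {
    fail_counts <- fail_counts | qc$total_counts < config$min_total_counts
  }
  if (!is.null(config$max_total_counts)) {
    fail_counts <- fail_counts | qc$total_counts > config$max_total_counts
  }
  reason[fail_counts] <- "total_counts"
  reason[fail_mito] <- "mito_fraction"
  reason[fail_genes] <- "n_genes_detected"   # first rule wins
  qc$pass <- is.na(reason)
  qc$reason <- reason
  assert_that(any(qc$pass), "QC removed every cell; relax the thresholds")
  kept <- sce[, qc$pass]
  counts <- SummarizedExperiment::assay(kept, "counts")
  expressed <- Matrix::rowSums(counts) > 0
  kept <- kept[expressed, ]
  for (col in c("n_genes_detected", "total_counts", "mito_fraction")) {
    SummarizedExperiment::colData(kept)[[col]] <- qc[[col]][qc$pass]
  }
  removed <- table(factor(reason[!qc$pass],
                          levels = c("n_genes_detected", "mito_fraction",
                                     "total_counts")))
  attr(qc, "removed") <- as.list(removed)
  attr(qc, "genes_dropped") <- sum(!expressed)
  list(matrix = kept, report = qc)
}

#' Log-normalize counts
#'
#' Computes `x = ln(1 + scale_factor * c / T)` per gene and cell, where `T`
#' is the cell's total count. By construction `sum(expm1(x))` over genes
#' equals `scale_factor` for every cell.
#'
#' @param sce A `SingleCellExperiment` with counts.
#' @param scale_factor Scale factor (default 10,000).
#' @return The object with a `logcounts` assay added.
#' @export
log_normalize <- function(sce, scale_factor = 10000) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  totals <- Matrix::colSums(counts)
  assert_that(all(totals > 0), "cells with zero total counts present")
  norm <- counts %*% Matrix::Diagonal(x = scale_factor / totals)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  SummarizedExperiment::assay(sce, "logcounts") <-
    methods::as(norm, "CsparseMatrix")
  sce
}

#' Select highly variable genes
#'
#' Ranks genes by standardized variance after a variance-stabilizing
#' mean-variance trend fit on raw counts: a loess of log10 variance on
#' log10 mean predicts each gene's expected variance; counts are
#' standardized by the predicted SD, clipped at `sqrt(n_cells)`, and the
#' variance of the clipped standardized values is the ranking statistic.
#' Ties are broken lexicographically by gene id, so the selection is
#' deterministic.
#'
#' @param sce A `SingleCellExperiment` with counts.
#' @param n_hvg Number of genes to return.
#' @param loess_span Span of the trend fit.
#' @return Character vector of `n_hvg` gene ids ordered by decreasing
#'   standardized variance, with the full statistic table as attribute
#'   `"stats"`.
#' @export
select_hvg <- function(sce, n_hvg = 2000, loess_span = 0.3) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  assert_that(n_hvg <= nrow(counts),
              "`n_hvg` exceeds the number of genes")
  n <- ncol(counts)
  mu <- Matrix::rowMeans(counts)
  v <- Matrix::rowSums((counts - mu)^2) / (n - 1)
  std_var <- numeric(length(mu))
  fit_ok <- v > 0 & mu > 0
  if (sum(fit_ok) > 10) {
    df <- data.frame(lm = log10(mu[fit_ok]), lv = log10(v[fit_ok]))
    trend <- stats::loess(lv ~ lm, data = df, span = loess_span,
                          degree = 2,
                          control = stats::loess.control(
                            surface = "direct"))
    exp_sd <- sqrt(10^stats::predict(trend, df))
    clip <- sqrt(n)
    dense <- as_dense(counts[fit_ok, , drop = FALSE])
    z <- (dense - mu[fit_ok]) / exp_sd
    z[z > clip] <- clip
    z[z < -clip] <- -clip
    std_var[fit_ok] <- apply(z, 1, stats::var)
  }
  ids <- rownames(counts)
  ord <- order(-std_var, ids)
  out <- ids[ord][seq_len(n_hvg)]
  attr(out, "stats") <- data.frame(gene_id = ids, mean = mu, variance = v,
                                   standardized_variance = std_var,
                                   stringsAsFactors = FALSE)
  out
}

#' Scale highly variable genes and run PCA
#'
#' Z-scores each HVG across cells on the log-normalized data (mean 0, SD 1),
#' clips at `+/- clip`, and computes `n_pcs` principal components of the
#' cells on the scaled matrix. Components are ordered by decreasing
#' explained variance and sign-fixed so each component's largest-magnitude
#' gene loading is positive, making the decomposition deterministic.
#'
#' @param sce A `SingleCellExperiment` with `logcounts`.
#' @param hvg Character vector of gene ids (from [select_hvg()]).
#' @param n_pcs Number of components.
#' @param clip Absolute clip on the z-scores.
#' @return The object with the scaled HVG matrix in
#'   `metadata(sce)$scaled`, PCA coordinates in `reducedDim(sce, "PCA")`
#'   (attribute `"percentVar"` holds explained variance), and the HVG list
#'   in `metadata(sce)$hvg`.
#' @export
scale_and_pca <- function(sce, hvg, n_pcs = 30, clip = 10) {
  assert_that("logcounts" %in%
                SummarizedExperiment::assayNames(sce),
              "run log_normalize() first")
  missing <- setdiff(hvg, rownames(sce))
  assert_that(length(missing) == 0,
              paste0("HVGs absent from the matrix: ",
                     paste(utils::head(missing, 5), collapse = ", ")))
  x <- as_dense(SummarizedExperiment::assay(sce, "logcounts")[hvg, ,
                                                              drop = FALSE])
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance HVG(s) excluded from scaling")
    x <- x[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  scaled <- (x - rowMeans(x)) / sds
  scaled[scaled > clip] <- clip
  scaled[scaled < -clip] <- -clip
  n_pcs <- min(n_pcs, nrow(scaled) - 1L, ncol(scaled) - 1L)
  pc <- stats::prcomp(t(scaled), center = TRUE, scale. = FALSE,
                      rank. = n_pcs)
  # deterministic sign: largest-|loading| positive per component
  for (j in seq_len(ncol(pc$rotation))) {
    i_max <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i_max, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  coords <- pc$x[, seq_len(n_pcs), drop = FALSE]
  attr(coords, "percentVar") <-
    pc$sdev[seq_len(n_pcs)]^2 / sum(pc$sdev^2) * 100
  SingleCellExperiment::reducedDim(sce, "PCA") <- coords
  S4Vectors::metadata(sce)$scaled <- scaled
  S4Vectors::metadata(sce)$hvg <- hvg
  sce
}
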
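# Wilcoxon rank-sum differential expression and the ranking score.

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact for small samples even in the presence of ties, by dynamic
#' programming over the permutation distribution of the rank sum (midranks
#' doubled to integers); normal approximation with tie correction and
#' continuity correction for larger samples.
#'
#' @param x,y Numeric samples.
#' @param exact_max Use the exact distribution when `length(x) + length(y)`
#'   is at most this (default 50).
#' @return Two-sided p-value in (0, 1].
#' @export
rank_sum_p <- function(x, y, exact_max = 50) {
  nx <- length(x)
  ny <- length(y)
  assert_that(nx >= 1 && ny >= 1, "both groups must be non-empty")
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  n <- nx + ny
  if (n <= exact_max) {
    # permutation distribution of the rank sum for subsets of size nx,
    # via subset-sum DP on doubled midranks (integers)
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    # dp[[k]][s+1] = number of size-k subsets with doubled-rank sum s
    max_s <- sum(sort(r2, decreasing = TRUE)[seq_len(nx)])
    dp <- matrix(0, nrow = nx + 1L, ncol = max_s + 1L)
    dp[1L, 1L] <- 1
    for (ri in r2) {
      kmax <- nx
      for (kk in seq(from = min(kmax, nx), to = 1L)) {
        shifted <- c(rep(0, ri), dp[kk, seq_len(max_s + 1L - ri)])
        dp[kk + 1L, ] <- dp[kk + 1L, ] + shifted
      }
    }
    counts <- dp[nx + 1L, ]
    sums <- (seq_along(counts) - 1L) / 2    # back to rank-sum scale
    totc <- sum(counts)
    p_le <- sum(counts[sums <= w + 1e-9]) / totc
    p_ge <- sum(counts[sums >= w - 1e-9]) / totc
    return(min(1, 2 * min(p_le, p_ge)))
  }
  # normal approximation with tie and continuity correction
  mu <- nx * (n + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / ((n) * (n - 1))
  sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  z <- w - mu
  z <- z - sign(z) * 0.5   # continuity correction
  p <- 2 * stats::pnorm(-abs(z) / sqrt(sigma2))
  min(1, max(p, .Machine$double.xmin))
}

#' Wilcoxon differential expression between two cell groups
#'
#' Genes are pre-filtered to those detected in at least `min_pct` of cells
#' in either group and with `|avg_log2FC| >= min_logfc`. The fold change is
#' computed on the de-logged normalized scale with a pseudocount of 1:
#' `avg_log2FC = log2((mean_A(expm1 x) + 1) / (mean_B(expm1 x) + 1))`.
#' P-values come from [rank_sum_p()]; both Bonferroni (m = genes tested)
#' and Benjamini-Hochberg adjusted values are reported.
#'
#' @param sce A `SingleCellExperiment` with `logcounts`.
#' @param cells_a,cells_b Disjoint cell selectors (ids, indices or logical).
#' @param min_pct Minimum expressing fraction in either group.
#' @param min_logfc Minimum absolute avg_log2FC.
#' @return Data frame (one row per tested gene): `gene_id`, `avg_log2FC`,
#'   `p_value`, `p_adj_bonferroni`, `p_adj_bh`, `pct_in`, `pct_out`, sorted
#'   by increasing p then decreasing |fold change|.
#' @export
wilcoxon_dge <- function(sce, cells_a, cells_b, min_pct = 0.1,
                         min_logfc = 0.25) {
  cells_a <- resolve_cells(sce, cells_a)
  cells_b <- resolve_cells(sce, cells_b)
  assert_that(length(intersect(cells_a, cells_b)) == 0,
              "cell groups overlap")
  assert_that(length(cells_a) >= 2 && length(cells_b) >= 2,
              "each group needs at least 2 cells")
  expr <- SummarizedExperiment::assay(sce, "logcounts")
  xa <- expr[, cells_a, drop = FALSE]
  xb <- expr[, cells_b, drop = FALSE]
  pct_in <- Matrix::rowMeans(xa > 0)
  pct_out <- Matrix::rowMeans(xb > 0)
  mean_a <- Matrix::rowMeans(expm1_mat(xa))
  mean_b <- Matrix::rowMeans(expm1_mat(xb))
  lfc <- log2((mean_a + 1) / (mean_b + 1))
  keep <- (pmax(pct_in, pct_out) >= min_pct) & (abs(lfc) >= min_logfc)
  genes <- rownames(expr)[keep]
  if (length(genes) == 0) {
    return(data.frame(gene_id = character(), avg_log2FC = numeric(),
                      p_value = numeric(), p_adj_bonferroni = numeric(),
                      p_adj_bh = numeric(), pct_in = numeric(),
                      pct_out = numeric(), stringsAsFactors = FALSE))
  }
  da <- as_dense(xa[genes, , drop = FALSE])
  db <- as_dense(xb[genes, , drop = FALSE])
  p <- vapply(seq_along(genes), function(i) {
    rank_sum_p(da[i, ], db[i, ])
  }, numeric(1))
  out <- data.frame(
    gene_id = genes,
    avg_log2FC = lfc[keep],
    p_value = p,
    p_adj_bonferroni = stats::p.adjust(p, method = "bonferroni"),
    p_adj_bh = stats::p.adjust(p, method = "BH"),
    pct_in = pct_in[keep],
    pct_out = pct_out[keep],
    stringsAsFactors = FALSE
  )
  out[order(out$p_value, -abs(out$avg_log2FC), out$gene_id), ,
      drop = FALSE]
}

#' @noRd
expm1_mat <- function(x) {
  if (methods::is(x, "sparseMatrix")) {
    x@x <- expm1(x@x)
    x
  } else {
    expm1(x)
  }
}

#' Ranking scores for a DGE table
#'
#' Computes `ranking_score = avg_log2FC * -log10(p_adj)` per gene, the
#' prioritization metric combining effect size and significance, and sorts
#' genes by decreasing score (ties broken lexicographically by gene id).
#' Adjusted p-values are floored at `eps` before the log so fully saturated
#' significance stays finite; `p_adj = 1` gives a score of exactly 0.
#'
#' @param dge A data frame from [wilcoxon_dge()].
#' @param adjust Which adjusted p to use: `"bh"` (default) or
#'   `"bonferroni"`.
#' @param eps Floor for adjusted p-values.
#' @return The table with a `ranking_score` column, sorted by decreasing
#'   score.
#' @export
ranking_scores <- function(dge, adjust = c("bh", "bonferroni"),
                           eps = 1e-300) {
  adjust <- match.arg(adjust)
  col <- if (adjust == "bh") "p_adj_bh" else "p_adj_bonferroni"
  assert_that(col %in% names(dge),
              paste0("DGE table lacks column ", col))
  p_adj <- pmax(dge[[col]], eps)
  dge$ranking_score <- dge$avg_log2FC * (-log10(p_adj))
  dge[order(-dge$ranking_score, dge$gene_id), , drop = FALSE]
}
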
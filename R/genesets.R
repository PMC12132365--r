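# Derivation of the two bespoke gene sets: the shared SASP set (top-n of
# the SASP leading-edge genes per senescent cluster, intersected across
# clusters) and the etoposide-induced senescence signature (top genes of
# the pooled-senescent DGE plus the weakly-identified cluster, minus genes
# elevated in untreated G0/G1 cells), plus per-cell scoring against them.

#' Shared SASP genes across senescent clusters
#'
#' For each senescent cluster, ranks the SASP leading-edge genes by that
#' cluster's ranking score and takes the top `top_n`; the result is the
#' intersection of these per-cluster lists - the SASP genes upregulated in
#' every senotype. The derivation is deterministic and invariant to the
#' order of the clusters.
#'
#' @param sasp_leading_edge Character vector of SASP-related leading-edge
#'   genes.
#' @param per_cluster_dge Named list of DGE tables (one per senescent
#'   cluster, each vs all other cells) carrying `ranking_score` (tables
#'   without it are passed through [ranking_scores()] with defaults).
#' @param top_n Genes taken per cluster (default 50).
#' @return List with `genes` (the intersection, ordered by the first
#'   cluster's ranking) and `trace` (per-step intermediate lists).
#' @export
shared_sasp_genes <- function(sasp_leading_edge, per_cluster_dge,
                              top_n = 50) {
  assert_that(length(sasp_leading_edge) > 0,
              "leading-edge list is empty")
  assert_that(length(per_cluster_dge) >= 1 &&
                !is.null(names(per_cluster_dge)),
              "`per_cluster_dge` must be a named list of DGE tables")
  if (length(per_cluster_dge) == 1) {
    warning("single cluster supplied; returning its top list unchanged")
  }
  top_lists <- lapply(per_cluster_dge, function(tab) {
    if (!"ranking_score" %in% names(tab)) tab <- ranking_scores(tab)
    missing <- setdiff(sasp_leading_edge, tab$gene_id)
    assert_that(length(missing) < length(sasp_leading_edge),
                "a cluster DGE table contains none of the genes")
    sub <- tab[tab$gene_id %in% sasp_leading_edge, , drop = FALSE]
    sub <- sub[order(-sub$ranking_score, sub$gene_id), , drop = FALSE]
    utils::head(sub$gene_id, top_n)
  })
  shared <- Reduce(intersect, top_lists)
  # order by the first cluster's ranking for a stable, meaningful output
  shared <- top_lists[[1]][top_lists[[1]] %in% shared]
  list(
    genes = shared,
    trace = list(
      input_leading_edge = sasp_leading_edge,
      top_n = top_n,
      per_cluster_top = top_lists,
      intersection = shared
    )
  )
}

#' Derive the etoposide-induced senescence signature
#'
#' Takes the union of the `top_combined` genes (by ranking score) from the
#' pooled senescent-vs-rest DGE and the `top_weak` genes from the
#' weakly-identified cluster's DGE, deduplicated preserving best rank,
#' then removes genes elevated in untreated G0/G1 cells: a gene is dropped
#' when its mean normalized expression (on the de-logged `expm1` scale,
#' the same scale as the fold change) in the untreated G0/G1 group exceeds
#' `background_ratio` times its mean in the pooled senescent cells. The
#' trace records every removal with both means.
#'
#' @param dge_combined DGE table of pooled senescent clusters vs all other
#'   cells.
#' @param dge_weak DGE table of the weakly-identified senescent cluster vs
#'   all other cells.
#' @param sce A `SingleCellExperiment` with `logcounts`.
#' @param senescent_cells,untreated_g0g1_cells Cell selectors for the two
#'   reference populations.
#' @param top_combined,top_weak Genes taken from each table.
#' @param background_ratio Removal threshold on the untreated/senescent
#'   mean-expression ratio.
#' @return List with `genes` and a `trace` of every step.
#' @export
derive_senescence_signature <- function(dge_combined, dge_weak, sce,
                                        senescent_cells,
                                        untreated_g0g1_cells,
                                        top_combined = 100, top_weak = 50,
                                        background_ratio = 0.5) {
  untreated_g0g1_cells <- resolve_cells(sce, untreated_g0g1_cells)
  senescent_cells <- resolve_cells(sce, senescent_cells)
  assert_that(length(untreated_g0g1_cells) > 0,
              "untreated G0/G1 group is empty")
  if (!"ranking_score" %in% names(dge_combined)) {
    dge_combined <- ranking_scores(dge_combined)
  }
  if (!"ranking_score" %in% names(dge_weak)) {
    dge_weak <- ranking_scores(dge_weak)
  }
  top1 <- utils::head(dge_combined$gene_id, top_combined)
  top2 <- utils::head(dge_weak$gene_id, top_weak)
  combined <- unique(c(top1, top2))   # best-rank-first union

  expr <- SummarizedExperiment::assay(sce, "logcounts")
  present <- intersect(combined, rownames(expr))
  mean_bg <- Matrix::rowMeans(expm1_mat(
    expr[present, untreated_g0g1_cells, drop = FALSE]))
  mean_sen <- Matrix::rowMeans(expm1_mat(
    expr[present, senescent_cells, drop = FALSE]))
  elevated <- mean_bg > background_ratio * mean_sen
  removed <- present[elevated]
  final <- setdiff(combined, removed)
  list(
    genes = final,
    trace = list(
      top_combined = top1,
      top_weak = top2,
      union = combined,
      background_means = data.frame(
        gene_id = present,
        mean_untreated_g0g1 = unname(mean_bg),
        mean_senescent = unname(mean_sen),
        removed = unname(elevated),
        stringsAsFactors = FALSE
      ),
      background_ratio = background_ratio,
      removed = removed,
      final = final
    )
  )
}

#' Score cells against a gene set
#'
#' Applies the binned-control [module_score()] and, when cluster labels
#' are supplied, summarizes the score distribution per cluster (median and
#' interquartile range). The score depends only on expression, never on
#' the labels.
#'
#' @param sce A `SingleCellExperiment` with `logcounts`.
#' @param genes Gene set to score.
#' @param clusters Optional per-cell cluster labels.
#' @param n_bins,n_ctrl,seed Passed to [module_score()].
#' @return List with `score` (per-cell) and `by_cluster` (data frame or
#'   `NULL`).
#' @export
score_gene_set <- function(sce, genes, clusters = NULL, n_bins = 24,
                           n_ctrl = 100, seed = 42L) {
  score <- module_score(sce, genes, n_bins = n_bins, n_ctrl = n_ctrl,
                        seed = seed)
  by_cluster <- NULL
  if (!is.null(clusters)) {
    assert_that(length(clusters) == ncol(sce),
                "`clusters` must have one label per cell")
    sp <- split(score, clusters)
    by_cluster <- data.frame(
      cluster = names(sp),
      n = vapply(sp, length, integer(1)),
      median = vapply(sp, stats::median, numeric(1)),
      q25 = vapply(sp, function(v) stats::quantile(v, 0.25), numeric(1)),
      q75 = vapply(sp, function(v) stats::quantile(v, 0.75), numeric(1)),
      stringsAsFactors = FALSE
    )
  }
  list(score = score, by_cluster = by_cluster)
}
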
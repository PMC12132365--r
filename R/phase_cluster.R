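# Gene module scoring with binned controls, cell-cycle phase assignment,
# SNN/Leiden clustering, 2-D embedding, and composition tables.

#' Binned-control gene module score
#'
#' For each set gene, `n_ctrl` control genes are drawn (seeded, without
#' replacement) from the same average-expression bin; the score is the mean
#' log-normalized expression of the set genes minus the mean over the pooled
#' control genes, per cell. Genes are binned into `n_bins` equal-frequency
#' bins of average expression across cells. The score is invariant to the
#' order of genes within the set.
#'
#' @param sce A `SingleCellExperiment` with `logcounts`.
#' @param genes Character vector of gene ids in the set.
#' @param n_bins Number of average-expression bins.
#' @param n_ctrl Control genes sampled per set gene (capped at the bin
#'   size).
#' @param seed Integer seed for control sampling.
#' @param exclude_from_controls Genes never used as controls. Defaults to
#'   the set itself; callers scoring related programs (e.g. the two phase
#'   lists) can pass their union so neither program contaminates the
#'   other's control pool.
#' @return Named numeric vector of per-cell scores.
#' @export
module_score <- function(sce, genes, n_bins = 24, n_ctrl = 100,
                         seed = 42L, exclude_from_controls = genes) {
  assert_that("logcounts" %in% SummarizedExperiment::assayNames(sce),
              "run log_normalize() first")
  expr <- SummarizedExperiment::assay(sce, "logcounts")
  present <- intersect(unique(genes), rownames(expr))
  if (length(present) == 0) {
    stop("none of the set genes are in the matrix: ",
         paste(utils::head(genes, 10), collapse = ", "), call. = FALSE)
  }
  present <- sort(present)  # order-invariance
  avg <- Matrix::rowMeans(expr)
  # equal-frequency bins on average expression (ties stay together by rank)
  rk <- rank(avg, ties.method = "first")
  bins <- if (n_bins < 2) {
    rep(1L, length(rk))
  } else {
    cut(rk, breaks = n_bins, labels = FALSE, include.lowest = TRUE)
  }
  names(bins) <- rownames(expr)
  excluded <- union(exclude_from_controls, present)
  ctrl <- with_seed(seed, {
    unlist(lapply(present, function(g) {
      pool <- names(bins)[bins == bins[[g]]]
      pool <- setdiff(pool, excluded)
      if (length(pool) == 0) return(character(0))
      pool[sample_int(length(pool), min(n_ctrl, length(pool)))]
    }), use.names = FALSE)
  })
  set_mean <- Matrix::colMeans(expr[present, , drop = FALSE])
  ctrl_mean <- if (length(ctrl)) {
    Matrix::colMeans(expr[ctrl, , drop = FALSE])
  } else {
    rep(0, ncol(expr))
  }
  score <- set_mean - ctrl_mean
  names(score) <- colnames(expr)
  score
}

#' Assign cell-cycle phase from S and G2/M module scores
#'
#' A cell is called `S` when its S score exceeds both the G2/M score and
#' zero; `G2M` when the G2/M score is at least the S score and positive;
#' any cell not categorized as S or G2/M is labeled `G0/G1`.
#'
#' @param sce A `SingleCellExperiment` with `logcounts`.
#' @param s_genes,g2m_genes Phase marker gene ids.
#' @param n_bins,n_ctrl,seed Passed to [module_score()].
#' @return Data frame with `cell_id`, `s_score`, `g2m_score`, `phase`.
#' @export
assign_phase <- function(sce, s_genes, g2m_genes, n_bins = 24,
                         n_ctrl = 100, seed = 42L) {
  both <- union(s_genes, g2m_genes)
  s_score <- module_score(sce, s_genes, n_bins, n_ctrl, seed,
                          exclude_from_controls = both)
  g2m_score <- module_score(sce, g2m_genes, n_bins, n_ctrl, seed,
                            exclude_from_controls = both)
  phase <- rep("G0/G1", ncol(sce))
  phase[g2m_score >= s_score & g2m_score > 0] <- "G2M"
  phase[s_score > g2m_score & s_score > 0] <- "S"
  data.frame(cell_id = colnames(sce), s_score = unname(s_score),
             g2m_score = unname(g2m_score), phase = phase,
             stringsAsFactors = FALSE)
}

#' Exact k-nearest neighbours in PC space
#' @noRd
knn_indices <- function(coords, k) {
  n <- nrow(coords)
  assert_that(k < n, "`k` must be smaller than the number of cells")
  d <- as.matrix(stats::dist(coords))
  t(apply(d, 1, function(row) order(row)[seq_len(k)]))  # includes self
}

#' Shared-nearest-neighbour Leiden clustering
#'
#' Builds a k-NN graph in PC space (neighbour sets include the cell
#' itself), weights each edge by the Jaccard overlap of the two neighbour
#' sets, prunes weights below `prune`, and partitions the graph by Leiden
#' modularity optimization at the given resolution. Cluster ids are
#' relabeled in decreasing size order (1 = largest), and the partition is
#' deterministic at a fixed seed.
#'
#' @param sce A `SingleCellExperiment` with a `"PCA"` reducedDim, or a
#'   numeric cells x dims matrix.
#' @param k Neighbours per cell.
#' @param resolution Modularity resolution.
#' @param prune Jaccard cutoff below which edges are discarded.
#' @param seed Integer seed.
#' @return Integer vector of cluster ids named by cell.
#' @export
cluster_snn <- function(sce, k = 20, resolution = 0.8, prune = 1 / 15,
                        seed = 42L) {
  coords <- if (methods::is(sce, "SingleCellExperiment")) {
    SingleCellExperiment::reducedDim(sce, "PCA")
  } else {
    as.matrix(sce)
  }
  n <- nrow(coords)
  nn <- knn_indices(coords, k)
  # SNN weights: Jaccard of neighbour sets for every kNN pair
  pairs_i <- rep(seq_len(n), each = k)
  pairs_j <- as.vector(t(nn))
  # symmetric closure so jaccard is computed once per unordered pair
  pi2 <- pmin(pairs_i, pairs_j)
  pj2 <- pmax(pairs_i, pairs_j)
  key <- unique(cbind(pi2, pj2)[pi2 != pj2, , drop = FALSE])
  nn_sets <- lapply(seq_len(n), function(i) nn[i, ])
  w <- vapply(seq_len(nrow(key)), function(r) {
    a <- nn_sets[[key[r, 1]]]
    b <- nn_sets[[key[r, 2]]]
    inter <- length(intersect(a, b))
    inter / (2 * k - inter)
  }, numeric(1))
  ok <- w >= prune
  g <- igraph::graph_from_data_frame(
    data.frame(from = key[ok, 1], to = key[ok, 2], weight = w[ok]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n))
  )
  comm <- with_seed(seed, {
    igraph::cluster_leiden(g, objective_function = "modularity",
                           resolution = resolution, n_iterations = 10)
  })
  memb <- igraph::membership(comm)
  memb <- memb[as.character(seq_len(n))]
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  out <- as.integer(relabel[as.character(memb)])
  names(out) <- rownames(coords)
  out
}

#' 2-D embedding of PC space
#'
#' UMAP embedding of the PCA coordinates, used for visualization only; no
#' downstream computation reads it. Deterministic at a fixed seed.
#'
#' @param sce A `SingleCellExperiment` with a `"PCA"` reducedDim, or a
#'   matrix.
#' @param seed Integer seed.
#' @param n_neighbors UMAP neighbourhood size.
#' @return Cells x 2 matrix of coordinates.
#' @export
embed_2d <- function(sce, seed = 42L, n_neighbors = 30) {
  coords <- if (methods::is(sce, "SingleCellExperiment")) {
    SingleCellExperiment::reducedDim(sce, "PCA")
  } else {
    as.matrix(sce)
  }
  emb <- with_seed(seed, {
    uwot::umap(coords, n_neighbors = min(n_neighbors, nrow(coords) - 1),
               n_threads = 1, n_sgd_threads = 1)
  })
  rownames(emb) <- rownames(coords)
  colnames(emb) <- c("UMAP1", "UMAP2")
  emb
}

#' Group composition table
#'
#' Tabulates, per group (cluster or pseudotime bin), the proportion of
#' cells from each dose (or any second label). Rows sum to 1; raw counts
#' are kept alongside.
#'
#' @param group Per-cell grouping labels.
#' @param of Per-cell composition labels (e.g., dose).
#' @return Data frame in long format: `group`, `of`, `n`, `proportion`.
#' @export
composition_table <- function(group, of) {
  assert_that(length(group) == length(of),
              "`group` and `of` must have the same length")
  assert_that(length(group) > 0, "empty grouping")
  tab <- table(group = group, of = of)
  assert_that(all(rowSums(tab) > 0), "empty group present")
  prop <- prop.table(tab, margin = 1)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df$proportion <- as.data.frame(prop)$Freq
  names(df)[names(df) == "Freq"] <- "n"
  df
}

#' Semantic labels for G0/G1-majority clusters
#'
#' Clusters whose majority phase is G0/G1 are ranked by their occupancy of
#' the highest dose. Clusters whose top-dose occupancy is at least
#' `enrichment` times the population-wide top-dose share are labeled
#' `senescent-like` (several clusters can qualify - the senotypes); among
#' the remaining G0/G1-majority clusters the lowest-occupancy one is
#' `quiescent-like` and the rest `transition`. Other clusters are
#' `cycling`. If no cluster passes the enrichment bar, the single
#' highest-occupancy G0/G1 cluster is called senescent-like. The rule can
#' be overridden by supplying explicit labels downstream.
#'
#' @param cluster Per-cell cluster ids.
#' @param phase Per-cell phase labels.
#' @param dose Per-cell dose labels.
#' @param high_dose The dose label treated as the top dose (default: the
#'   last unique value).
#' @param enrichment Occupancy enrichment factor for a senescent call.
#' @return Named character vector: cluster id -> semantic label.
#' @export
label_clusters <- function(cluster, phase, dose, high_dose = NULL,
                           enrichment = 1.5) {
  doses <- unique(dose)
  high_dose <- high_dose %||% doses[length(doses)]
  share <- mean(dose == high_dose)
  ids <- sort(unique(cluster))
  g0_major <- vapply(ids, function(cl) {
    mean(phase[cluster == cl] == "G0/G1") > 0.5
  }, logical(1))
  occupancy <- vapply(ids, function(cl) {
    mean(dose[cluster == cl] == high_dose)
  }, numeric(1))
  labels <- stats::setNames(rep("cycling", length(ids)), ids)
  g0_ids <- ids[g0_major]
  if (length(g0_ids) > 0) {
    occ <- occupancy[g0_major]
    sen <- occ >= enrichment * share
    if (!any(sen)) sen <- occ == max(occ)
    labels[as.character(g0_ids[sen])] <- "senescent-like"
    rest <- g0_ids[!sen]
    if (length(rest) > 0) {
      occ_rest <- occ[!sen]
      labels[as.character(rest)] <- "transition"
      labels[as.character(rest[which.min(occ_rest)])] <- "quiescent-like"
    }
  }
  labels
}
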
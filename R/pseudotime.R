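# Principal-graph pseudotime: minimum spanning tree over cluster centroids
# in PC space, cell projection onto tree edges, geodesic pseudotime from a
# root chosen next to the proliferating clusters, branch splitting, Loess
# score gradients and 0-1 rescaled heatmap matrices.

#' Learn a trajectory over a cell subset
#'
#' Builds the principal graph as the Euclidean minimum spanning tree of the
#' cluster centroids (in PC space) of the selected cells, projects every
#' selected cell onto the nearest point of the tree's edges, and measures
#' pseudotime as geodesic distance from the root projection. The root node
#' is the centroid nearest the reference point (by default the mean
#' centroid of the cycling clusters, i.e. the cells closest to
#' proliferation). The branch point is the first node beyond the root (by
#' tree distance) with degree > 2; cells projecting beyond it are labeled
#' `trajectory_1` or `trajectory_2`, cells before it `shared`. When a
#' per-cell `branch_marker` is supplied (e.g. DNA content, which flags the
#' mitotic-slip limb by its 4N cells), the subtree with the highest mean
#' marker becomes `trajectory_2` and every other subtree `trajectory_1`;
#' without a marker the largest subtree is `trajectory_1` and the rest
#' `trajectory_2`.
#'
#' @param sce A `SingleCellExperiment` with a `"PCA"` reducedDim, or a
#'   cells x dims coordinate matrix.
#' @param cells Selector for the cells to order (e.g. the G0/G1
#'   etoposide-treated subset).
#' @param clusters Per-cell cluster labels for **all** cells in `sce`
#'   (named, or in `sce` column order).
#' @param root_ref Either a numeric PC-space point used to pick the root
#'   centroid, a cluster id (its centroid becomes the root), or `NULL` with
#'   `cycling_cells` given.
#' @param cycling_cells Optional selector of proliferating cells whose mean
#'   PC position serves as `root_ref` when `root_ref` is `NULL`.
#' @param branch_marker Optional per-cell numeric (named by cell id, or in
#'   `sce` column order) used to name the branches; DNA content is the
#'   natural choice since mitotic-slip cells carry 4N genomes.
#' @return An object of class `"trajectory"`: list with `nodes` (centroid
#'   matrix), `edges` (data frame `from`, `to`, `length`), `root`,
#'   `branch_node` (or `NA`), and `cells` (data frame `cell_id`, `cluster`,
#'   `edge_from`, `edge_to`, `offset`, `pseudotime`, `branch`).
#' @export
learn_trajectory <- function(sce, cells, clusters, root_ref = NULL,
                             cycling_cells = NULL, branch_marker = NULL) {
  coords <- if (methods::is(sce, "SingleCellExperiment")) {
    SingleCellExperiment::reducedDim(sce, "PCA")
  } else {
    as.matrix(sce)
  }
  all_ids <- rownames(coords)
  if (!is.null(branch_marker) && is.null(names(branch_marker))) {
    assert_that(length(branch_marker) == nrow(coords),
                "unnamed `branch_marker` must cover every cell")
    names(branch_marker) <- all_ids
  }
  if (is.null(names(clusters))) {
    assert_that(length(clusters) == nrow(coords),
                "`clusters` must cover every cell")
    names(clusters) <- all_ids
  }
  cells <- if (is.character(cells)) cells else all_ids[cells]
  assert_that(length(cells) > 0, "empty cell subset")
  sub <- coords[cells, , drop = FALSE]
  cl <- as.character(clusters[cells])
  cl_ids <- sort(unique(cl))
  assert_that(length(cl_ids) >= 2,
              "trajectory needs at least 2 clusters in the subset")
  centroids <- t(vapply(cl_ids, function(k) {
    colMeans(sub[cl == k, , drop = FALSE])
  }, numeric(ncol(sub))))
  rownames(centroids) <- cl_ids

  # MST over centroids
  d <- as.matrix(stats::dist(centroids))
  g_full <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                                weighted = TRUE)
  tree <- igraph::mst(g_full)
  comp <- igraph::components(tree)
  if (comp$no > 1) {
    warning("centroid graph disconnected; using the largest component")
    keep <- names(comp$membership)[comp$membership ==
                                     which.max(comp$csize)]
    tree <- igraph::induced_subgraph(tree, keep)
    cl_ids <- keep
    centroids <- centroids[keep, , drop = FALSE]
    in_keep <- cl %in% keep
    cells <- cells[in_keep]
    sub <- sub[in_keep, , drop = FALSE]
    cl <- cl[in_keep]
  }
  el <- igraph::as_edgelist(tree)
  edge_len <- vapply(seq_len(nrow(el)), function(i) {
    sqrt(sum((centroids[el[i, 1], ] - centroids[el[i, 2], ])^2))
  }, numeric(1))
  edges <- data.frame(from = el[, 1], to = el[, 2], length = edge_len,
                      stringsAsFactors = FALSE)

  # root: centroid nearest the reference point
  if (is.null(root_ref)) {
    assert_that(!is.null(cycling_cells),
                "supply `root_ref` or `cycling_cells`")
    cyc <- if (is.character(cycling_cells)) cycling_cells else
      all_ids[cycling_cells]
    root_ref <- colMeans(coords[cyc, , drop = FALSE])
  }
  if (length(root_ref) == 1 && as.character(root_ref) %in% cl_ids) {
    root <- as.character(root_ref)
  } else {
    dd <- vapply(cl_ids, function(k) {
      sqrt(sum((centroids[k, ] - root_ref)^2))
    }, numeric(1))
    root <- cl_ids[which.min(dd)]
  }

  # project each cell onto the nearest point of any tree edge
  proj <- project_cells_on_edges(sub, centroids, edges)

  # geodesic node distances from root
  node_dist <- igraph::distances(tree, v = root, weights =
                                   igraph::E(tree)$weight)[1, ]
  pt <- pmin(node_dist[proj$from] + proj$offset,
             node_dist[proj$to] + (proj$len - proj$offset))

  # branch point: nearest node to the root (by tree distance) with
  # degree > 2
  deg <- igraph::degree(tree)
  branch_candidates <- names(deg)[deg > 2]
  branch_node <- NA_character_
  branch <- rep("shared", length(cells))
  if (length(branch_candidates) > 0) {
    branch_node <- branch_candidates[
      which.min(node_dist[branch_candidates])]
    # subtrees hanging off the branch node, excluding the root side
    nb <- igraph::neighbors(tree, branch_node)$name
    path_to_root <- igraph::shortest_paths(
      tree, from = branch_node, to = root)$vpath[[1]]$name
    root_side <- if (length(path_to_root) > 1) path_to_root[2] else NULL
    sub_roots <- setdiff(nb, root_side)
    cut_tree <- igraph::delete_vertices(tree, branch_node)
    cmp <- igraph::components(cut_tree)$membership
    subtree_nodes <- lapply(sub_roots, function(r) {
      names(cmp)[cmp == cmp[[r]]]
    })
    # a cell belongs to a subtree when its projection edge has at least
    # one endpoint strictly inside the subtree
    on_subtree <- lapply(subtree_nodes, function(nodes) {
      proj$from %in% nodes | proj$to %in% nodes
    })
    if (!is.null(branch_marker)) {
      mk <- vapply(on_subtree, function(on) {
        mean(branch_marker[cells[on]], na.rm = TRUE)
      }, numeric(1))
      two <- which.max(mk)
    } else {
      n_cells_sub <- vapply(on_subtree, sum, numeric(1))
      two <- which(n_cells_sub != max(n_cells_sub))
      if (length(two) == 0) two <- length(on_subtree)
    }
    for (i in seq_along(subtree_nodes)) {
      lbl <- if (i %in% two) "trajectory_2" else "trajectory_1"
      branch[on_subtree[[i]]] <- lbl
    }
  }
  structure(list(
    nodes = centroids,
    edges = edges,
    root = root,
    branch_node = branch_node,
    cells = data.frame(cell_id = cells, cluster = cl,
                       edge_from = proj$from, edge_to = proj$to,
                       offset = proj$offset, pseudotime = unname(pt),
                       branch = branch, stringsAsFactors = FALSE)
  ), class = "trajectory")
}

#' @noRd
project_cells_on_edges <- function(sub, centroids, edges) {
  n <- nrow(sub)
  best <- list(dist = rep(Inf, n), from = character(n), to = character(n),
               offset = numeric(n), len = numeric(n))
  for (i in seq_len(nrow(edges))) {
    a <- centroids[edges$from[i], ]
    b <- centroids[edges$to[i], ]
    ab <- b - a
    len2 <- sum(ab^2)
    diff <- sweep(sub, 2, a)
    t_par <- pmin(pmax(as.vector(diff %*% ab) / len2, 0), 1)
    proj_pts <- outer(t_par, ab) + rep(a, each = n)
    dd <- rowSums((sub - proj_pts)^2)
    better <- dd < best$dist
    best$dist[better] <- dd[better]
    best$from[better] <- edges$from[i]
    best$to[better] <- edges$to[i]
    best$offset[better] <- t_par[better] * sqrt(len2)
    best$len[better] <- sqrt(len2)
  }
  best
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges,",
      nrow(x$cells), "cells\n")
  cat("root:", x$root, " branch node:", x$branch_node, "\n")
  print(table(x$cells$branch))
  invisible(x)
}

#' Loess fit of scores over pseudotime
#'
#' Local weighted regression with tricube weights over the span-nearest
#' neighbours, evaluated on a grid. Deterministic. With `span = 1` and
#' `degree = 1` each grid value equals one global tricube-weighted least
#' squares fit.
#'
#' @param x,y Numeric vectors (e.g. pseudotime and score).
#' @param span Neighbourhood fraction in (0, 1].
#' @param degree Local polynomial degree (0, 1 or 2).
#' @param grid Evaluation points (default: 100 equally spaced points over
#'   the range of `x`).
#' @return List with `grid` and `fitted`.
#' @export
loess_fit <- function(x, y, span = 0.3, degree = 1, grid = NULL) {
  assert_that(length(x) == length(y), "`x` and `y` lengths differ")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  assert_that(length(x) >= max(3, degree + 1), "too few points")
  assert_that(span > 0 && span <= 1, "`span` must lie in (0, 1]")
  assert_that(stats::sd(x) > 0, "all x values identical")
  grid <- grid %||% seq(min(x), max(x), length.out = 100)
  fit <- stats::loess(y ~ x, span = span, degree = degree,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  fitted <- stats::predict(fit, data.frame(x = grid))
  list(grid = grid, fitted = as.numeric(fitted))
}

#' Rescale to the unit interval
#'
#' `(v - min) / (max - min)`; a constant input returns all zeros with the
#' attribute `degenerate = TRUE`. Idempotent on non-degenerate input.
#'
#' @param values Finite numeric vector.
#' @return Rescaled vector with attribute `degenerate`.
#' @export
rescale_unit <- function(values) {
  assert_that(length(values) > 0, "empty input")
  assert_that(all(is.finite(values)), "non-finite values")
  rng <- range(values)
  if (rng[1] == rng[2]) {
    return(structure(rep(0, length(values)), degenerate = TRUE))
  }
  structure((values - rng[1]) / (rng[2] - rng[1]), degenerate = FALSE)
}

#' Pathway-group score matrices over pseudotime
#'
#' For each gene group: module score per cell, Loess fit against
#' pseudotime separately per branch (each branch pools its own cells with
#' the pre-branch `shared` cells), then 0-1 rescaling. Rows are ordered by
#' the position of the fitted maximum on the first branch. Groups with no
#' genes in the matrix are skipped with a warning.
#'
#' @param sce A `SingleCellExperiment` with `logcounts`.
#' @param trajectory A [learn_trajectory()] result.
#' @param groups Named list of gene-id vectors.
#' @param span,degree,grid_n Loess parameters.
#' @param n_bins,n_ctrl,seed Module-score parameters.
#' @return Named list (one per branch: `trajectory_1`, `trajectory_2` when
#'   present, else `shared`): matrices groups x grid of rescaled fitted
#'   scores, with attributes `"grid"`, `"degenerate"` (flagging constant
#'   rows) and `"fitted_raw"` (the un-rescaled Loess fits, for comparing
#'   peak heights across branches).
#' @export
pathway_heatmap_matrix <- function(sce, trajectory, groups, span = 0.3,
                                   degree = 1, grid_n = 100, n_bins = 24,
                                   n_ctrl = 100, seed = 42L) {
  cells_df <- trajectory$cells
  branches <- intersect(c("trajectory_1", "trajectory_2"),
                        unique(cells_df$branch))
  if (length(branches) == 0) branches <- "shared"
  scores <- list()
  kept <- character(0)
  for (nm in names(groups)) {
    genes <- intersect(groups[[nm]], rownames(sce))
    if (length(genes) == 0) {
      warning("group '", nm, "' has no genes in the matrix; skipped")
      next
    }
    scores[[nm]] <- module_score(sce, genes, n_bins = n_bins,
                                 n_ctrl = n_ctrl, seed = seed)
    kept <- c(kept, nm)
  }
  assert_that(length(kept) > 0, "no scorable groups")
  out <- list()
  for (br in branches) {
    use <- cells_df$branch %in% c("shared", br)
    pt <- cells_df$pseudotime[use]
    ids <- cells_df$cell_id[use]
    grid <- seq(min(pt), max(pt), length.out = grid_n)
    mat <- matrix(NA_real_, nrow = length(kept), ncol = grid_n,
                  dimnames = list(kept, NULL))
    raw <- mat
    degen <- logical(length(kept))
    names(degen) <- kept
    for (i in seq_along(kept)) {
      fit <- loess_fit(pt, scores[[kept[i]]][ids], span = span,
                       degree = degree, grid = grid)
      raw[i, ] <- fit$fitted
      r <- rescale_unit(fit$fitted)
      mat[i, ] <- r
      degen[i] <- isTRUE(attr(r, "degenerate"))
    }
    ord <- order(apply(mat, 1, which.max))
    mat <- mat[ord, , drop = FALSE]
    attr(mat, "grid") <- grid
    attr(mat, "degenerate") <- degen[ord]
    attr(mat, "fitted_raw") <- raw[ord, , drop = FALSE]
    out[[br]] <- mat
  }
  out
}
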
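test_that("collinear centroids give additive pseudotime", {
  # three clusters on a line at x = 0, 3, 8; cells exactly at centroids
  coords <- rbind(matrix(rep(c(0, 0), each = 10), 10, 2),
                  matrix(rep(c(3, 0), each = 10), 10, 2),
                  matrix(rep(c(8, 0), each = 10), 10, 2))
  rownames(coords) <- sprintf("c%02d", 1:30)
  clusters <- rep(c("A", "B", "C"), each = 10)
  names(clusters) <- rownames(coords)
  tr <- learn_trajectory(coords, rownames(coords), clusters,
                         root_ref = c(0, 0))
  expect_equal(tr$root, "A")
  pt <- tr$cells$pseudotime
  expect_equal(unname(pt[1:10]), rep(0, 10), tolerance = 1e-10)
  expect_equal(unname(pt[11:20]), rep(3, 10), tolerance = 1e-10)
  expect_equal(unname(pt[21:30]), rep(8, 10), tolerance = 1e-10)
  expect_true(all(tr$cells$branch == "shared"))
  expect_true(is.na(tr$branch_node))
})

test_that("a Y-shaped layout splits into consistent branch labels", {
  set.seed(91)
  # root -> stem -> fork into two arms
  mk <- function(center, n = 25) {
    sweep(matrix(rnorm(n * 2, sd = 0.1), n, 2), 2, center, "+")
  }
  coords <- rbind(mk(c(0, 0)), mk(c(4, 0)),
                  mk(c(8, 3)), mk(c(8, -3)),
                  mk(c(12, 5)), mk(c(12, -5)))
  rownames(coords) <- sprintf("c%03d", 1:150)
  clusters <- rep(c("root", "stem", "up1", "dn1", "up2", "dn2"),
                  each = 25)
  names(clusters) <- rownames(coords)
  tr <- learn_trajectory(coords, rownames(coords), clusters,
                         root_ref = c(0, 0))
  expect_equal(tr$root, "root")
  expect_equal(tr$branch_node, "stem")
  cells <- tr$cells
  up <- cells$cluster %in% c("up1", "up2")
  dn <- cells$cluster %in% c("dn1", "dn2")
  expect_equal(length(unique(cells$branch[up])), 1)
  expect_equal(length(unique(cells$branch[dn])), 1)
  expect_true(unique(cells$branch[up]) != unique(cells$branch[dn]))
  expect_true(all(cells$branch[cells$cluster == "root"] == "shared"))
  # branch labels start exactly at the fork: every branch-labeled cell
  # projects at or beyond the branch node, every shared cell before it
  d_branch <- sqrt(sum((tr$nodes["stem", ] - tr$nodes["root", ])^2))
  expect_true(all(cells$pseudotime[cells$branch != "shared"] >=
                    d_branch - 0.2))
  expect_true(all(cells$pseudotime[cells$branch == "shared"] <=
                    d_branch + 0.2))
  # pseudotime nondecreasing along each root-to-leaf path
  mean_pt <- tapply(cells$pseudotime, cells$cluster, mean)
  expect_true(mean_pt["root"] < mean_pt["stem"])
  expect_true(mean_pt["stem"] < mean_pt["up1"])
  expect_true(mean_pt["up1"] < mean_pt["up2"])
})

test_that("a branch marker names the high-marker arm trajectory_2", {
  set.seed(93)
  mk <- function(center, n = 20) {
    sweep(matrix(rnorm(n * 2, sd = 0.1), n, 2), 2, center, "+")
  }
  coords <- rbind(mk(c(0, 0)), mk(c(4, 0)), mk(c(8, 3)), mk(c(8, -3)))
  rownames(coords) <- sprintf("c%03d", 1:80)
  clusters <- rep(c("root", "stem", "arm_up", "arm_dn"), each = 20)
  names(clusters) <- rownames(coords)
  marker <- c(rep(2, 40), rep(2, 20), rep(4, 20))   # arm_dn is 4N
  names(marker) <- rownames(coords)
  tr <- learn_trajectory(coords, rownames(coords), clusters,
                         root_ref = c(0, 0), branch_marker = marker)
  cells <- tr$cells
  expect_true(all(cells$branch[cells$cluster == "arm_dn"] ==
                    "trajectory_2"))
  expect_true(all(cells$branch[cells$cluster == "arm_up"] ==
                    "trajectory_1"))
})

test_that("pseudotime is invariant to rigid rotation of PC space", {
  set.seed(97)
  coords <- rbind(matrix(rnorm(40, sd = 0.2), 20, 2),
                  matrix(rnorm(40, mean = 3, sd = 0.2), 20, 2),
                  matrix(rnorm(40, mean = 6, sd = 0.2), 20, 2))
  rownames(coords) <- sprintf("c%02d", 1:60)
  clusters <- rep(c("A", "B", "C"), each = 20)
  names(clusters) <- rownames(coords)
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  r1 <- learn_trajectory(coords, rownames(coords), clusters,
                         root_ref = c(0, 0))
  r2 <- learn_trajectory(coords %*% rot, rownames(coords), clusters,
                         root_ref = c(0, 0) %*% rot)
  expect_equal(r1$cells$pseudotime, r2$cells$pseudotime,
               tolerance = 1e-8)
})

test_that("trajectory requires at least two clusters", {
  coords <- matrix(rnorm(20), 10, 2)
  rownames(coords) <- sprintf("c%02d", 1:10)
  cl <- setNames(rep("only", 10), rownames(coords))
  expect_error(learn_trajectory(coords, rownames(coords), cl,
                                root_ref = c(0, 0)), "at least 2")
})

test_that("loess_fit reproduces exact lines and constants", {
  x <- seq(0, 1, length.out = 40)
  grid <- seq(0.05, 0.95, length.out = 10)
  fit <- loess_fit(x, 2 * x, span = 0.5, degree = 1, grid = grid)
  expect_equal(fit$fitted, 2 * grid, tolerance = 1e-10)
  fitc <- loess_fit(x, rep(3.5, 40), span = 0.4, degree = 1,
                    grid = grid)
  expect_equal(fitc$fitted, rep(3.5, 10), tolerance = 1e-10)
  expect_error(loess_fit(rep(1, 10), rnorm(10)), "identical")
  expect_error(loess_fit(x, 2 * x, span = 1.5), "span")
})

test_that("loess at span 1 equals the direct WLS oracle everywhere", {
  set.seed(101)
  x <- sort(runif(60))
  y <- sin(2 * pi * x) + rnorm(60, sd = 0.1)
  grid <- seq(min(x), max(x), length.out = 25)
  for (deg in c(1, 2)) {
    fit <- loess_fit(x, y, span = 1, degree = deg, grid = grid)
    oracle <- vapply(grid, function(x0) {
      oracle_wls_tricube(x, y, x0, span = 1, degree = deg)
    }, numeric(1))
    expect_equal(fit$fitted, oracle, tolerance = 1e-9)
  }
})

test_that("rescale_unit maps, flags and is idempotent", {
  expect_equal(as.numeric(rescale_unit(c(2, 4, 6))), c(0, 0.5, 1))
  flat <- rescale_unit(c(5, 5, 5))
  expect_equal(as.numeric(flat), c(0, 0, 0))
  expect_true(attr(flat, "degenerate"))
  v <- rnorm(20)
  once <- rescale_unit(v)
  twice <- rescale_unit(as.numeric(once))
  expect_equal(as.numeric(once), as.numeric(twice), tolerance = 1e-12)
  expect_error(rescale_unit(numeric(0)), "empty")
  expect_error(rescale_unit(c(1, NA)), "finite")
})

test_that("pathway heatmap rows are unit-scaled with graded fits", {
  proc <- get_small_processed()
  cl <- cluster_snn(proc$m, k = 15, resolution = 0.8, seed = 42)
  subset_cells <- colnames(proc$m)[proc$truth$branch != "cycling" &
                                     proc$truth$dose != "UT"]
  cyc <- colnames(proc$m)[proc$truth$branch == "cycling"]
  marker <- setNames(proc$truth$dna_content, colnames(proc$m))
  tr <- learn_trajectory(proc$m, subset_cells, cl, cycling_cells = cyc,
                         branch_marker = marker)
  groups <- list(
    up = proc$genes$gene_id[proc$genes$program == "pan_senescence"],
    down = proc$genes$gene_id[proc$genes$program == "biosynthesis"],
    absent = c("none1", "none2"))
  expect_warning(hm <- pathway_heatmap_matrix(proc$m, tr, groups,
                                              grid_n = 40, seed = 42),
                 "no genes")
  for (br in names(hm)) {
    mat <- hm[[br]]
    expect_false("absent" %in% rownames(mat))
    for (r in rownames(mat)) {
      expect_equal(min(mat[r, ]), 0)
      expect_equal(max(mat[r, ]), 1)
    }
    raw <- attr(mat, "fitted_raw")
    # planted graded programs: fitted up-row increases overall, down-row
    # decreases overall along the branch
    expect_gt(raw["up", ncol(raw)], raw["up", 1])
    expect_lt(raw["down", ncol(raw)], raw["down", 1])
  }
})
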
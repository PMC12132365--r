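test_that("module_score matches the seeded brute-force oracle", {
  set.seed(31)
  counts <- matrix(rpois(20 * 30, lambda = rep(seq(2, 40, 2), 30)),
                   20, 30)
  sce <- log_normalize(make_sce(counts))
  genes <- rownames(sce)[c(3, 7, 12)]
  for (seed in c(1L, 42L, 99L)) {
    got <- module_score(sce, genes, n_bins = 4, n_ctrl = 3, seed = seed)
    want <- oracle_module_score(sce, genes, n_bins = 4, n_ctrl = 3,
                                seed = seed)
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }
})

test_that("module_score identities: identical profiles and exact shifts", {
  # all genes share one expression profile -> score ~ 0 everywhere
  profile <- seq(1, 5, length.out = 25)
  x <- matrix(rep(profile, each = 40), 40, 25)
  sce <- make_sce(matrix(1L, 40, 25))
  SummarizedExperiment::assay(sce, "logcounts",
                              withDimnames = FALSE) <- x
  s <- module_score(sce, rownames(sce)[1:5], n_bins = 2, n_ctrl = 10,
                    seed = 1)
  expect_lt(max(abs(s)), 1e-10)
  # set genes exceed every same-bin gene by exactly c -> score = c
  x2 <- x
  x2[1:5, ] <- x2[1:5, ] + 0.75
  sce2 <- make_sce(matrix(1L, 40, 25))
  SummarizedExperiment::assay(sce2, "logcounts",
                              withDimnames = FALSE) <- x2
  s2 <- module_score(sce2, rownames(sce2)[1:5], n_bins = 1, n_ctrl = 50,
                     seed = 1)
  expect_equal(unname(s2), rep(0.75, 25), tolerance = 1e-12)
})

test_that("module_score is invariant to gene order and errors on misses", {
  proc <- get_small_processed()
  genes <- rownames(proc$m)[51:70]
  a <- module_score(proc$m, genes, seed = 7)
  b <- module_score(proc$m, rev(genes), seed = 7)
  expect_identical(a, b)
  expect_error(module_score(proc$m, c("nope1", "nope2")),
               "none of the set genes")
})

test_that("assign_phase follows the score rules and the G0/G1 default", {
  # build expression where cell1 expresses only S genes, cell2 only G2M,
  # cell3 neither
  x <- matrix(0, 30, 3)
  x[1:5, 1] <- 3     # S genes high in cell 1
  x[6:10, 2] <- 3    # G2M genes high in cell 2
  x[11:30, ] <- 1    # background
  sce <- make_sce(matrix(1L, 30, 3))
  SummarizedExperiment::assay(sce, "logcounts",
                              withDimnames = FALSE) <- x
  ph <- assign_phase(sce, rownames(sce)[1:5], rownames(sce)[6:10],
                     n_bins = 1, n_ctrl = 30, seed = 1)
  expect_identical(ph$phase, c("S", "G2M", "G0/G1"))
  # both scores <= 0 -> G0/G1, and labels partition all cells
  expect_true(all(ph$phase %in% c("S", "G2M", "G0/G1")))
})

test_that("phase recovery on planted programs exceeds 90%", {
  proc <- get_small_processed()
  s_genes <- proc$genes$gene_id[proc$genes$program == "s_phase"]
  g2m_genes <- proc$genes$gene_id[proc$genes$program == "g2m_phase"]
  ph <- assign_phase(proc$m, s_genes, g2m_genes, seed = 42)
  expect_gt(mean(ph$phase == proc$truth$phase), 0.9)
})

test_that("cluster_snn separates well-separated blobs exactly", {
  set.seed(13)
  blob1 <- matrix(rnorm(60 * 5), 60, 5)
  blob2 <- matrix(rnorm(60 * 5), 60, 5)
  blob2[, 1] <- blob2[, 1] + 20   # 20 sigma apart
  coords <- rbind(blob1, blob2)
  rownames(coords) <- sprintf("c%03d", 1:120)
  cl <- cluster_snn(coords, k = 20, resolution = 0.8, seed = 42)
  expect_equal(length(unique(cl)), 2)
  expect_equal(length(unique(cl[1:60])), 1)
  expect_equal(length(unique(cl[61:120])), 1)
  expect_true(cl[1] != cl[61])
})

test_that("cluster_snn is deterministic and order-equivariant", {
  set.seed(17)
  coords <- rbind(matrix(rnorm(50 * 4), 50, 4),
                  matrix(rnorm(50 * 4, mean = 12), 50, 4))
  rownames(coords) <- sprintf("c%03d", 1:100)
  a <- cluster_snn(coords, k = 8, seed = 7)
  b <- cluster_snn(coords, k = 8, seed = 7)
  expect_identical(a, b)
  perm <- sample(100)
  cp <- cluster_snn(coords[perm, ], k = 8, seed = 7)
  # same partition up to relabeling
  expect_equal(mclust::adjustedRandIndex(a[perm], cp), 1)
  expect_error(cluster_snn(coords, k = 100), "smaller than")
})

test_that("cluster ids are relabeled by decreasing size", {
  set.seed(19)
  coords <- rbind(matrix(rnorm(80 * 3), 80, 3),
                  matrix(rnorm(30 * 3, mean = 15), 30, 3))
  rownames(coords) <- sprintf("c%03d", 1:110)
  cl <- cluster_snn(coords, k = 8, seed = 3)
  sizes <- table(cl)
  expect_true(all(diff(as.integer(sizes)) <= 0))
  expect_equal(names(sizes)[1], "1")
})

test_that("embed_2d is finite, shaped, seeded, and separates blobs", {
  set.seed(23)
  coords <- rbind(matrix(rnorm(60 * 6), 60, 6),
                  matrix(rnorm(60 * 6, mean = 25), 60, 6))
  rownames(coords) <- sprintf("c%03d", 1:120)
  e1 <- embed_2d(coords, seed = 11)
  expect_equal(dim(e1), c(120L, 2L))
  expect_true(all(is.finite(e1)))
  e2 <- embed_2d(coords, seed = 11)
  expect_identical(e1, e2)
  # blob separation: centroid gap exceeds within-blob 95th percentile
  c1 <- colMeans(e1[1:60, ]); c2 <- colMeans(e1[61:120, ])
  gap <- sqrt(sum((c1 - c2)^2))
  r1 <- quantile(sqrt(rowSums((e1[1:60, ] -
                                 rep(c1, each = 60))^2)), 0.95)
  r2 <- quantile(sqrt(rowSums((e1[61:120, ] -
                                 rep(c2, each = 60))^2)), 0.95)
  expect_gt(gap, max(r1, r2))
})

test_that("composition_table proportions are exact and rows sum to one", {
  tab <- composition_table(group = c(1, 1, 1, 1),
                           of = c("UT", "UT", "UT", "tx"))
  expect_equal(sort(tab$proportion), c(0.25, 0.75))
  expect_equal(sum(tab$n), 4)
  set.seed(3)
  g <- sample(1:5, 200, replace = TRUE)
  d <- sample(c("a", "b", "c"), 200, replace = TRUE)
  tab2 <- composition_table(g, d)
  sums <- tapply(tab2$proportion, tab2$group, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_error(composition_table(integer(0), character(0)), "empty")
})

test_that("senotype clusters are recovered among senescent cells", {
  proc <- get_small_processed()
  cl <- cluster_snn(proc$m, k = 15, resolution = 0.8, seed = 42)
  sen <- !is.na(proc$truth$senotype)
  ari <- mclust::adjustedRandIndex(cl[sen], proc$truth$senotype[sen])
  expect_gte(ari, 0.7)
})

test_that("label_clusters marks dose-enriched arrested clusters", {
  cluster <- rep(1:3, each = 100)
  phase <- rep("G0/G1", 300)
  phase[cluster == 1] <- sample(c("S", "G2M"), 100, replace = TRUE)
  dose <- c(rep("UT", 100),                       # cycling cluster
            rep(c("UT", "d25"), c(90, 10)),       # arrested, low dose
            rep(c("UT", "d25"), c(20, 80)))       # arrested, high dose
  lab <- label_clusters(cluster, phase, dose, high_dose = "d25")
  expect_equal(unname(lab["1"]), "cycling")
  expect_equal(unname(lab["2"]), "quiescent-like")
  expect_equal(unname(lab["3"]), "senescent-like")
})
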
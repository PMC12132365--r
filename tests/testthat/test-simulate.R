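test_that("simulate_counts is deterministic and shape-correct", {
  p <- continuum_params(n_cells_per_dose = c(UT = 40, dose_25 = 40),
                        n_genes = 400, n_senotype = 15,
                        n_biosynthesis = 15, seed = 9)
  a <- simulate_counts(p)
  b <- simulate_counts(p)
  expect_identical(as.matrix(SummarizedExperiment::assay(a$matrix)),
                   as.matrix(SummarizedExperiment::assay(b$matrix)))
  expect_identical(a$cell_truth, b$cell_truth)
  expect_equal(dim(a$matrix), c(400L, 80L))
  expect_equal(nrow(a$cell_truth), 80L)
  counts <- SummarizedExperiment::assay(a$matrix, "counts")
  expect_true(all(counts@x >= 0) && all(counts@x == round(counts@x)))
})

test_that("ground truth is internally consistent", {
  sim <- get_small_sim()
  tt <- sim$cell_truth
  p <- sim$params
  expect_true(all((tt$branch == "cycling") ==
                    (tt$depth < p$cycling_cutoff)))
  expect_true(all(tt$depth >= 0 & tt$depth <= 1))
  sen <- !is.na(tt$senotype)
  expect_true(all(tt$depth[sen] >= p$senescence_cutoff))
  expect_true(all(tt$senotype[tt$branch == "slip_path" & sen] ==
                    "senotype_slip"))
  # slip cells carry the 4N proxy
  expect_gt(mean(tt$dna_content[tt$branch == "slip_path"]), 3.5)
  expect_lt(mean(tt$dna_content[tt$branch == "g0_path"]), 2.5)
  # phase labels only in cycling cells
  expect_true(all(tt$phase[tt$branch != "cycling"] == "G0/G1"))
})

test_that("zero effect sizes remove all depth structure", {
  p <- continuum_params(n_cells_per_dose = c(UT = 300, dose_25 = 300),
                        n_genes = 300, n_senotype = 10,
                        n_biosynthesis = 10, effect_scale = 0,
                        frac_high_mito = 0, frac_low_lib = 0, seed = 4)
  sim <- simulate_counts(p)
  counts <- as.matrix(SummarizedExperiment::assay(sim$matrix))
  depth <- sim$cell_truth$depth
  lib <- sim$cell_truth$lib_factor
  # per-gene slope of normalized expression vs depth ~ 0: test the mean
  # count ratio deep vs shallow for the planted program genes
  rel <- sweep(counts, 2, lib, "/")
  deep <- depth > stats::median(depth)
  prog <- sim$gene_truth$program == "pan_senescence"
  ratio <- rowMeans(rel[prog, deep]) / rowMeans(rel[prog, !deep])
  expect_true(all(abs(log(ratio)) < 0.35))
  expect_lt(abs(mean(log(ratio))), 0.08)
})

test_that("a planted +2 log-mean effect reproduces e^2 in empirical means", {
  p <- continuum_params(
    n_cells_per_dose = c(UT = 1000, dose_25 = 1000), n_genes = 300,
    n_senotype = 10, n_biosynthesis = 10,
    effect_phase = 0, effect_pan = 0, effect_senotype = 0,
    effect_sasp = 0, effect_quiescence = 0, effect_biosynthesis = 0,
    effect_phase_off = 0, effect_cycle_repression = 0,
    frac_high_mito = 0, frac_low_lib = 0,
    extra_programs = list(list(genes = "g0290", effect = 2,
                               depth_min = 0.5)),
    seed = 8)
  sim <- simulate_counts(p)
  counts <- as.matrix(SummarizedExperiment::assay(sim$matrix))
  tt <- sim$cell_truth
  rel <- sweep(counts, 2, tt$lib_factor, "/")
  hi <- tt$depth > 0.5
  ratio <- mean(rel["g0290", hi]) / mean(rel["g0290", !hi])
  expect_equal(log(ratio), 2, tolerance = 0.15)
})

test_that("marginal counts match the generating NB moments", {
  p <- continuum_params(n_cells_per_dose = c(UT = 1000, dose_25 = 1000),
                        n_genes = 400, n_senotype = 10,
                        n_biosynthesis = 10, effect_scale = 0,
                        frac_high_mito = 0, frac_low_lib = 0,
                        library_size_lognormal = c(0, 0), seed = 6)
  sim <- simulate_counts(p)
  counts <- as.matrix(SummarizedExperiment::assay(sim$matrix))
  mu <- rowMeans(counts)
  v <- apply(counts, 1, stats::var)
  # NB: var = mu + phi mu^2 with phi in [0.1, 1]; at n = 2000 the
  # empirical dispersion should land inside a generous band
  keep <- mu > 1
  phi_hat <- (v[keep] - mu[keep]) / mu[keep]^2
  expect_gt(mean(phi_hat > 0.05), 0.95)
  expect_gt(mean(phi_hat < 1.6), 0.95)
  expect_lt(abs(mean(log(pmax(phi_hat, 1e-3))) -
                  mean(log(c(0.1, 1)))), 1.5)
})

test_that("planted monotone programs are monotone in latent depth", {
  sim <- get_small_sim()
  counts <- as.matrix(SummarizedExperiment::assay(sim$matrix))
  tt <- sim$cell_truth
  rel <- sweep(counts, 2, colSums(counts), "/")
  arrested <- tt$branch != "cycling"
  pan <- sim$gene_truth$program == "pan_senescence"
  bio <- sim$gene_truth$program == "biosynthesis"
  rho_pan <- apply(rel[pan, arrested], 1, function(x) {
    stats::cor(x, tt$depth[arrested], method = "spearman")
  })
  rho_bio <- apply(rel[bio, arrested], 1, function(x) {
    stats::cor(x, tt$depth[arrested], method = "spearman")
  })
  # sign test: essentially all planted up-genes correlate positively and
  # down-genes negatively with depth
  expect_gt(mean(rho_pan > 0), 0.95)
  expect_gt(mean(rho_bio < 0), 0.95)
})

test_that("CDK2 trace generator honours its construction rules", {
  pure_sen <- simulate_traces(50, c(0, 0, 1), noise_sd = 0, seed = 1)
  expect_true(all(pure_sen$traces$values < 0.8))
  expect_true(all(pure_sen$truth$behavior == "senescent"))
  pure_fast <- simulate_traces(50, c(1, 0, 0), noise_sd = 0, seed = 1)
  dur <- cdk2_low_duration(pure_fast$traces, 0.8)
  expect_true(all(dur < 12))
  expect_error(simulate_traces(10, c(0.5, 0.2, 0.2)), "sum to 1")
  # determinism
  a <- simulate_traces(20, c(0.3, 0.3, 0.4), noise_sd = 0.05, seed = 7)
  b <- simulate_traces(20, c(0.3, 0.3, 0.4), noise_sd = 0.05, seed = 7)
  expect_identical(a$traces$values, b$traces$values)
})

test_that("reporter trace generator is linear with exact slopes", {
  sim <- simulate_reporter_traces(30, c(slow = 0.10, senescent = 0.02),
                                  induction_frame = 20, n_frames = 100,
                                  noise_sd = 0, seed = 3)
  sl <- reporter_slope(sim$traces, fit_window = 25:60)
  expect_equal(sl$slope_per_frame, sim$truth$slope_per_frame,
               tolerance = 1e-10)
  # slope 0 stays at the baseline
  flat <- simulate_reporter_traces(5, c(none = 0), induction_frame = 10,
                                   n_frames = 50, noise_sd = 0, seed = 1)
  norm <- flat$traces$values / rowMeans(flat$traces$values[, 1:10])
  expect_true(all(abs(norm - 1) < 1e-12))
  expect_error(simulate_reporter_traces(5, c(bad = -0.1)),
               "negative slopes")
  expect_error(simulate_reporter_traces(5, c(a = 0.1),
                                        induction_frame = 200),
               "inside the trace window")
})
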
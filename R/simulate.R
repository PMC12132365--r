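# Synthetic single-cell data with a planted quiescence-senescence continuum.
#
# The generator emulates the study design: four etoposide dose conditions
# (untreated, 2.5, 10, 25 uM) whose cells sit at different depths of a latent
# cell-cycle-withdrawal continuum d in [0, 1]; a branch structure (the
# dominant mitosis-to-G0 path versus the rarer mitotic-slip path, the latter
# carrying a 4N DNA-content proxy); three senotype expression programs among
# the deep-arrest cells; graded p21-like pan-senescence and SASP programs;
# cell-cycle phase programs in cycling cells; and negative-binomial counts
# with gene-specific dispersion on top of log-normal library sizes.

#' Parameters for the synthetic continuum generator
#'
#' The defaults define the simulated study: 500 cells per dose (2,000 total)
#' over 1,500 genes, dose-dependent cycling fractions and arrest-depth
#' distributions, dose-dependent mitotic-slip fractions, three senotype
#' programs of 60 genes each, 40 graded pan-senescence markers, 30 universal
#' and 20 slip-branch-specific SASP genes, 25 quiescence-only genes, and a
#' 60-gene biosynthesis program that declines with arrest depth.
#'
#' @param n_cells_per_dose Named positive integers, cells per dose label.
#' @param n_genes Total genes in the universe (includes `n_mito` MT- genes).
#' @param cycling_prob Per-dose probability that a cell is actively cycling
#'   (latent depth below `cycling_cutoff`).
#' @param depth_shape1,depth_shape2 Per-dose Beta shapes for the arrested
#'   cells' depth above `cycling_cutoff` (higher dose = deeper arrest).
#' @param slip_fraction Per-dose probability that an arrested cell took the
#'   mitotic-slip branch rather than the mitosis-to-G0 branch.
#' @param cycling_cutoff Depth below which a cell is cycling. Fixed by the
#'   generator, not the analyst.
#' @param senescence_cutoff Depth at or above which an arrested cell carries
#'   a senotype label (ground-truth senescent).
#' @param senotype_depth_split Depth boundary between the two
#'   mitosis-to-G0 senotypes: G0-path senescent cells below it are
#'   senotype A, at or above it senotype B (the senotype programs have
#'   depth-activation ranges, so the deep-arrest senotypes tile the
#'   continuum).
#' @param n_mito,n_s,n_g2m,n_pan,n_sasp_universal,n_sasp_branch,n_quiescence,n_senotype,n_biosynthesis
#'   Sizes of the planted gene programs.
#' @param effect_phase,effect_pan,effect_senotype,effect_sasp,effect_quiescence,effect_biosynthesis
#'   Program effect sizes on the natural-log NB mean. The quiescence-only
#'   effect is deliberately weak: shallow-arrest cells carry no strong
#'   unique program, only attenuated senescence changes plus this faint
#'   module.
#' @param effect_phase_off Out-of-phase trough of the S and G2/M programs:
#'   phase genes peak in their own phase and are strongly repressed in every
#'   other cell, mirroring cyclin-like dynamics where out-of-phase markers
#'   are near-undetectable in droplet data.
#' @param effect_cycle_repression Graded repression of the S and G2/M gene
#'   programs in arrested cells (applied as `effect * depth`, on top of the
#'   out-of-phase trough); cell-cycle genes are the canonical
#'   down-regulated program of arrest.
#' @param effect_scale Global multiplier on every planted effect (0 removes
#'   all structure).
#' @param dispersion_range Per-gene NB dispersion phi (variance = mu +
#'   phi mu^2) drawn log-uniformly from this range.
#' @param library_size_lognormal `c(meanlog, sdlog)` of the per-cell library
#'   size factor.
#' @param total_counts_mean Expected total counts per cell at library factor
#'   1 with no effects.
#' @param mito_fraction_mean Expected mitochondrial count fraction for a
#'   healthy cell.
#' @param frac_high_mito Fraction of cells planted with ~6x mitochondrial
#'   load (to exercise the mito QC filter).
#' @param frac_low_lib Fraction of cells planted with ~5% library size (to
#'   exercise the detected-genes QC filter).
#' @param extra_programs Optional list of additional programs, each a list
#'   with fields `genes` (ids or indices), `effect`, and optionally
#'   `depth_min`, `depth_max`, `branch`.
#' @param seed Integer seed; identical parameters and seed give bit-identical
#'   output.
#' @return A validated list of class `"continuum_params"`.
#' @export
continuum_params <- function(n_cells_per_dose = c(UT = 500, dose_2.5 = 500,
                                                  dose_10 = 500,
                                                  dose_25 = 500),
                             n_genes = 1500,
                             cycling_prob = c(0.85, 0.45, 0.25, 0.05),
                             depth_shape1 = c(1.5, 1.8, 2.5, 5),
                             depth_shape2 = c(6, 4, 2.5, 1.8),
                             slip_fraction = c(0, 0.05, 0.15, 0.25),
                             cycling_cutoff = 0.15,
                             senescence_cutoff = 0.6,
                             senotype_depth_split = 0.8,
                             n_mito = 13, n_s = 40, n_g2m = 40, n_pan = 40,
                             n_sasp_universal = 30, n_sasp_branch = 20,
                             n_quiescence = 25, n_senotype = 60,
                             n_biosynthesis = 60,
                             effect_phase = 1.5, effect_pan = 2.2,
                             effect_senotype = 1.2, effect_sasp = 2.0,
                             effect_quiescence = 0.8,
                             effect_biosynthesis = -1.8,
                             effect_phase_off = -2.0,
                             effect_cycle_repression = -1.5,
                             effect_scale = 1,
                             dispersion_range = c(0.1, 1),
                             library_size_lognormal = c(meanlog = 0,
                                                        sdlog = 0.3),
                             total_counts_mean = 5000,
                             mito_fraction_mean = 0.05,
                             frac_high_mito = 0.03,
                             frac_low_lib = 0.02,
                             extra_programs = list(),
                             seed = 1L) {
  n_dose <- length(n_cells_per_dose)
  assert_that(n_dose >= 1 && all(n_cells_per_dose > 0) &&
                !is.null(names(n_cells_per_dose)),
              "`n_cells_per_dose` must be named positive integers")
  default_doses <- c("UT", "dose_2.5", "dose_10", "dose_25")
  for (nm in c("cycling_prob", "depth_shape1", "depth_shape2",
               "slip_fraction")) {
    v <- get(nm)
    if (length(v) != n_dose && length(v) == length(default_doses) &&
        all(names(n_cells_per_dose) %in% default_doses)) {
      # a named subset of the four standard doses inherits the matching
      # entries of the default per-dose vectors
      v <- v[match(names(n_cells_per_dose), default_doses)]
      assign(nm, v)
    }
    assert_that(length(v) == n_dose,
                paste0("`", nm, "` must have one value per dose"))
  }
  assert_that(all(slip_fraction >= 0 & slip_fraction <= 1),
              "`slip_fraction` must lie in [0, 1]")
  assert_that(all(cycling_prob >= 0 & cycling_prob <= 1),
              "`cycling_prob` must lie in [0, 1]")
  assert_that(cycling_cutoff > 0 && cycling_cutoff < senescence_cutoff &&
                senescence_cutoff < 1,
              "need 0 < cycling_cutoff < senescence_cutoff < 1")
  assert_that(senotype_depth_split > senescence_cutoff &&
                senotype_depth_split < 1,
              "`senotype_depth_split` must lie in (senescence_cutoff, 1)")
  n_program <- n_mito + n_s + n_g2m + n_pan + n_sasp_universal +
    n_sasp_branch + n_quiescence + 3 * n_senotype + n_biosynthesis
  assert_that(n_genes > n_program,
              sprintf("n_genes (%d) must exceed total program genes (%d)",
                      n_genes, n_program))
  effs <- c(effect_phase, effect_pan, effect_senotype, effect_sasp,
            effect_quiescence, effect_biosynthesis, effect_phase_off,
            effect_cycle_repression, effect_scale)
  assert_that(all(is.finite(effs)), "effect sizes must be finite")
  assert_that(all(dispersion_range > 0), "NB dispersion must be positive")
  params <- list(
    n_cells_per_dose = n_cells_per_dose, n_genes = n_genes,
    cycling_prob = cycling_prob, depth_shape1 = depth_shape1,
    depth_shape2 = depth_shape2, slip_fraction = slip_fraction,
    cycling_cutoff = cycling_cutoff, senescence_cutoff = senescence_cutoff,
    senotype_depth_split = senotype_depth_split,
    n_mito = n_mito, n_s = n_s, n_g2m = n_g2m, n_pan = n_pan,
    n_sasp_universal = n_sasp_universal, n_sasp_branch = n_sasp_branch,
    n_quiescence = n_quiescence, n_senotype = n_senotype,
    n_biosynthesis = n_biosynthesis,
    effect_phase = effect_phase, effect_pan = effect_pan,
    effect_senotype = effect_senotype, effect_sasp = effect_sasp,
    effect_quiescence = effect_quiescence,
    effect_biosynthesis = effect_biosynthesis,
    effect_phase_off = effect_phase_off,
    effect_cycle_repression = effect_cycle_repression,
    effect_scale = effect_scale,
    dispersion_range = dispersion_range,
    library_size_lognormal = library_size_lognormal,
    total_counts_mean = total_counts_mean,
    mito_fraction_mean = mito_fraction_mean,
    frac_high_mito = frac_high_mito, frac_low_lib = frac_low_lib,
    extra_programs = extra_programs,
    seed = as.integer(seed)
  )
  structure(params, class = "continuum_params")
}

#' Gene program layout for a parameter set
#'
#' Deterministically allocates the gene universe into the planted programs:
#' mitochondrial genes first (named `MT-01`, ...), then contiguous blocks for
#' each program, then unassigned background genes.
#'
#' @param params A [continuum_params()] object.
#' @return Data frame with columns `gene_id`, `gene_name`, `program`.
#' @export
gene_programs <- function(params) {
  p <- params
  ids <- sprintf("g%04d", seq_len(p$n_genes))
  names_ <- ids
  mito_idx <- seq_len(p$n_mito)
  ids[mito_idx] <- sprintf("MT-%02d", mito_idx)
  names_[mito_idx] <- ids[mito_idx]
  program <- rep("background", p$n_genes)
  program[mito_idx] <- "mito"
  cursor <- p$n_mito
  take <- function(n, label) {
    idx <- cursor + seq_len(n)
    program[idx] <<- label
    cursor <<- cursor + n
    idx
  }
  take(p$n_s, "s_phase")
  take(p$n_g2m, "g2m_phase")
  take(p$n_pan, "pan_senescence")
  take(p$n_sasp_universal, "sasp_universal")
  take(p$n_sasp_branch, "sasp_branch")
  take(p$n_quiescence, "quiescence_only")
  take(p$n_senotype, "senotype_A")
  take(p$n_senotype, "senotype_B")
  take(p$n_senotype, "senotype_slip")
  take(p$n_biosynthesis, "biosynthesis")
  data.frame(gene_id = ids, gene_name = names_, program = program,
             stringsAsFactors = FALSE)
}

#' Simulate a count matrix with planted continuum structure
#'
#' Counts are negative-binomial with cell- and gene-specific means whose
#' natural-log is `baseline + sum(active program effects) + log(library
#' factor)`. Program activity depends on the cell's latent depth, branch,
#' senotype and phase. Ground truth covers every cell and gene; identical
#' seed and parameters give bit-identical output.
#'
#' @param params A [continuum_params()] object.
#' @return A list with elements:
#'   \describe{
#'     \item{matrix}{`SingleCellExperiment` with sparse `counts`, per-cell
#'       `dose` in `colData`, and gene programs in `rowData`.}
#'     \item{cell_truth}{Data frame: `cell_id`, `dose`, `depth`, `branch`
#'       (`cycling`/`g0_path`/`slip_path`), `senotype`, `phase`,
#'       `dna_content`, `lib_factor`, `planted_high_mito`,
#'       `planted_low_lib`.}
#'     \item{gene_truth}{Data frame from [gene_programs()].}
#'     \item{params}{The parameters used.}
#'   }
#' @examples
#' sim <- simulate_counts(continuum_params(
#'   n_cells_per_dose = c(UT = 30, dose_25 = 30), n_genes = 400,
#'   n_senotype = 20, n_biosynthesis = 20, seed = 7))
#' dim(sim$matrix)
#' table(sim$cell_truth$branch)
#' @export
simulate_counts <- function(params) {
  assert_that(inherits(params, "continuum_params"),
              "`params` must come from continuum_params()")
  p <- params
  genes <- gene_programs(p)
  doses <- names(p$n_cells_per_dose)
  n_cells <- sum(p$n_cells_per_dose)

  with_seed(p$seed, {
    # --- per-gene baseline abundance and dispersion -----------------------
    base_rel <- stats::rlnorm(p$n_genes, meanlog = 0, sdlog = 1.2)
    mito <- genes$program == "mito"
    # pin expected mito share of the baseline library
    base_rel[mito] <- p$mito_fraction_mean * sum(base_rel[!mito]) /
      ((1 - p$mito_fraction_mean) * sum(mito))
    baseline <- log(base_rel / sum(base_rel) * p$total_counts_mean)
    dispersion <- exp(stats::runif(p$n_genes,
                                   log(p$dispersion_range[1]),
                                   log(p$dispersion_range[2])))

    # --- per-cell latent state -------------------------------------------
    dose <- rep(doses, times = p$n_cells_per_dose)
    di <- match(dose, doses)
    cycling <- stats::runif(n_cells) < p$cycling_prob[di]
    depth <- numeric(n_cells)
    depth[cycling] <- stats::runif(sum(cycling), 0, p$cycling_cutoff)
    arrested <- !cycling
    slip <- arrested & (stats::runif(n_cells) < p$slip_fraction[di])
    g0 <- arrested & !slip
    depth[g0] <- p$cycling_cutoff + (1 - p$cycling_cutoff) *
      stats::rbeta(sum(g0), p$depth_shape1[di][g0], p$depth_shape2[di][g0])
    # slip cells arrest directly and deeply (no quiescence transit)
    depth[slip] <- p$senescence_cutoff + (1 - p$senescence_cutoff) *
      stats::rbeta(sum(slip), 2, 2)
    branch <- ifelse(cycling, "cycling", ifelse(slip, "slip_path", "g0_path"))

    senescent <- arrested & depth >= p$senescence_cutoff
    senotype <- rep(NA_character_, n_cells)
    senotype[senescent & slip] <- "senotype_slip"
    g0_sen <- senescent & g0
    senotype[g0_sen & depth < p$senotype_depth_split] <- "senotype_A"
    senotype[g0_sen & depth >= p$senotype_depth_split] <- "senotype_B"

    phase <- rep("G0/G1", n_cells)
    cyc_idx <- which(cycling)
    phase[cyc_idx] <- sample(c("G0/G1", "S", "G2M"), length(cyc_idx),
                             replace = TRUE, prob = c(0.5, 0.25, 0.25))

    dna <- numeric(n_cells)
    dna[phase == "G0/G1" & !slip] <- stats::rnorm(sum(phase == "G0/G1" & !slip), 2, 0.12)
    dna[phase == "S"] <- stats::rnorm(sum(phase == "S"), 3, 0.30)
    dna[phase == "G2M"] <- stats::rnorm(sum(phase == "G2M"), 4, 0.15)
    dna[slip] <- stats::rnorm(sum(slip), 4, 0.15)

    lib <- stats::rlnorm(n_cells, p$library_size_lognormal[1],
                         p$library_size_lognormal[2])
    low_lib <- stats::runif(n_cells) < p$frac_low_lib
    lib[low_lib] <- lib[low_lib] * 0.05
    high_mito <- stats::runif(n_cells) < p$frac_high_mito

    # --- program effects on the log mean ---------------------------------
    eff <- matrix(0, p$n_genes, n_cells)
    add <- function(gene_sel, cell_weight) {
      idx <- which(gene_sel)
      act <- which(cell_weight != 0)
      if (length(idx) && length(act)) {
        eff[idx, act] <<- eff[idx, act] +
          rep(cell_weight[act], each = length(idx))
      }
    }
    s <- p$effect_scale
    # phase genes peak in their own phase and trough everywhere else;
    # arrest deepens the repression in a depth-graded way
    add(genes$program == "s_phase",
        s * (p$effect_phase * (phase == "S") +
               p$effect_phase_off * (phase != "S")))
    add(genes$program == "g2m_phase",
        s * (p$effect_phase * (phase == "G2M") +
               p$effect_phase_off * (phase != "G2M")))
    cycle_genes <- genes$program %in% c("s_phase", "g2m_phase")
    add(cycle_genes, s * p$effect_cycle_repression * depth * arrested)
    add(genes$program == "pan_senescence",
        s * p$effect_pan * depth * arrested)
    # SASP ramps on from depth 0.3 and saturates by 0.8 (interferon-class
    # SASP genes are strongly induced in every deeply arrested cell)
    add(genes$program == "sasp_universal",
        s * p$effect_sasp *
          pmin(1, pmax(0, (depth - 0.3) / 0.5)) * arrested)
    add(genes$program == "sasp_branch", s * p$effect_sasp * slip)
    add(genes$program == "quiescence_only",
        s * p$effect_quiescence *
          (arrested & depth > p$cycling_cutoff & depth < 0.5))
    for (st in c("senotype_A", "senotype_B", "senotype_slip")) {
      add(genes$program == st,
          s * p$effect_senotype * (!is.na(senotype) & senotype == st))
    }
    add(genes$program == "biosynthesis", s * p$effect_biosynthesis * depth)
    for (xp in p$extra_programs) {
      gsel <- if (is.numeric(xp$genes)) {
        seq_len(p$n_genes) %in% xp$genes
      } else {
        genes$gene_id %in% xp$genes
      }
      assert_that(any(gsel), "extra program matched no genes")
      w <- rep(1, n_cells)
      if (!is.null(xp$depth_min)) w <- w * (depth >= xp$depth_min)
      if (!is.null(xp$depth_max)) w <- w * (depth <= xp$depth_max)
      if (!is.null(xp$branch)) w <- w * (branch == xp$branch)
      add(gsel, s * xp$effect * w)
    }
    eff[mito, high_mito] <- eff[mito, high_mito] + log(6)

    mu <- exp(baseline + eff + rep(log(lib), each = p$n_genes))
    counts <- matrix(
      stats::rnbinom(length(mu), mu = as.vector(mu),
                     size = rep(1 / dispersion, times = n_cells)),
      nrow = p$n_genes
    )
    cell_ids <- sprintf("cell_%04d", seq_len(n_cells))
    dimnames(counts) <- list(genes$gene_id, cell_ids)

    sce <- SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = methods::as(counts, "CsparseMatrix")),
      rowData = S4Vectors::DataFrame(gene_id = genes$gene_id,
                                     gene_name = genes$gene_name,
                                     program = genes$program,
                                     row.names = genes$gene_id),
      colData = S4Vectors::DataFrame(cell_id = cell_ids, dose = dose,
                                     dna_content = dna,
                                     row.names = cell_ids)
    )
    cell_truth <- data.frame(
      cell_id = cell_ids, dose = dose, depth = depth, branch = branch,
      senotype = senotype, phase = phase, dna_content = dna,
      lib_factor = lib, planted_high_mito = high_mito,
      planted_low_lib = low_lib, stringsAsFactors = FALSE
    )
    list(matrix = sce, cell_truth = cell_truth, gene_truth = genes,
         params = p)
  })
}

#' Simulate CDK2 activity traces
#'
#' Fast-cycling cells show repeated rise/reset cycles spending little time
#' below the activity threshold; slow-cycling cells interleave long
#' sub-threshold plateaus with cycles; senescent cells stay sub-threshold
#' for the whole movie. Gaussian noise of configurable amplitude is added.
#'
#' @param n_cells Number of cells.
#' @param behavior_mix Proportions over `c(fast, slow, senescent)`; must sum
#'   to 1.
#' @param frame_interval_min Minutes between frames.
#' @param n_frames Number of frames.
#' @param noise_sd Additive Gaussian noise SD (activity units).
#' @param seed Integer seed.
#' @return A list with `traces` (a `trace_set`) and `truth` (data frame of
#'   per-cell true behavior).
#' @export
simulate_traces <- function(n_cells, behavior_mix = c(fast = 1 / 3,
                                                      slow = 1 / 3,
                                                      senescent = 1 / 3),
                            frame_interval_min = 12, n_frames = 480,
                            noise_sd = 0, seed = 1L) {
  assert_that(length(behavior_mix) == 3 && all(behavior_mix >= 0) &&
                sum(behavior_mix) > 0,
              "`behavior_mix` must be 3 non-negative proportions")
  assert_that(abs(sum(behavior_mix) - 1) < 1e-8,
              "`behavior_mix` must sum to 1")
  behaviors <- c("fast", "slow", "senescent")
  with_seed(seed, {
    labels <- sample(behaviors, n_cells, replace = TRUE,
                     prob = behavior_mix)
    fph <- 60 / frame_interval_min      # frames per hour
    cyc_frames <- round(16 * fph)       # one cell cycle ~16 h
    vals <- matrix(0, n_cells, n_frames)
    for (i in seq_len(n_cells)) {
      vals[i, ] <- switch(
        labels[i],
        fast = {
          off <- sample.int(cyc_frames, 1) - 1L
          f <- ((seq_len(n_frames) - 1L + off) %% cyc_frames)
          0.75 + 0.55 * f / cyc_frames
        },
        slow = {
          x <- numeric(0)
          while (length(x) < n_frames) {
            plateau <- round(stats::runif(1, 15, 30) * fph)
            x <- c(x, rep(0.4, plateau), 0.75 +
                     0.55 * (seq_len(cyc_frames) - 1) / cyc_frames)
          }
          x[seq_len(n_frames)]
        },
        senescent = rep(0.3, n_frames)
      )
    }
    if (noise_sd > 0) {
      vals <- vals + matrix(stats::rnorm(n_cells * n_frames, 0, noise_sd),
                            n_cells, n_frames)
    }
    rownames(vals) <- sprintf("cell_%04d", seq_len(n_cells))
    ts <- trace_set(vals, frame_interval_min = frame_interval_min)
    list(traces = ts,
         truth = data.frame(cell_id = rownames(vals), behavior = labels,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate reporter accumulation traces
#'
#' Pre-induction signal fluctuates around a per-cell baseline; after the
#' induction frame the signal rises linearly with the cell's class slope
#' (per frame, on the baseline-normalized scale) plus noise. With zero noise
#' the fitted normalized slope equals the generating slope exactly.
#'
#' @param n_cells Number of cells.
#' @param slopes_by_class Named non-negative slopes (normalized units per
#'   frame), e.g. `c(slow = 0.10, senescent = 0.02)`.
#' @param class_mix Proportions per class (defaults to equal).
#' @param induction_frame Frame at which induction occurs (1-based; frames
#'   up to and including it are pre-induction baseline).
#' @param n_frames Total frames.
#' @param frame_interval_min Minutes between frames.
#' @param noise_sd Noise SD on the normalized scale.
#' @param seed Integer seed.
#' @return A list with `traces` (a `trace_set` with `induction_frame` set)
#'   and `truth` (per-cell class and generating slope).
#' @export
simulate_reporter_traces <- function(n_cells, slopes_by_class,
                                     class_mix = NULL,
                                     induction_frame = 20,
                                     n_frames = 120,
                                     frame_interval_min = 12,
                                     noise_sd = 0, seed = 1L) {
  assert_that(length(slopes_by_class) >= 1 &&
                !is.null(names(slopes_by_class)),
              "`slopes_by_class` must be a named vector")
  assert_that(all(slopes_by_class >= 0), "negative slopes rejected")
  assert_that(induction_frame >= 1 && induction_frame < n_frames,
              "`induction_frame` must fall inside the trace window")
  classes <- names(slopes_by_class)
  class_mix <- class_mix %||% rep(1 / length(classes), length(classes))
  with_seed(seed, {
    labels <- sample(classes, n_cells, replace = TRUE, prob = class_mix)
    baseline <- stats::rnorm(n_cells, 100, 10)
    vals <- matrix(0, n_cells, n_frames)
    post <- seq_len(n_frames) > induction_frame
    for (i in seq_len(n_cells)) {
      s <- slopes_by_class[[labels[i]]]
      norm <- rep(1, n_frames)
      norm[post] <- 1 + s * (which(post) - induction_frame)
      vals[i, ] <- baseline[i] * norm
    }
    if (noise_sd > 0) {
      vals <- vals + matrix(stats::rnorm(n_cells * n_frames, 0, noise_sd),
                            n_cells, n_frames) * baseline
    }
    rownames(vals) <- sprintf("cell_%04d", seq_len(n_cells))
    ts <- trace_set(vals, frame_interval_min = frame_interval_min,
                    induction_frame = induction_frame)
    list(traces = ts,
         truth = data.frame(cell_id = rownames(vals), class = labels,
                            slope_per_frame = unname(
                              slopes_by_class[labels]),
                            stringsAsFactors = FALSE))
  })
}
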
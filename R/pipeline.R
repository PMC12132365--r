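# End-to-end pipeline: QC -> normalize -> HVG/PCA -> phase -> cluster ->
# DGE -> GSEA -> scores -> pseudotime -> derived gene sets.

#' Run the full senotyping pipeline
#'
#' Executes every stage in order on a count matrix (or a simulation), using
#' the thresholds and seeds in `config`, and optionally writes per-stage
#' CSV/JSON outputs plus a log. Given fixed seeds the run is deterministic.
#'
#' @param input A `SingleCellExperiment` with counts, a path to a 10x-style
#'   directory, or a [continuum_params()] object (simulated on the fly).
#' @param config A [pipeline_config()].
#' @param s_genes,g2m_genes Cell-cycle phase marker gene ids. When `NULL`
#'   and the input carries a `program` rowData column (simulated data), the
#'   planted `s_phase`/`g2m_phase` programs are used.
#' @param gene_sets Optional named list of gene sets (GMT-derived) for
#'   enrichment and scoring.
#' @param sasp_sets Names within `gene_sets` regarded as SASP-related
#'   (their leading edges feed the shared-SASP derivation). Defaults to
#'   names containing "SASP" (case-insensitive).
#' @param untreated_label Dose label of the untreated condition (default:
#'   `"UT"` when present, else the first dose).
#' @param out_dir Optional output directory for per-stage files.
#' @param verbose Log stage progress to stderr.
#' @return A list bundle: the processed matrix (`matrix`), `qc_report`,
#'   `hvg`, `phase`, `clusters`, `cluster_labels`, `embedding`,
#'   `composition`, `dge` (per senescent cluster + `combined`), `gsea`,
#'   `scores`, `trajectory`, `heatmaps`, `shared_sasp`, `signature`,
#'   `signature_scores`, and `config`.
#' @export
run_pipeline <- function(input, config = pipeline_config(),
                         s_genes = NULL, g2m_genes = NULL,
                         gene_sets = NULL, sasp_sets = NULL,
                         untreated_label = NULL, out_dir = NULL,
                         verbose = TRUE) {
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    if (verbose) message(msg)
    log_lines <<- c(log_lines, msg)
  }
  emit <- function(name, df) {
    if (!is.null(out_dir)) {
      utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                       row.names = FALSE)
    }
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  validate_config(config)

  # ---- input ------------------------------------------------------------
  truth <- NULL
  if (inherits(input, "continuum_params")) {
    say("simulate: ", sum(input$n_cells_per_dose), " cells x ",
        input$n_genes, " genes")
    sim <- simulate_counts(input)
    sce <- sim$matrix
    truth <- sim$cell_truth
  } else if (is.character(input)) {
    say("read_10x: ", input)
    sce <- read_10x(input)
  } else {
    sce <- input
  }
  assert_that(methods::is(sce, "SingleCellExperiment"),
              "input must resolve to a SingleCellExperiment")
  rd <- SummarizedExperiment::rowData(sce)
  if (is.null(s_genes) && "program" %in% names(rd)) {
    s_genes <- rownames(sce)[rd$program == "s_phase"]
    g2m_genes <- rownames(sce)[rd$program == "g2m_phase"]
  }
  assert_that(!is.null(s_genes) && !is.null(g2m_genes),
              "supply s_genes and g2m_genes (or simulated input)")
  dose <- SummarizedExperiment::colData(sce)$dose
  assert_that(!is.null(dose), "colData must carry a `dose` column")
  doses <- unique(dose)
  untreated_label <- untreated_label %||%
    (if ("UT" %in% doses) "UT" else doses[1])
  high_dose <- doses[length(doses)]

  # ---- qc + normalize ---------------------------------------------------
  qc <- qc_filter(sce, config)
  sce <- qc$matrix
  say("qc: kept ", ncol(sce), " cells / dropped ",
      sum(!qc$report$pass), "; ", nrow(sce), " genes")
  emit("qc_report", qc$report)
  sce <- log_normalize(sce, config$scale_factor)
  dose <- SummarizedExperiment::colData(sce)$dose

  # ---- hvg + pca --------------------------------------------------------
  hvg <- select_hvg(sce, min(config$n_hvg, nrow(sce)))
  sce <- scale_and_pca(sce, hvg, n_pcs = config$n_pcs,
                       clip = config$scale_clip)
  say("pca: ", ncol(SingleCellExperiment::reducedDim(sce, "PCA")),
      " components over ", length(hvg), " HVGs")
  emit("hvg", data.frame(gene_id = as.character(hvg)))

  # ---- phase ------------------------------------------------------------
  phase_df <- assign_phase(sce, s_genes, g2m_genes,
                           n_bins = config$score_bins,
                           n_ctrl = config$score_ctrl,
                           seed = config$seeds$score)
  SummarizedExperiment::colData(sce)$phase <- phase_df$phase
  say("phase: ", paste(names(table(phase_df$phase)),
                       table(phase_df$phase), collapse = ", "))
  emit("phase", phase_df)

  # ---- cluster + embed --------------------------------------------------
  clusters <- cluster_snn(sce, k = config$snn_k,
                          resolution = config$cluster_resolution,
                          prune = config$snn_prune,
                          seed = config$seeds$cluster)
  SummarizedExperiment::colData(sce)$cluster <- clusters
  labels <- label_clusters(clusters, phase_df$phase, dose,
                           high_dose = high_dose)
  say("cluster: ", length(unique(clusters)), " clusters (",
      sum(labels == "senescent-like"), " senescent-like)")
  emb <- embed_2d(sce, seed = config$seeds$embed)
  comp <- composition_table(clusters, dose)
  emit("clusters", data.frame(cell_id = colnames(sce),
                              cluster = unname(clusters),
                              label = unname(labels[as.character(
                                clusters)])))
  emit("embedding", data.frame(cell_id = colnames(sce), emb))
  emit("composition", comp)

  # ---- differential expression -----------------------------------------
  sen_clusters <- names(labels)[labels == "senescent-like"]
  all_cells <- colnames(sce)
  dge <- list()
  for (cl in sen_clusters) {
    in_cl <- all_cells[clusters == as.integer(cl)]
    dge[[cl]] <- ranking_scores(
      wilcoxon_dge(sce, in_cl, setdiff(all_cells, in_cl),
                   min_pct = config$dge_min_pct,
                   min_logfc = config$dge_min_logfc),
      adjust = config$rank_adjust, eps = config$rank_eps)
    emit(paste0("dge_cluster_", cl), dge[[cl]])
  }
  sen_cells <- all_cells[clusters %in% as.integer(sen_clusters)]
  dge$combined <- ranking_scores(
    wilcoxon_dge(sce, sen_cells, setdiff(all_cells, sen_cells),
                 min_pct = config$dge_min_pct,
                 min_logfc = config$dge_min_logfc),
    adjust = config$rank_adjust, eps = config$rank_eps)
  emit("dge_combined", dge$combined)
  say("dge: ", length(sen_clusters), " senescent clusters + combined")

  # ---- gsea -------------------------------------------------------------
  gsea <- list()
  sasp_leading <- character(0)
  if (!is.null(gene_sets)) {
    sasp_sets <- sasp_sets %||%
      names(gene_sets)[grepl("sasp", names(gene_sets),
                             ignore.case = TRUE)]
    for (cl in sen_clusters) {
      scores <- stats::setNames(dge[[cl]]$ranking_score,
                                dge[[cl]]$gene_id)
      gsea[[cl]] <- gsea_preranked(
        scores, gene_sets, weight = config$gsea_weight,
        n_perm = config$gsea_nperm, min_size = config$gsea_min_size,
        max_size = config$gsea_max_size, seed = config$seeds$gsea)
      emit(paste0("gsea_cluster_", cl),
           gsea[[cl]][, setdiff(names(gsea[[cl]]), "leading_edge")])
      present_sasp <- intersect(sasp_sets, gsea[[cl]]$set)
      if (length(present_sasp) > 0) {
        sasp_leading <- union(
          sasp_leading,
          leading_edge_union(gsea[[cl]], present_sasp, scores))
      }
    }
    say("gsea: ", length(gsea), " cluster runs; SASP leading edge = ",
        length(sasp_leading), " genes")
  }

  # ---- per-cell scores for supplied sets -------------------------------
  scores_tab <- NULL
  if (!is.null(gene_sets)) {
    scores_tab <- data.frame(cell_id = colnames(sce),
                             stringsAsFactors = FALSE)
    for (nm in names(gene_sets)) {
      genes <- intersect(gene_sets[[nm]], rownames(sce))
      if (length(genes) == 0) next
      scores_tab[[nm]] <- unname(module_score(
        sce, genes, n_bins = config$score_bins,
        n_ctrl = config$score_ctrl, seed = config$seeds$score))
    }
    emit("scores", scores_tab)
  }

  # ---- pseudotime -------------------------------------------------------
  subset_cells <- all_cells[phase_df$phase == "G0/G1" &
                              dose != untreated_label]
  cycling_cells <- all_cells[phase_df$phase != "G0/G1"]
  trajectory <- NULL
  heatmaps <- NULL
  if (length(unique(clusters[subset_cells])) >= 2 &&
      length(cycling_cells) >= 1) {
    dna <- SummarizedExperiment::colData(sce)$dna_content
    if (!is.null(dna)) names(dna) <- colnames(sce)
    trajectory <- learn_trajectory(sce, subset_cells, clusters,
                                   cycling_cells = cycling_cells,
                                   branch_marker = dna)
    say("pseudotime: root ", trajectory$root, ", branch node ",
        trajectory$branch_node)
    emit("pseudotime", trajectory$cells)
    emit("trajectory_edges", trajectory$edges)
    if (!is.null(gene_sets)) {
      heatmaps <- pathway_heatmap_matrix(
        sce, trajectory, gene_sets, span = config$loess_span,
        degree = config$loess_degree, grid_n = config$grid_n,
        n_bins = config$score_bins, n_ctrl = config$score_ctrl,
        seed = config$seeds$score)
      for (br in names(heatmaps)) {
        emit(paste0("heatmap_", br),
             data.frame(group = rownames(heatmaps[[br]]),
                        heatmaps[[br]], check.names = FALSE))
      }
    }
  } else {
    say("pseudotime: skipped (fewer than 2 arrested clusters)")
  }

  # ---- derived gene sets ------------------------------------------------
  shared_sasp <- NULL
  if (length(sasp_leading) > 0 && length(sen_clusters) >= 2) {
    shared_sasp <- shared_sasp_genes(sasp_leading, dge[sen_clusters],
                                     top_n = config$top_sasp)
    say("shared SASP: ", length(shared_sasp$genes), " genes")
  }
  signature <- NULL
  signature_scores <- NULL
  if (length(sen_clusters) >= 1) {
    # the weakly-identified cluster: fewest Bonferroni-significant genes
    n_sig <- vapply(sen_clusters, function(cl) {
      sum(dge[[cl]]$p_adj_bonferroni < 0.05 & dge[[cl]]$avg_log2FC > 0)
    }, numeric(1))
    weak <- sen_clusters[which.min(n_sig)]
    ut_g0g1 <- all_cells[dose == untreated_label &
                           phase_df$phase == "G0/G1"]
    if (length(ut_g0g1) > 0) {
      signature <- derive_senescence_signature(
        dge$combined, dge[[weak]], sce,
        senescent_cells = sen_cells, untreated_g0g1_cells = ut_g0g1,
        top_combined = config$top_combined, top_weak = config$top_weak,
        background_ratio = config$background_ratio)
      say("signature: ", length(signature$genes), " genes (weak cluster ",
          weak, ")")
      signature_scores <- score_gene_set(
        sce, intersect(signature$genes, rownames(sce)),
        clusters = clusters, n_bins = config$score_bins,
        n_ctrl = config$score_ctrl, seed = config$seeds$score)
      if (!is.null(out_dir)) {
        write_gmt(list(etoposide_senescence = signature$genes,
                       shared_sasp = shared_sasp$genes %||% character(0)),
                  file.path(out_dir, "derived_gene_sets.gmt"))
        jsonlite::write_json(signature$trace,
                             file.path(out_dir, "signature_trace.json"),
                             auto_unbox = TRUE, digits = NA)
      }
    }
  }

  if (!is.null(out_dir)) {
    writeLines(log_lines, file.path(out_dir, "pipeline_log.txt"))
  }
  list(matrix = sce, qc_report = qc$report, hvg = hvg, phase = phase_df,
       clusters = clusters, cluster_labels = labels, embedding = emb,
       composition = comp, dge = dge, gsea = gsea, scores = scores_tab,
       trajectory = trajectory, heatmaps = heatmaps,
       shared_sasp = shared_sasp, signature = signature,
       signature_scores = signature_scores, truth = truth,
       config = config)
}
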
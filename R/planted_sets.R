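# Gene-set collections derived from the generator's planted programs --
# the synthetic stand-ins for the GMT collections (GO BP terms, cell-cycle
# lists, SASP lists) a real analysis would load.

#' Gene sets over the planted programs of a simulation
#'
#' Builds a named gene-set collection from a [simulate_counts()] result:
#' three SASP-related sets that mix universal SASP genes, slip-branch SASP
#' genes, senotype-specific genes and background filler (so per-cluster
#' leading edges are cluster-specific and only the universal genes are
#' shared, as in real pathway collections), the two cell-cycle phase
#' lists, the pan-senescence/biosynthesis/quiescence programs, the three
#' senotype marker sets, and two pure background sets as negative
#' controls. Deterministic: members are taken in gene order.
#'
#' @param sim A [simulate_counts()] result.
#' @return Named list of gene-id vectors with attribute `sasp_sets` naming
#'   the SASP-related sets.
#' @export
planted_gene_sets <- function(sim) {
  gt <- sim$gene_truth
  by_prog <- split(gt$gene_id, gt$program)
  bg <- by_prog$background
  uni <- by_prog$sasp_universal
  br <- by_prog$sasp_branch
  half <- ceiling(length(uni) / 2)
  halfb <- ceiling(length(br) / 2)
  stA <- by_prog$senotype_A
  stB <- by_prog$senotype_B
  sets <- list(
    SASP_interferon_response = c(uni[seq_len(half)], stA[1:10],
                                 stB[1:10], bg[1:10]),
    SASP_inflammatory_secretion = c(uni[seq(half + 1, length(uni))],
                                    br[seq_len(halfb)], bg[11:20]),
    SASP_wound_healing = c(br[seq(halfb + 1, length(br))], stA[11:20],
                           stB[11:20], bg[21:30]),
    cell_cycle_S = by_prog$s_phase,
    cell_cycle_G2M = by_prog$g2m_phase,
    translation_biosynthesis = by_prog$biosynthesis,
    p21_arrest_markers = by_prog$pan_senescence,
    quiescence_shallow = by_prog$quiescence_only,
    senotype_A_markers = by_prog$senotype_A,
    senotype_B_markers = by_prog$senotype_B,
    senotype_slip_markers = by_prog$senotype_slip,
    background_control_1 = bg[31:50],
    background_control_2 = bg[51:70]
  )
  attr(sets, "sasp_sets") <- c("SASP_interferon_response",
                               "SASP_inflammatory_secretion",
                               "SASP_wound_healing")
  sets
}
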
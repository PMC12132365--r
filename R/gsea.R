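# Native preranked gene set enrichment: weighted Kolmogorov-Smirnov
# running sum, gene-label permutation null, BH adjustment, leading edge.

#' Enrichment score of one set on a ranked list
#'
#' Walks the ranked list; hits increment the running sum by
#' `|score|^weight` normalized by the sum of `|score|^weight` over the set,
#' misses decrement by `1/(N - N_hits)`. The enrichment score is the
#' maximum-magnitude deviation of the running sum. With `weight = 0` this
#' is the classic unweighted KS statistic.
#'
#' @param scores Numeric ranking scores sorted in decreasing order.
#' @param hit Logical vector, same length, marking set membership.
#' @param weight Weight exponent.
#' @return List: `es`, `peak` (index of the extremum), `running` (the full
#'   running sum).
#' @keywords internal
#' @export
running_sum_es <- function(scores, hit, weight = 1) {
  n <- length(scores)
  n_hit <- sum(hit)
  if (n_hit == 0 || n_hit == n) {
    return(list(es = 0, peak = NA_integer_, running = rep(0, n)))
  }
  inc <- abs(scores)^weight
  inc[!hit] <- 0
  denom <- sum(inc)
  if (denom == 0) inc[hit] <- 1 / n_hit else inc <- inc / denom
  dec <- 1 / (n - n_hit)
  step <- ifelse(hit, inc, -dec)
  running <- cumsum(step)
  # earliest extremum wins when |deviations| tie to numerical precision
  peak <- which(abs(running) >= max(abs(running)) - 1e-12)[1]
  list(es = running[peak], peak = peak, running = running)
}

#' Preranked gene set enrichment analysis
#'
#' Computes the weighted KS enrichment score for each gene set against a
#' ranked, scored gene list; significance comes from a seeded gene-label
#' permutation null (random sets of the same size), one-sided toward the
#' observed ES sign. `NES = ES / mean(|permuted ES| of the same sign)`.
#' P-values are BH-adjusted across sets. The leading edge contains the set
#' genes at or before the running-sum extremum (at or after, for negative
#' ES).
#'
#' @param scores Named numeric vector of ranking scores (sorted internally
#'   in decreasing order; names are gene ids and must be unique).
#' @param sets Named list of gene-id vectors.
#' @param weight Weight exponent on |score| for hit increments.
#' @param n_perm Number of permutations.
#' @param min_size,max_size Set-size bounds after intersection with the
#'   ranked universe.
#' @param seed Integer seed for the permutations.
#' @return Data frame, one row per tested set: `set`, `set_size_tested`,
#'   `es`, `nes`, `p_value`, `p_adj_bh`, and a list-column
#'   `leading_edge`.
#' @export
gsea_preranked <- function(scores, sets, weight = 1, n_perm = 1000,
                           min_size = 10, max_size = 500, seed = 42L) {
  assert_that(length(scores) > 0 && !is.null(names(scores)),
              "`scores` must be a named vector")
  assert_that(!anyDuplicated(names(scores)),
              "ranked list has duplicate genes")
  ord <- order(-scores, names(scores))
  scores <- scores[ord]
  universe <- names(scores)
  n <- length(universe)
  sizes <- vapply(sets, function(s) length(intersect(s, universe)),
                  integer(1))
  testable <- sizes >= min_size & sizes <= max_size & sizes < n
  if (any(sizes >= n)) {
    warning("set(s) covering the whole universe get ES = 0: ",
            paste(names(sets)[sizes >= n], collapse = ", "))
  }
  whole <- names(sets)[sizes >= n]
  keep <- names(sets)[testable]
  assert_that(length(keep) > 0 || length(whole) > 0,
              "no sets pass the size bounds")

  # shared permutation null per set size
  uniq_sizes <- sort(unique(sizes[keep]))
  perm_es <- with_seed(seed, {
    out <- list()
    for (sz in uniq_sizes) {
      out[[as.character(sz)]] <- vapply(seq_len(n_perm), function(i) {
        hit <- logical(n)
        hit[sample_int(n, sz)] <- TRUE
        running_sum_es(scores, hit, weight)$es
      }, numeric(1))
    }
    out
  })

  rows <- lapply(keep, function(nm) {
    members <- intersect(sets[[nm]], universe)
    hit <- universe %in% members
    obs <- running_sum_es(scores, hit, weight)
    perm <- perm_es[[as.character(sum(hit))]]
    if (obs$es >= 0) {
      pos <- perm[perm >= 0]
      p <- (1 + sum(pos >= obs$es)) / (1 + length(pos))
      nes <- if (length(pos) && mean(pos) > 0) obs$es / mean(pos) else 0
      le <- universe[hit & seq_len(n) <= obs$peak]
    } else {
      neg <- perm[perm < 0]
      p <- (1 + sum(neg <= obs$es)) / (1 + length(neg))
      nes <- if (length(neg)) obs$es / mean(abs(neg)) else 0
      le <- universe[hit & seq_len(n) >= obs$peak]
    }
    list(set = nm, set_size_tested = sum(hit), es = obs$es, nes = nes,
         p_value = p, leading_edge = le)
  })
  res <- data.frame(
    set = vapply(rows, `[[`, character(1), "set"),
    set_size_tested = vapply(rows, `[[`, integer(1), "set_size_tested"),
    es = vapply(rows, `[[`, numeric(1), "es"),
    nes = vapply(rows, `[[`, numeric(1), "nes"),
    p_value = vapply(rows, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE
  )
  if (length(whole)) {
    res <- rbind(res, data.frame(set = whole, set_size_tested = n,
                                 es = 0, nes = 0, p_value = 1,
                                 stringsAsFactors = FALSE))
    rows <- c(rows, lapply(whole, function(nm) {
      list(leading_edge = character(0))
    }))
  }
  res$p_adj_bh <- stats::p.adjust(res$p_value, method = "BH")
  res$leading_edge <- lapply(rows, `[[`, "leading_edge")
  res
}

#' Ordered union of leading edges
#'
#' Unions the leading-edge genes of the named sets, ordered by each gene's
#' best (largest) ranking score across the ranked list used for the
#' enrichment.
#'
#' @param results A data frame from [gsea_preranked()].
#' @param set_names Sets whose leading edges to pool.
#' @param scores The named score vector the enrichment was run on (used
#'   for ordering; optional - falls back to first-seen order).
#' @return Character vector of genes.
#' @export
leading_edge_union <- function(results, set_names, scores = NULL) {
  missing <- setdiff(set_names, results$set)
  assert_that(length(missing) == 0,
              paste0("unknown set name(s): ",
                     paste(missing, collapse = ", ")))
  idx <- match(set_names, results$set)
  genes <- unique(unlist(results$leading_edge[idx], use.names = FALSE))
  if (!is.null(scores)) {
    genes <- genes[order(-scores[genes], genes)]
  }
  genes
}
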
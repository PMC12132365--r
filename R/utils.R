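# Internal helpers shared across the pipeline.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded sampling inside one stage
#' never perturbs the RNG stream of the caller. All stochastic operations in
#' the package route their sampling through this helper.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  code
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop unless a condition holds
#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

#' Dense numeric matrix from a possibly sparse assay
#' @noRd
as_dense <- function(x) {
  if (methods::is(x, "sparseMatrix")) as.matrix(x) else as.matrix(x)
}

#' Resolve a cell selector (logical, integer, or character) to cell ids
#' @noRd
resolve_cells <- function(object, cells) {
  ids <- colnames(object)
  if (is.logical(cells)) {
    assert_that(length(cells) == length(ids),
                "logical cell selector has wrong length")
    return(ids[cells])
  }
  if (is.numeric(cells)) return(ids[cells])
  missing <- setdiff(cells, ids)
  assert_that(length(missing) == 0L,
              paste0("unknown cell ids: ", paste(utils::head(missing, 5),
                                                 collapse = ", ")))
  as.character(cells)
}

#' Seeded sample() that is stable across R versions for our use
#' @noRd
sample_int <- function(n, size, replace = FALSE) {
  sample.int(n, size = size, replace = replace)
}
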
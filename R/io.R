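# Readers and writers for the standard on-disk formats: 10x-style
# MatrixMarket triples and GMT gene-set collections.

#' Read a 10x-style count matrix directory
#'
#' Expects `matrix.mtx`, `features.tsv` (or `genes.tsv`) and `barcodes.tsv`,
#' each optionally gzipped. The features file's first column is used as the
#' gene id and the second as the gene name; a 2-column file is tolerated with
#' a warning (names are reused as ids). The matrix is oriented genes x cells
#' regardless of on-disk convention (10x stores genes as rows, which is kept).
#'
#' @param dir_path Directory containing the three files.
#' @return A [SingleCellExperiment::SingleCellExperiment] with a sparse
#'   integer `counts` assay, `rowData` columns `gene_id`/`gene_name`, and
#'   barcodes as column names.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' m <- Matrix::sparseMatrix(i = c(1, 3), j = c(1, 2), x = c(5, 2),
#'                           dims = c(3, 2))
#' write_10x(m, dir, gene_ids = paste0("G", 1:3),
#'           gene_names = paste0("gene", 1:3),
#'           barcodes = c("AAA-1", "AAC-1"))
#' sce <- read_10x(dir)
#' SummarizedExperiment::assay(sce, "counts")[1, 1]
#' @export
read_10x <- function(dir_path) {
  assert_that(dir.exists(dir_path), paste0("no such directory: ", dir_path))
  find_file <- function(bases) {
    for (b in bases) {
      for (ext in c("", ".gz")) {
        p <- file.path(dir_path, paste0(b, ext))
        if (file.exists(p)) return(p)
      }
    }
    stop("missing file (tried: ", paste(bases, collapse = ", "),
         ") in ", dir_path, call. = FALSE)
  }
  mtx_path <- find_file("matrix.mtx")
  feat_path <- find_file(c("features.tsv", "genes.tsv"))
  bc_path <- find_file("barcodes.tsv")

  counts <- Matrix::readMM(gzfile_if_needed(mtx_path))
  counts <- methods::as(counts, "CsparseMatrix")
  if (any(counts@x != round(counts@x)) || any(counts@x < 0)) {
    stop("matrix contains non-integer or negative entries", call. = FALSE)
  }
  feats <- utils::read.delim(gzfile_if_needed(feat_path), header = FALSE,
                             stringsAsFactors = FALSE)
  if (ncol(feats) < 2) {
    warning("features file has a single column; using it for ids and names")
    feats$V2 <- feats$V1
  }
  barcodes <- readLines(gzfile_if_needed(bc_path))
  assert_that(nrow(feats) == nrow(counts),
              sprintf("feature rows (%d) do not match matrix rows (%d)",
                      nrow(feats), nrow(counts)))
  assert_that(length(barcodes) == ncol(counts),
              sprintf("barcodes (%d) do not match matrix columns (%d)",
                      length(barcodes), ncol(counts)))
  assert_that(!anyDuplicated(feats[[1]]), "gene ids are not unique")
  assert_that(!anyDuplicated(barcodes), "cell barcodes are not unique")
  dimnames(counts) <- list(feats[[1]], barcodes)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(gene_id = feats[[1]],
                                   gene_name = feats[[2]],
                                   row.names = feats[[1]])
  )
  sce
}

#' @noRd
gzfile_if_needed <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path) else path
}

#' Write a count matrix in 10x-style MatrixMarket layout
#'
#' @param x A `SingleCellExperiment` with a `counts` assay, or a matrix /
#'   sparse matrix of counts (genes x cells).
#' @param dir_path Output directory (created if absent).
#' @param gene_ids,gene_names,barcodes Required when `x` is a bare matrix;
#'   taken from the object otherwise.
#' @param gzip Write gzipped files (default plain text).
#' @return `dir_path`, invisibly.
#' @export
write_10x <- function(x, dir_path, gene_ids = NULL, gene_names = NULL,
                      barcodes = NULL, gzip = FALSE) {
  if (methods::is(x, "SingleCellExperiment")) {
    rd <- SummarizedExperiment::rowData(x)
    gene_ids <- gene_ids %||% rd$gene_id %||% rownames(x)
    gene_names <- gene_names %||% rd$gene_name %||% rownames(x)
    barcodes <- barcodes %||% colnames(x)
    x <- SummarizedExperiment::assay(x, "counts")
  }
  gene_ids <- gene_ids %||% rownames(x)
  gene_names <- gene_names %||% gene_ids
  barcodes <- barcodes %||% colnames(x)
  assert_that(!is.null(gene_ids) && !is.null(barcodes),
              "gene ids and barcodes are required")
  assert_that(length(gene_ids) == nrow(x) && length(barcodes) == ncol(x),
              "gene/barcode lengths do not match the matrix")
  if (!dir.exists(dir_path)) dir.create(dir_path, recursive = TRUE)
  ext <- if (gzip) ".gz" else ""
  m <- methods::as(methods::as(x, "CsparseMatrix"), "generalMatrix")
  mtx_tmp <- tempfile(fileext = ".mtx")
  Matrix::writeMM(m, mtx_tmp)
  put <- function(lines, base) {
    target <- file.path(dir_path, paste0(base, ext))
    con <- if (gzip) gzfile(target, "w") else file(target, "w")
    writeLines(lines, con)
    close(con)
  }
  put(readLines(mtx_tmp), "matrix.mtx")
  unlink(mtx_tmp)
  put(paste(gene_ids, gene_names, "Gene Expression", sep = "\t"),
      "features.tsv")
  put(barcodes, "barcodes.tsv")
  invisible(dir_path)
}

#' Read a GMT gene-set collection
#'
#' One set per tab-separated line: name, description, then genes. Duplicate
#' genes within a line are removed with a warning; order is preserved.
#'
#' @param path Path to a GMT file (optionally gzipped).
#' @return A named list of character vectors with attribute `provenance`, a
#'   data frame recording source and description per set.
#' @export
read_gmt <- function(path) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  lines <- readLines(gzfile_if_needed(path))
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  prov <- list()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    assert_that(length(fields) >= 3,
                paste0("GMT line with fewer than 3 fields: ",
                       substr(ln, 1, 40)))
    nm <- fields[1]
    genes <- fields[-c(1, 2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate genes in set '", nm, "' removed")
      genes <- unique(genes)
    }
    assert_that(length(genes) > 0, paste0("empty gene set: ", nm))
    sets[[nm]] <- genes
    prov[[nm]] <- data.frame(set = nm, source = "gmt",
                             description = fields[2],
                             stringsAsFactors = FALSE)
  }
  attr(sets, "provenance") <- if (length(prov)) {
    do.call(rbind, unname(prov))
  } else {
    data.frame(set = character(), source = character(),
               description = character())
  }
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional per-set description (defaults to "na").
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  assert_that(length(sets) > 0 && !is.null(names(sets)),
              "`sets` must be a non-empty named list")
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
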
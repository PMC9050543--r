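#' Construct a CountAssay
#'
#' The central container of the package: a sparse genes x barcodes UMI
#' count matrix together with per-gene and per-barcode metadata. It is the
#' return type of the count simulators and the input of the QC,
#' composition, trajectory, differential-expression and annotation modules.
#'
#' @param counts sparse (or dense) non-negative integer matrix, genes in
#'   rows and barcodes in columns. Row and column names are kept; when
#'   absent they are taken from the metadata tables.
#' @param gene_meta data.frame with one row per gene. Must contain
#'   `gene_id`; logical columns `is_mito` and `is_ribo` are added (all
#'   `FALSE`) when missing.
#' @param barcode_meta data.frame with one row per barcode. Must contain
#'   `barcode` and `sample`; `condition` (when present) must be one of
#'   `"control"` or `"case"`. Optional well-known columns: `age`, `pmi`,
#'   `cell_type`, `umap_1`, `umap_2`, `doublet_score`, `is_doublet`.
#' @return object of class `count_assay`: a list with elements `counts`,
#'   `gene_meta`, `barcode_meta`.
#' @examples
#' m <- Matrix::rsparsematrix(10, 4, 0.5, rand.x = function(n) rpois(n, 3))
#' m@x <- abs(m@x)
#' a <- count_assay(m,
#'   gene_meta = data.frame(gene_id = paste0("g", 1:10)),
#'   barcode_meta = data.frame(barcode = paste0("bc", 1:4), sample = "s1"))
#' dim(a)
#' @export
count_assay <- function(counts, gene_meta, barcode_meta) {
  if (!inherits(counts, "Matrix"))
    counts <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  .sn_assert(is.data.frame(gene_meta) && "gene_id" %in% names(gene_meta),
             "gene_meta must be a data.frame with a 'gene_id' column")
  .sn_assert(is.data.frame(barcode_meta) &&
               all(c("barcode", "sample") %in% names(barcode_meta)),
             "barcode_meta must be a data.frame with 'barcode' and 'sample'")
  .sn_assert(nrow(counts) == nrow(gene_meta),
             "counts has ", nrow(counts), " rows but gene_meta has ",
             nrow(gene_meta))
  .sn_assert(ncol(counts) == nrow(barcode_meta),
             "counts has ", ncol(counts), " columns but barcode_meta has ",
             nrow(barcode_meta))
  .sn_assert(length(counts@x) == 0L || min(counts@x) >= 0,
             "counts must be non-negative")
  .sn_assert(length(counts@x) == 0L || all(counts@x == round(counts@x)),
             "counts must be integers")
  if (!"is_mito" %in% names(gene_meta)) gene_meta$is_mito <- FALSE
  if (!"is_ribo" %in% names(gene_meta)) gene_meta$is_ribo <- FALSE
  if ("condition" %in% names(barcode_meta)) {
    bad <- setdiff(unique(as.character(barcode_meta$condition)),
                   c("control", "case"))
    .sn_assert(length(bad) == 0L,
               "condition must be 'control' or 'case'; found: ",
               paste(bad, collapse = ", "))
  }
  rownames(counts) <- as.character(gene_meta$gene_id)
  colnames(counts) <- as.character(barcode_meta$barcode)
  rownames(gene_meta) <- NULL
  rownames(barcode_meta) <- NULL
  structure(list(counts = counts, gene_meta = gene_meta,
                 barcode_meta = barcode_meta),
            class = "count_assay")
}

#' @export
dim.count_assay <- function(x) dim(x$counts)

#' @exportS3Method base::print
print.count_assay <- function(x, ...) {
  cat("count_assay:", nrow(x$counts), "genes x", ncol(x$counts),
      "barcodes\n")
  if ("sample" %in% names(x$barcode_meta))
    cat("  samples:", length(unique(x$barcode_meta$sample)), "\n")
  if ("cell_type" %in% names(x$barcode_meta))
    cat("  cell types:",
        length(unique(stats::na.omit(x$barcode_meta$cell_type))), "\n")
  invisible(x)
}

#' Subset a CountAssay by gene and/or barcode index
#'
#' @param x count_assay
#' @param genes,barcodes integer, logical or character indices; `NULL`
#'   keeps everything.
#' @return count_assay
#' @export
subset_assay <- function(x, genes = NULL, barcodes = NULL) {
  .sn_assert(inherits(x, "count_assay"), "x must be a count_assay")
  gi <- if (is.null(genes)) seq_len(nrow(x$counts)) else genes
  bi <- if (is.null(barcodes)) seq_len(ncol(x$counts)) else barcodes
  if (is.character(gi)) gi <- match(gi, x$gene_meta$gene_id)
  if (is.character(bi)) bi <- match(bi, x$barcode_meta$barcode)
  count_assay(x$counts[gi, bi, drop = FALSE],
              x$gene_meta[gi, , drop = FALSE],
              x$barcode_meta[bi, , drop = FALSE])
}

#' Write a CountAssay as a CellRanger-style MatrixMarket triplet
#'
#' Writes `matrix.mtx`, `features.tsv`, `barcodes.tsv` plus a
#' `metadata.tsv` with the full barcode table, mirroring the on-disk
#' layout emitted by droplet-based quantification pipelines.
#'
#' @param x count_assay
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_count_dir <- function(x, dir) {
  .sn_assert(inherits(x, "count_assay"), "x must be a count_assay")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  write.table(x$gene_meta, file.path(dir, "features.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(as.character(x$barcode_meta$barcode),
             file.path(dir, "barcodes.tsv"))
  write.table(x$barcode_meta, file.path(dir, "metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a CountAssay from a MatrixMarket triplet directory
#'
#' Accepts the layout written by [write_count_dir()]: `matrix.mtx` with
#' `features.tsv` (header, `gene_id` column) and either a full
#' `metadata.tsv` or a bare `barcodes.tsv`.
#'
#' @param dir directory path.
#' @return count_assay
#' @export
read_count_dir <- function(dir) {
  .sn_assert(file.exists(file.path(dir, "matrix.mtx")),
             "no matrix.mtx under ", dir)
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- read.delim(file.path(dir, "features.tsv"),
                      stringsAsFactors = FALSE)
  meta_path <- file.path(dir, "metadata.tsv")
  if (file.exists(meta_path)) {
    bc <- read.delim(meta_path, stringsAsFactors = FALSE)
  } else {
    bc <- data.frame(barcode = readLines(file.path(dir, "barcodes.tsv")),
                     sample = "unknown", stringsAsFactors = FALSE)
  }
  count_assay(m, genes, bc)
}
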
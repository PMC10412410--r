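#' Read a raw count matrix into a SingleCellExperiment
#'
#' Reads either a 10x-style Matrix Market triplet directory
#' (`matrix.mtx[.gz]` + `barcodes.tsv[.gz]` + `features.tsv[.gz]` or
#' `genes.tsv[.gz]`) or a dense TSV with cells as rows, genes as columns and
#' a header row of gene ids. On-disk MTX follows the 10x convention of genes
#' as rows and cells as columns; either way the result is a
#' [SingleCellExperiment::SingleCellExperiment] with a sparse `counts` assay
#' in the Bioconductor orientation (genes as rows, cells as columns),
#' `colnames` the cell barcodes and `rownames` the gene ids. Cell order on
#' disk is preserved exactly: it is the contract by which labels, embeddings
#' and reports are aligned.
#'
#' @param path Directory containing the MTX triplet, a path to a
#'   `matrix.mtx[.gz]` file with sidecars alongside, or a dense TSV file.
#' @param layout `"auto"` (default; directories and `.mtx` files are treated
#'   as triplets, anything else as dense TSV), `"mtx_triplet"`, or
#'   `"dense_tsv"`.
#' @return A `SingleCellExperiment` with assay `counts`.
#' @examples
#' tmp <- tempfile(fileext = ".tsv")
#' m <- matrix(rpois(12, 2), nrow = 3,
#'             dimnames = list(paste0("cell", 1:3), paste0("g", 1:4)))
#' write.table(m, tmp, sep = "\t", quote = FALSE, col.names = NA)
#' sce <- readCounts(tmp)
#' dim(sce)  # 4 genes x 3 cells
#' @export
readCounts <- function(path, layout = c("auto", "mtx_triplet", "dense_tsv")) {
    layout <- match.arg(layout)
    if (!file.exists(path))
        stop("path does not exist: ", path)
    if (layout == "auto") {
        layout <- if (dir.exists(path) || grepl("\\.mtx(\\.gz)?$", path))
            "mtx_triplet" else "dense_tsv"
    }
    if (layout == "mtx_triplet") .readMtxTriplet(path) else .readDenseTsv(path)
}

.findSidecar <- function(dir, stems) {
    for (stem in stems) {
        for (ext in c("", ".gz")) {
            f <- file.path(dir, paste0(stem, ext))
            if (file.exists(f)) return(f)
        }
    }
    NULL
}

.readMtxTriplet <- function(path) {
    if (dir.exists(path)) {
        dir <- path
        mtx <- .findSidecar(dir, c("matrix.mtx"))
    } else {
        dir <- dirname(path)
        mtx <- path
    }
    if (is.null(mtx))
        stop("format error: no matrix.mtx[.gz] found in ", path)
    bc  <- .findSidecar(dir, c("barcodes.tsv"))
    ft  <- .findSidecar(dir, c("features.tsv", "genes.tsv"))
    if (is.null(bc))
        stop("format error: missing barcodes.tsv[.gz] alongside ", mtx)
    if (is.null(ft))
        stop("format error: missing features.tsv[.gz] or genes.tsv[.gz] ",
             "alongside ", mtx)

    m <- Matrix::readMM(mtx)  # genes x cells on disk (10x convention)
    barcodes <- utils::read.table(bc, sep = "\t", header = FALSE,
                                  stringsAsFactors = FALSE)[[1]]
    feat <- utils::read.table(ft, sep = "\t", header = FALSE,
                              stringsAsFactors = FALSE)
    gene_ids <- feat[[1]]
    gene_names <- if (ncol(feat) >= 2) feat[[2]] else feat[[1]]

    if (length(barcodes) != ncol(m))
        stop("integrity error: ", length(barcodes), " barcodes but matrix has ",
             ncol(m), " cell columns")
    if (length(gene_ids) != nrow(m))
        stop("integrity error: ", length(gene_ids), " features but matrix has ",
             nrow(m), " gene rows")
    .validateCountValues(m)
    if (anyDuplicated(barcodes))
        stop("validation error: duplicated cell barcodes")
    if (anyDuplicated(gene_ids))
        stop("validation error: duplicated gene ids")

    counts <- methods::as(m, "CsparseMatrix")
    dimnames(counts) <- list(gene_ids, barcodes)
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts))
    SummarizedExperiment::rowData(sce)$gene_name <- gene_names
    sce
}

.readDenseTsv <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df)  # cells x genes on disk
    .validateCountValues(m)
    if (anyDuplicated(rownames(m)))
        stop("validation error: duplicated cell ids")
    if (anyDuplicated(colnames(m)))
        stop("validation error: duplicated gene ids")
    counts <- methods::as(Matrix::Matrix(t(m), sparse = TRUE), "CsparseMatrix")
    SingleCellExperiment::SingleCellExperiment(assays = list(counts = counts))
}

.validateCountValues <- function(m) {
    v <- if (methods::is(m, "sparseMatrix")) m@x else as.numeric(m)
    if (length(v)) {
        if (any(v < 0))
            stop("validation error: negative count entries")
        if (any(abs(v - round(v)) > 1e-8))
            stop("validation error: non-integral count entries")
    }
    invisible(TRUE)
}

#' Write a 10x-style MTX triplet
#'
#' Writes `matrix.mtx`, `barcodes.tsv` and `features.tsv` (gene id and
#' display name) into `dir`, in the genes-by-cells orientation that
#' [readCounts()] expects.
#'
#' @param sce A `SingleCellExperiment` with a `counts` assay.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCounts <- function(sce, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    counts <- SummarizedExperiment::assay(sce, "counts")
    Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                    file.path(dir, "matrix.mtx"))
    writeLines(colnames(sce), file.path(dir, "barcodes.tsv"))
    rd <- SummarizedExperiment::rowData(sce)
    gene_names <- if ("gene_name" %in% colnames(rd)) rd$gene_name
                  else rownames(sce)
    utils::write.table(data.frame(rownames(sce), gene_names),
                       file.path(dir, "features.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(dir)
}

#' Read and write per-cell label tables
#'
#' Labels travel as a two-column TSV with header `cell_id<TAB>label`.
#' `writeLabels()` accepts either such a `data.frame` or a factor/character
#' vector named by cell id. Reading and writing are exact inverses.
#'
#' @param labels A `data.frame` with columns `cell_id` and `label`, or a
#'   named factor/character vector.
#' @param path File path.
#' @return `readLabels()` returns a `data.frame` with character columns
#'   `cell_id` and `label`; `writeLabels()` returns `path` invisibly.
#' @export
writeLabels <- function(labels, path) {
    df <- .asLabelTable(labels)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' @rdname writeLabels
#' @export
readLabels <- function(path) {
    if (!file.exists(path)) stop("path does not exist: ", path)
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = "character",
                            stringsAsFactors = FALSE)
    if (!all(c("cell_id", "label") %in% colnames(df)))
        stop("format error: expected header cell_id<TAB>label in ", path)
    if (anyDuplicated(df$cell_id))
        stop("validation error: duplicated cell_id in ", path)
    df[, c("cell_id", "label")]
}

.asLabelTable <- function(labels) {
    if (is.data.frame(labels)) {
        stopifnot(all(c("cell_id", "label") %in% colnames(labels)))
        data.frame(cell_id = as.character(labels$cell_id),
                   label = as.character(labels$label),
                   stringsAsFactors = FALSE)
    } else {
        if (is.null(names(labels)))
            stop("labels vector must be named by cell id")
        data.frame(cell_id = names(labels),
                   label = as.character(labels),
                   stringsAsFactors = FALSE)
    }
}

# Convert a label table (or named vector) to a factor aligned with cell ids.
.alignLabels <- function(labels, cell_ids) {
    if (is.data.frame(labels)) {
        labels <- stats::setNames(as.character(labels$label),
                                  as.character(labels$cell_id))
    }
    if (!is.null(names(labels))) {
        missing <- setdiff(cell_ids, names(labels))
        if (length(missing))
            stop("labels missing for ", length(missing), " cells (e.g. ",
                 missing[1], ")")
        labels <- labels[cell_ids]
    } else if (length(labels) != length(cell_ids)) {
        stop("unnamed labels must match cell count")
    }
    factor(as.character(labels))
}
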
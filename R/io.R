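#' Load an expression matrix into an expression store
#'
#' Supported formats:
#' \describe{
#'   \item{`mtx`}{Matrix Market coordinate file plus plain-text sidecar name
#'     files (CellRanger-style triplet). Sidecars default to `genes.tsv` and
#'     `barcodes.tsv` next to the matrix; the first tab-separated field of
#'     each line is used.}
#'   \item{`csv` / `tsv`}{Dense table with a header row of gene names and the
#'     cell name in the first column.}
#' }
#' Whatever the on-disk orientation, the returned store is cells x genes.
#'
#' @param path path to the matrix file.
#' @param format one of `"mtx"`, `"csv"`, `"tsv"`.
#' @param orientation `"cells_x_genes"` (default) or `"genes_x_cells"`,
#'   describing the file, not the result.
#' @param gene_file,cell_file sidecar name files for `mtx`.
#' @return an [expression_store()].
#' @export
load_expression <- function(path,
                            format = c("mtx", "csv", "tsv"),
                            orientation = c("cells_x_genes", "genes_x_cells"),
                            gene_file = NULL, cell_file = NULL) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("matrix file not found: ", path)
  if (format == "mtx") {
    dirn <- dirname(path)
    if (is.null(gene_file)) gene_file <- file.path(dirn, "genes.tsv")
    if (is.null(cell_file)) cell_file <- file.path(dirn, "barcodes.tsv")
    if (!file.exists(gene_file)) stop("gene sidecar file not found: ", gene_file)
    if (!file.exists(cell_file)) stop("cell sidecar file not found: ", cell_file)
    check_mtx_entry_count(path)
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) stop("malformed Matrix Market file '",
                                           path, "': ", conditionMessage(e)))
    first_field <- function(f)
      vapply(strsplit(readLines(f), "\t", fixed = TRUE), `[[`, "", 1L)
    genes <- first_field(gene_file)
    cells <- first_field(cell_file)
    if (orientation == "genes_x_cells") m <- Matrix::t(m)
    if (nrow(m) != length(cells))
      stop(sprintf("cell sidecar mismatch: matrix has %d cells, sidecar %d",
                   nrow(m), length(cells)))
    if (ncol(m) != length(genes))
      stop(sprintf("gene sidecar mismatch: matrix has %d genes, sidecar %d",
                   ncol(m), length(genes)))
    expression_store(m, genes, cells)
  } else {
    sep <- if (format == "csv") "," else "\t"
    dt <- data.table::fread(path, sep = sep, header = TRUE,
                            data.table = FALSE)
    axis_names <- as.character(dt[[1L]])
    m <- as.matrix(dt[, -1L, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric entries in ", path)
    if (orientation == "genes_x_cells") {
      expression_store(t(m), gene_names = axis_names,
                       cell_names = colnames(dt)[-1L])
    } else {
      expression_store(m, gene_names = colnames(dt)[-1L],
                       cell_names = axis_names)
    }
  }
}

# The reference reader silently accepts coordinate files whose declared entry
# count disagrees with the data lines present; treat that as malformed.
check_mtx_entry_count <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  body <- lines[!startsWith(lines, "%")]
  if (!length(body)) stop("malformed Matrix Market file '", path, "': empty")
  hdr <- suppressWarnings(as.numeric(strsplit(trimws(body[1L]), "\\s+")[[1L]]))
  if (length(hdr) == 3L && !anyNA(hdr) && hdr[3L] != length(body) - 1L)
    stop(sprintf(
      "malformed Matrix Market file '%s': header declares %d entries, %d present",
      path, hdr[3L], length(body) - 1L))
  invisible(NULL)
}

#' Write an expression store
#'
#' Inverse of [load_expression()] for round-tripping: `mtx` writes the matrix
#' plus `genes.tsv` / `barcodes.tsv` sidecars into a directory; `csv`/`tsv`
#' write a dense table (header = gene names, first column = cell names).
#'
#' @param store an [expression_store()].
#' @param path output file (`csv`/`tsv`) or directory (`mtx`).
#' @param format one of `"mtx"`, `"csv"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(store, path, format = c("mtx", "csv", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(store, "expression_store"))
  if (store$backing == "on-disk")
    stop("write_expression expects an in-memory store")
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(store$mat, "CsparseMatrix"),
                    file.path(path, "matrix.mtx"))
    writeLines(store$gene_names, file.path(path, "genes.tsv"))
    writeLines(store$cell_names, file.path(path, "barcodes.tsv"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    m <- as.matrix(store$mat)
    dt <- data.frame(cell = store$cell_names, m, check.names = FALSE)
    colnames(dt) <- c("cell", store$gene_names)
    data.table::fwrite(dt, path, sep = sep)
  }
  invisible(path)
}

#' Load per-cell class labels
#'
#' Two layouts: a headerless file with one integer label per line, aligned to
#' the store's cell order; or a two-column CSV `cell_name,label` (with or
#' without a header), matched to the store by cell name.
#'
#' @param path label file.
#' @param store an [expression_store()] whose cell order the labels must match.
#' @return an integer vector of length `n_cells`.
#' @export
load_labels <- function(path, store) {
  if (!file.exists(path)) stop("label file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!any(grepl(",", lines, fixed = TRUE))) {
    lab <- suppressWarnings(as.integer(lines))
    if (anyNA(lab)) stop("non-integer entries in label file ", path)
    if (length(lab) != store$n_cells)
      stop(sprintf("label file has %d entries but store has %d cells",
                   length(lab), store$n_cells))
    return(lab)
  }
  parts <- strsplit(lines, ",", fixed = TRUE)
  nm <- vapply(parts, `[[`, "", 1L)
  vl <- vapply(parts, `[[`, "", 2L)
  if (is.na(suppressWarnings(as.integer(vl[1L])))) { # header row
    nm <- nm[-1L]; vl <- vl[-1L]
  }
  lab <- suppressWarnings(as.integer(vl))
  if (anyNA(lab)) stop("non-integer labels in ", path)
  pos <- match(store$cell_names, nm)
  if (anyNA(pos)) stop("label file is missing some cells of the store")
  lab[pos]
}

#' Write per-cell labels as a two-column CSV
#' @param labels integer labels, one per cell of `store`.
#' @param store the matching [expression_store()].
#' @param path output CSV path.
#' @export
write_labels <- function(labels, store, path) {
  stopifnot(length(labels) == store$n_cells)
  data.table::fwrite(data.frame(cell = store$cell_names,
                                label = as.integer(labels)), path)
  invisible(path)
}
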
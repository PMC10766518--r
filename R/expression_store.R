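#' Expression stores: cells-by-genes matrices with block access
#'
#' An `expression_store` wraps a cells x genes expression matrix with named
#' axes and a block-access contract: any rectangular block (a subset of cells
#' crossed with a subset of genes) can be materialized as a dense base matrix
#' without ever densifying the full data. Three backings are supported:
#' in-memory sparse (`Matrix::dgCMatrix`), in-memory dense (base matrix), and
#' on-disk (a binary CSR + CSC layout created by [write_disk_store()]), which
#' keeps resident memory at the size of the blocks actually requested.
#'
#' Every store carries an instrumentation counter of "resident" entries:
#' [fetch_block()] adds the dense size of the block it hands out and
#' [release_block()] subtracts it, so that a driver run can assert the memory
#' contract (at most an all-cells x selected-genes block plus a
#' cell-set x all-genes block live at once).
#'
#' @param mat a cells x genes matrix (base matrix or any `Matrix` class).
#' @param gene_names character vector of unique gene names, one per column.
#' @param cell_names character vector of unique cell names, one per row.
#' @return an object of class `expression_store`.
#' @examples
#' m <- matrix(c(1, 0, 2, 0, 3, 0), nrow = 2, byrow = TRUE)
#' st <- expression_store(m, paste0("g", 1:3), paste0("c", 1:2))
#' fetch_block(st, 1:2, c(1, 3))
#' @export
expression_store <- function(mat, gene_names = colnames(mat),
                             cell_names = rownames(mat)) {
  if (is.null(gene_names)) gene_names <- paste0("gene", seq_len(ncol(mat)))
  if (is.null(cell_names)) cell_names <- paste0("cell", seq_len(nrow(mat)))
  gene_names <- as.character(gene_names)
  cell_names <- as.character(cell_names)
  if (length(gene_names) != ncol(mat))
    stop("gene_names length does not match number of columns")
  if (length(cell_names) != nrow(mat))
    stop("cell_names length does not match number of rows")
  if (anyDuplicated(gene_names)) stop("gene_names must be unique")
  if (anyDuplicated(cell_names)) stop("cell_names must be unique")
  if (inherits(mat, "Matrix")) {
    if (any(!is.finite(mat@x))) stop("expression values must be finite")
    mat <- methods::as(methods::as(mat, "CsparseMatrix"), "generalMatrix")
    backing <- "in-memory-sparse"
  } else {
    mat <- as.matrix(mat)
    if (!is.numeric(mat)) stop("expression values must be numeric")
    if (any(!is.finite(mat))) stop("expression values must be finite")
    backing <- "in-memory-dense"
  }
  dimnames(mat) <- NULL
  structure(
    list(backing = backing, n_cells = nrow(mat), n_genes = ncol(mat),
         gene_names = gene_names, cell_names = cell_names, mat = mat,
         counter = new_counter()),
    class = "expression_store")
}

new_counter <- function() {
  e <- new.env(parent = emptyenv())
  e$resident <- 0
  e$peak <- 0
  e
}

#' @export
print.expression_store <- function(x, ...) {
  cat(sprintf("expression_store: %d cells x %d genes [%s]\n",
              x$n_cells, x$n_genes, x$backing))
  invisible(x)
}

#' @export
dim.expression_store <- function(x) c(x$n_cells, x$n_genes)

check_indices <- function(idx, n, what) {
  idx <- as.integer(idx)
  if (length(idx) && (min(idx) < 1L || max(idx) > n))
    stop(sprintf("%s index out of range [1, %d]", what, n))
  idx
}

#' Materialize a dense block of an expression store
#'
#' Returns the dense `length(cell_indices)` x `length(gene_indices)` block.
#' For an on-disk store only the requested rows or columns are read from disk;
#' the full matrix is never loaded. The block's dense entry count is added to
#' the store's resident-entry instrumentation until [release_block()] is
#' called on it.
#'
#' @param store an [expression_store()].
#' @param cell_indices,gene_indices 1-based integer indices.
#' @return a dense base matrix with an `"asvm_entries"` attribute used by
#'   [release_block()].
#' @export
fetch_block <- function(store, cell_indices, gene_indices) {
  stopifnot(inherits(store, "expression_store"))
  ci <- check_indices(cell_indices, store$n_cells, "cell")
  gi <- check_indices(gene_indices, store$n_genes, "gene")
  block <- if (store$backing == "on-disk") {
    disk_block(store, ci, gi)
  } else {
    as.matrix(store$mat[ci, gi, drop = FALSE])
  }
  dimnames(block) <- NULL
  n <- length(block)
  store$counter$resident <- store$counter$resident + n
  store$counter$peak <- max(store$counter$peak, store$counter$resident)
  attr(block, "asvm_entries") <- n
  block
}

#' Release a block fetched from a store
#'
#' Subtracts the block's entry count from the store's resident-entry counter.
#' Purely an instrumentation aid; the block itself is ordinary memory managed
#' by R's garbage collector.
#'
#' @param store the store the block came from.
#' @param block a matrix returned by [fetch_block()].
#' @export
release_block <- function(store, block) {
  n <- attr(block, "asvm_entries")
  if (!is.null(n))
    store$counter$resident <- max(0, store$counter$resident - n)
  invisible(NULL)
}

#' Peak resident entries observed on a store
#' @param store an [expression_store()].
#' @return the maximum simultaneous dense entry count handed out.
#' @export
peak_resident_entries <- function(store) store$counter$peak

#' Reset a store's resident-entry instrumentation
#' @param store an [expression_store()].
#' @export
reset_resident_counter <- function(store) {
  store$counter$resident <- 0
  store$counter$peak <- 0
  invisible(NULL)
}

# ---- on-disk backing -------------------------------------------------------
# Layout under `dir`: meta.json (dims), gene_names.txt, cell_names.txt, and
# six flat binary arrays holding the matrix twice, once row-compressed and
# once column-compressed, so that both all-cells-few-genes and
# few-cells-all-genes blocks touch only the data they need:
#   csr_ptr.bin (double, n_cells+1), csr_idx.bin (int, nnz, 0-based cols),
#   csr_val.bin (double, nnz); csc_ptr.bin / csc_idx.bin / csc_val.bin
#   analogously by column.

#' Write an expression store to an on-disk block-access layout
#'
#' Serializes the matrix to a directory holding row-compressed and
#' column-compressed binary sparse arrays plus name sidecars, enabling
#' out-of-core runs via [open_disk_store()].
#'
#' @param store an in-memory [expression_store()].
#' @param dir directory to create.
#' @return `dir`, invisibly.
#' @export
write_disk_store <- function(store, dir) {
  stopifnot(inherits(store, "expression_store"))
  if (store$backing == "on-disk") stop("store is already on disk")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(methods::as(store$mat, "CsparseMatrix"), "generalMatrix")
  # CSC comes for free from dgCMatrix; CSR from its transpose
  mt <- methods::as(Matrix::t(m), "CsparseMatrix")
  write_bin <- function(x, f, type) {
    con <- file(file.path(dir, f), "wb")
    on.exit(close(con))
    writeBin(if (type == "double") as.double(x) else as.integer(x), con,
             size = if (type == "double") 8L else 4L)
  }
  write_bin(m@p, "csc_ptr.bin", "double")
  write_bin(m@i, "csc_idx.bin", "integer")
  write_bin(m@x, "csc_val.bin", "double")
  write_bin(mt@p, "csr_ptr.bin", "double")
  write_bin(mt@i, "csr_idx.bin", "integer")
  write_bin(mt@x, "csr_val.bin", "double")
  writeLines(store$gene_names, file.path(dir, "gene_names.txt"))
  writeLines(store$cell_names, file.path(dir, "cell_names.txt"))
  jsonlite::write_json(
    list(n_cells = store$n_cells, n_genes = store$n_genes,
         nnz = length(m@x), format = "activesvm-disk-store-v1"),
    file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Open an on-disk expression store
#'
#' @param dir a directory written by [write_disk_store()].
#' @return an `expression_store` with `backing == "on-disk"`. Pointer arrays
#'   (one value per cell and per gene) are held in memory; values and index
#'   arrays stay on disk and are read blockwise.
#' @export
open_disk_store <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  read_bin <- function(f, type, n) {
    con <- file(file.path(dir, f), "rb")
    on.exit(close(con))
    readBin(con, what = if (type == "double") "double" else "integer",
            n = n, size = if (type == "double") 8L else 4L)
  }
  n_cells <- meta$n_cells
  n_genes <- meta$n_genes
  structure(
    list(backing = "on-disk", n_cells = n_cells, n_genes = n_genes,
         gene_names = readLines(file.path(dir, "gene_names.txt")),
         cell_names = readLines(file.path(dir, "cell_names.txt")),
         dir = dir,
         csr_ptr = read_bin("csr_ptr.bin", "double", n_cells + 1L),
         csc_ptr = read_bin("csc_ptr.bin", "double", n_genes + 1L),
         counter = new_counter()),
    class = "expression_store")
}

# Read one compressed slice (row i of CSR or column j of CSC) from disk.
read_slice <- function(dir, prefix, ptr, i, idx_con, val_con) {
  lo <- ptr[i]
  n <- ptr[i + 1L] - lo
  if (n == 0) return(list(idx = integer(0), val = double(0)))
  seek(idx_con, where = lo * 4, origin = "start")
  seek(val_con, where = lo * 8, origin = "start")
  list(idx = readBin(idx_con, "integer", n = n, size = 4L) + 1L,
       val = readBin(val_con, "double", n = n, size = 8L))
}

disk_block <- function(store, ci, gi) {
  out <- matrix(0, length(ci), length(gi))
  if (!length(ci) || !length(gi)) return(out)
  use_rows <- length(ci) <= length(gi)
  prefix <- if (use_rows) "csr" else "csc"
  idx_con <- file(file.path(store$dir, paste0(prefix, "_idx.bin")), "rb")
  val_con <- file(file.path(store$dir, paste0(prefix, "_val.bin")), "rb")
  on.exit({ close(idx_con); close(val_con) })
  if (use_rows) {
    pos <- integer(store$n_genes)
    pos[gi] <- seq_along(gi)
    for (r in seq_along(ci)) {
      sl <- read_slice(store$dir, prefix, store$csr_ptr, ci[r], idx_con, val_con)
      keep <- pos[sl$idx] > 0L
      if (any(keep)) out[r, pos[sl$idx[keep]]] <- sl$val[keep]
    }
  } else {
    pos <- integer(store$n_cells)
    pos[ci] <- seq_along(ci)
    for (cc in seq_along(gi)) {
      sl <- read_slice(store$dir, prefix, store$csc_ptr, gi[cc], idx_con, val_con)
      keep <- pos[sl$idx] > 0L
      if (any(keep)) out[pos[sl$idx[keep]], cc] <- sl$val[keep]
    }
  }
  out
}
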
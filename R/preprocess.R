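#' Remove all-zero genes and cells
#'
#' Genes (columns) with no counts in any cell and cells (rows) with no counts
#' in any gene carry no information for classification and are removed before
#' normalization. Index maps back to the original coordinates are returned so
#' downstream gene reports can be traced to the input matrix.
#'
#' @param store an in-memory [expression_store()].
#' @return a list with elements `store` (filtered), `kept_gene_indices`,
#'   `kept_cell_indices` (1-based positions in the input store).
#' @export
drop_empty <- function(store) {
  stopifnot(inherits(store, "expression_store"))
  if (store$backing == "on-disk") stop("drop_empty expects an in-memory store")
  m <- store$mat
  gene_nz <- if (inherits(m, "Matrix")) Matrix::colSums(m != 0) else colSums(m != 0)
  cell_nz <- if (inherits(m, "Matrix")) Matrix::rowSums(m != 0) else rowSums(m != 0)
  keep_g <- which(gene_nz > 0)
  keep_c <- which(cell_nz > 0)
  if (!length(keep_g) || !length(keep_c))
    stop("degenerate input: all expression values are zero")
  out <- expression_store(m[keep_c, keep_g, drop = FALSE],
                          store$gene_names[keep_g], store$cell_names[keep_c])
  list(store = out, kept_gene_indices = keep_g, kept_cell_indices = keep_c)
}

#' Per-gene column normalization followed by log transform
#'
#' Each gene column is divided by its total over all cells, then transformed
#' elementwise as `log1p(value / pseudocount)` (natural log; with the default
#' pseudocount of 1 this is the usual `log(1 + value)`). The scaled form keeps
#' zeros exactly zero for any pseudocount, preserving sparsity. After the
#' normalization step `sum(expm1(column))` equals 1 for every gene when
#' `pseudocount = 1`.
#'
#' @param store an in-memory [expression_store()] of non-negative values with
#'   empties already dropped.
#' @param pseudocount positive scale inside the log; default 1.
#' @return a transformed [expression_store()].
#' @export
normalize_column_log <- function(store, pseudocount = 1) {
  stopifnot(inherits(store, "expression_store"), pseudocount > 0)
  if (store$backing == "on-disk")
    stop("normalize_column_log expects an in-memory store")
  m <- store$mat
  if (inherits(m, "Matrix")) {
    if (any(m@x < 0)) stop("negative input values")
    tot <- Matrix::colSums(m)
    if (any(tot == 0)) stop("all-zero gene column; run drop_empty first")
    m <- methods::as(m %*% Matrix::Diagonal(x = 1 / tot), "CsparseMatrix")
    m@x <- log1p(m@x / pseudocount)
  } else {
    if (any(m < 0)) stop("negative input values")
    tot <- colSums(m)
    if (any(tot == 0)) stop("all-zero gene column; run drop_empty first")
    m <- log1p(sweep(m, 2L, tot, "/") / pseudocount)
  }
  expression_store(m, store$gene_names, store$cell_names)
}

#' Scale each cell vector to unit Euclidean norm
#'
#' Cells (rows) are individually l2-normalized. All-zero rows are returned
#' unchanged with a warning, since they have no direction to preserve.
#'
#' @param store an in-memory [expression_store()].
#' @return an [expression_store()] whose nonzero rows have norm 1 (1e-9).
#' @export
l2_normalize_rows <- function(store) {
  stopifnot(inherits(store, "expression_store"))
  if (store$backing == "on-disk")
    stop("l2_normalize_rows expects an in-memory store")
  m <- store$mat
  nrm <- if (inherits(m, "Matrix")) sqrt(Matrix::rowSums(m^2)) else sqrt(rowSums(m^2))
  zero <- nrm == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero cell row(s) left unchanged by l2 normalization")
    nrm[zero] <- 1
  }
  m <- if (inherits(m, "Matrix")) Matrix::Diagonal(x = 1 / nrm) %*% m
       else m / nrm
  expression_store(m, store$gene_names, store$cell_names)
}

#' Apply a named preprocessing dialect
#'
#' Two presets mirror common single-cell practice: `"colnorm_log_l2"`
#' (per-gene column normalization, log1p, then per-cell l2 scaling — used for
#' UMI count matrices of moderate size) and `"l2_only"` (per-cell l2 scaling
#' alone — used for very large or already-transformed matrices). `"none"`
#' passes the store through.
#'
#' @param store an in-memory [expression_store()].
#' @param dialect `"colnorm_log_l2"`, `"l2_only"`, or `"none"`.
#' @return a preprocessed [expression_store()].
#' @export
preprocess <- function(store, dialect = c("colnorm_log_l2", "l2_only", "none")) {
  dialect <- match.arg(dialect)
  switch(dialect,
         colnorm_log_l2 = l2_normalize_rows(normalize_column_log(store)),
         l2_only = l2_normalize_rows(store),
         none = store)
}

#' Random train/test split of cells
#'
#' Uniform sampling of cells without replacement into a training set of size
#' `round(train_fraction * n_cells)`; the rest is the test set. Stratified
#' (per-class proportional) splitting is available as an option. A class
#' absent from the training split triggers a warning, since the classifier
#' cannot learn it.
#'
#' @param n_cells number of cells.
#' @param labels integer class labels (length `n_cells`).
#' @param train_fraction in (0, 1); default 0.8.
#' @param seed integer seed; identical seeds give identical splits.
#' @param stratified if `TRUE`, split each class separately.
#' @return list with sorted integer `train_cell_indices`, `test_cell_indices`.
#' @export
split_train_test <- function(n_cells, labels, train_fraction = 0.8,
                             seed = 0L, stratified = FALSE) {
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must be strictly between 0 and 1")
  stopifnot(length(labels) == n_cells)
  train <- with_seed(stream_seed(seed, "split"), {
    if (stratified) {
      unlist(lapply(sort(unique(labels)), function(z) {
        idx <- which(labels == z)
        sample(idx, round(train_fraction * length(idx)))
      }))
    } else {
      sample.int(n_cells, round(train_fraction * n_cells))
    }
  })
  train <- sort(unique(as.integer(train)))
  test <- setdiff(seq_len(n_cells), train)
  missing <- setdiff(unique(labels), labels[train])
  if (length(missing))
    warning("class(es) absent from training split: ",
            paste(missing, collapse = ", "))
  list(train_cell_indices = train, test_cell_indices = test)
}
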
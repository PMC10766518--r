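#' Specification of a planted-marker synthetic count dataset
#'
#' Describes class-structured negative-binomial count data: every gene has
#' background mean `mu0`, and each class owns `markers_per_class` disjoint
#' marker genes whose mean is lifted to `fold_change * mu0` in that class's
#' cells. A Bernoulli dropout mask then zeroes each entry independently,
#' mimicking the sparsity of droplet scRNA-seq counts.
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param n_classes number of cell classes Z (>= 2).
#' @param markers_per_class planted markers per class (disjoint across
#'   classes; `n_classes * markers_per_class <= n_genes`).
#' @param proportions class proportions (default equal), summing to 1.
#' @param fold_change marker fold-change f >= 1 in the owning class; `f = 1`
#'   plants no signal (the null configuration used for calibration checks).
#' @param mu0 background negative-binomial mean (> 0).
#' @param dispersion NB dispersion phi, parameterized so that
#'   `variance = mu + phi * mu^2` (i.e. `size = 1/phi`).
#' @param dropout probability an entry is zeroed after sampling.
#' @param seed integer seed.
#' @return a `planted_spec` list.
#' @export
planted_spec <- function(n_cells = 600L, n_genes = 1000L, n_classes = 3L,
                         markers_per_class = 5L, proportions = NULL,
                         fold_change = 6, mu0 = 2, dispersion = 0.5,
                         dropout = 0.3, seed = 0L) {
  if (is.null(proportions)) proportions <- rep(1 / n_classes, n_classes)
  stopifnot(n_classes >= 2L,
            n_classes * markers_per_class <= n_genes,
            abs(sum(proportions) - 1) < 1e-8,
            fold_change >= 1, mu0 > 0, dispersion > 0,
            dropout >= 0, dropout <= 1)
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 n_classes = as.integer(n_classes),
                 markers_per_class = as.integer(markers_per_class),
                 proportions = proportions, fold_change = fold_change,
                 mu0 = mu0, dispersion = dispersion, dropout = dropout,
                 seed = as.integer(seed)),
            class = "planted_spec")
}

#' Generate a planted-marker synthetic count dataset
#'
#' Draws counts `NB(mean, size = 1/dispersion)` with the class-dependent
#' marker means of the spec, applies the dropout mask, and returns the store
#' together with the labels and the planted ground truth for recovery
#' scoring. Same seed, same matrix.
#'
#' @param spec a [planted_spec()].
#' @return list with `store` (sparse counts [expression_store()]), `labels`
#'   (integer classes `1..Z`), and `truth` (class of each cell, marker gene
#'   indices and names per class).
#' @export
generate_planted <- function(spec) {
  stopifnot(inherits(spec, "planted_spec"))
  Z <- spec$n_classes
  markers <- split(seq_len(Z * spec$markers_per_class),
                   rep(seq_len(Z), each = spec$markers_per_class))
  with_seed(stream_seed(spec$seed, "planted"), {
    labels <- sample(rep(seq_len(Z), times = diff(round(
      cumsum(c(0, spec$proportions)) * spec$n_cells))))
    mu <- matrix(spec$mu0, spec$n_cells, spec$n_genes)
    for (z in seq_len(Z))
      mu[labels == z, markers[[z]]] <- spec$fold_change * spec$mu0
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / spec$dispersion),
                     spec$n_cells, spec$n_genes)
    if (spec$dropout > 0) {
      keep <- matrix(stats::rbinom(length(mu), 1L, 1 - spec$dropout),
                     spec$n_cells, spec$n_genes)
      counts <- counts * keep
    }
    gene_names <- sprintf("g%04d", seq_len(spec$n_genes))
    store <- expression_store(
      methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
      gene_names = gene_names,
      cell_names = sprintf("cell%05d", seq_len(spec$n_cells)))
    truth <- structure(list(cell_class = labels,
                            marker_indices = markers,
                            marker_names = lapply(markers, function(i)
                              gene_names[i])),
                       class = "synthetic_truth")
    list(store = store, labels = labels, truth = truth)
  })
}

#' Fraction of planted markers recovered by a selection
#'
#' `|selected marker genes| / |all planted markers|`, matching by gene name
#' when names are given (robust to index remapping by [drop_empty()]) and by
#' index otherwise.
#'
#' @param selected_genes character gene names or integer indices.
#' @param truth the `synthetic_truth` from [generate_planted()].
#' @return recall in \[0, 1\].
#' @export
marker_recovery <- function(selected_genes, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (is.character(selected_genes)) {
    all_m <- unlist(truth$marker_names, use.names = FALSE)
  } else {
    all_m <- unlist(truth$marker_indices, use.names = FALSE)
  }
  length(intersect(selected_genes, all_m)) / length(all_m)
}
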
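# Small in-code fixtures shared across test files.

# The 1-D hard-margin toy: x = (-2, -1, 1, 2), y = (-1, -1, 1, 1).
# Its exact solution is w = 1, b = 0, functional margins (2, 1, 1, 2).
toy_1d <- function() {
  list(x = matrix(c(-2, -1, 1, 2), ncol = 1), y = c(-1L, -1L, 1L, 1L))
}

# A small planted dataset, preprocessed, with labels aligned to the store.
small_planted <- function(seed = 1L, n_cells = 150L, n_genes = 60L,
                          n_classes = 2L, markers_per_class = 3L,
                          fold_change = 6, dialect = "colnorm_log_l2") {
  sp <- planted_spec(n_cells = n_cells, n_genes = n_genes,
                     n_classes = n_classes,
                     markers_per_class = markers_per_class,
                     fold_change = fold_change, seed = seed)
  d <- generate_planted(sp)
  de <- drop_empty(d$store)
  list(store = preprocess(de$store, dialect),
       labels = d$labels[de$kept_cell_indices],
       truth = d$truth,
       kept_genes = de$kept_gene_indices)
}

# Random soft-margin toy instances for solver cross-checks: two gaussian
# clouds with a seed-dependent separation, sometimes overlapping.
random_svm_instance <- function(seed) {
  set.seed(seed)
  n <- sample(10:60, 1)
  p <- sample(1:10, 1)
  shift <- runif(1, 0.3, 2.5)
  y <- c(rep(-1L, ceiling(n / 2)), rep(1L, floor(n / 2)))
  x <- matrix(rnorm(n * p), n, p)
  x[y == 1, 1] <- x[y == 1, 1] + shift
  list(x = x, y = y, C = sample(c(0.1, 1, 10), 1))
}
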
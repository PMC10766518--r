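#' Run configuration for the active gene-selection loop
#'
#' @param strategy `"min_cell"` (accumulate and reuse misclassified cells,
#'   minimizing unique cells acquired) or `"min_complexity"` (fresh fixed-size
#'   sample each iteration, minimizing compute).
#' @param sampling `"random"` or `"balanced"` per-class cell sampling.
#' @param k target number of genes (>= 1; 0 gives an empty run).
#' @param c_budget cells acquired per iteration (>= 1).
#' @param C soft-margin SVM cost.
#' @param pool_criterion `"violators"` (dual coefficient at the cap; default)
#'   or `"violators_or_margin"` (any positive dual coefficient).
#' @param dialect preprocessing preset name (see [preprocess()]); recorded
#'   for provenance, the driver itself expects preprocessed data.
#' @param train_fraction fraction of cells in the training split.
#' @param seed root seed; every random stream is derived from it.
#' @param bootstrap_budget cells in the seeded sample used to score the
#'   first gene by 1-D training accuracy. Default `max(c_budget, 100)`
#'   (capped at the training-set size): a 1-D accuracy scan over thousands
#'   of candidate genes overfits badly on very small samples, and a noise
#'   gene as the panel seed costs several early iterations.
#' @return a `run_config` list.
#' @export
run_config <- function(strategy = c("min_complexity", "min_cell"),
                       sampling = c("random", "balanced"),
                       k = 10L, c_budget = 20L, C = 1,
                       pool_criterion = c("violators", "violators_or_margin"),
                       dialect = "colnorm_log_l2",
                       train_fraction = 0.8, seed = 0L,
                       bootstrap_budget = NULL) {
  strategy <- match.arg(strategy)
  sampling <- match.arg(sampling)
  pool_criterion <- match.arg(pool_criterion)
  stopifnot(k >= 0, c_budget >= 1, C > 0,
            train_fraction > 0, train_fraction < 1)
  if (is.null(bootstrap_budget)) bootstrap_budget <- max(c_budget, 100L)
  stopifnot(bootstrap_budget >= 2)
  structure(list(strategy = strategy, sampling = sampling, k = as.integer(k),
                 c_budget = as.integer(c_budget), C = C,
                 pool_criterion = pool_criterion, dialect = dialect,
                 train_fraction = train_fraction, seed = as.integer(seed),
                 bootstrap_budget = as.integer(bootstrap_budget)),
            class = "run_config")
}

# Seeded uniform draws from the training set until >= 2 classes are present.
sample_cells_multiclass <- function(train, labels, size, seed, what) {
  size <- min(size, length(train))
  cells <- with_seed(seed, sample(train, size))
  tries <- 0L
  while (length(unique(labels[cells])) < 2L && tries < 100L) {
    tries <- tries + 1L
    warning(what, ": single-class cell sample; augmenting with extra draws")
    extra <- with_seed(seed + tries, sample(train, min(size, length(train))))
    cells <- unique(c(cells, extra))
  }
  sort(cells)
}

#' Run the iterative active SVM gene-selection procedure
#'
#' Starting from a bootstrap gene (best 1-D training accuracy on a seeded
#' cell sample), each iteration (i) fits a linear SVM on *all* training cells
#' restricted to the selected genes, (ii) records train/test accuracy,
#' (iii) pools the margin violators and acquires a cell set per the
#' configured strategy, and (iv) adds the candidate gene whose extra
#' dimension maximally rotates the SVM margin on that cell set. The loop
#' stops at `k` genes or as soon as the pool empties (perfect training
#' classification). Identical configs and seeds give identical results.
#'
#' @param config a [run_config()].
#' @param store a preprocessed [expression_store()] (any backing).
#' @param labels integer class labels for all cells of the store.
#' @param split optional list with `train_cell_indices` and
#'   `test_cell_indices`; by default a fresh [split_train_test()] with the
#'   config's fraction and seed.
#' @param verbose emit one log line per iteration.
#' @return a `run_result`: list with `gene_indices`, `gene_names`, `records`
#'   (per-iteration data.frame: iteration, gene, gene_name, angle, train
#'   accuracy, test accuracy, cell-set size, unique cells to date), `final_state`
#'   (the last full-training SVM), `split`, `config`, `status`
#'   (`"reached_k"`, `"pool_empty"`, or `"empty_run"`), `unique_cells`
#'   (indices of every training cell examined in full).
#' @export
run_activesvm <- function(config, store, labels, split = NULL,
                          verbose = FALSE) {
  stopifnot(inherits(config, "run_config"),
            inherits(store, "expression_store"),
            length(labels) == store$n_cells)
  labels <- as.integer(labels)
  label_classes(labels)
  if (is.null(split))
    split <- split_train_test(store$n_cells, labels,
                              config$train_fraction, config$seed)
  train <- split$train_cell_indices
  test <- split$test_cell_indices
  empty_result <- function(status) {
    structure(list(gene_indices = integer(0), gene_names = character(0),
                   records = iteration_records(), final_state = NULL,
                   split = split, config = config, status = status,
                   unique_cells = integer(0)),
              class = "run_result")
  }
  if (config$k == 0L) return(empty_result("empty_run"))

  boot_cells <- sample_cells_multiclass(
    train, labels, config$bootstrap_budget,
    stream_seed(config$seed, "bootstrap"), "bootstrap")
  first <- select_first_gene(store, labels, boot_cells, config$C)
  J <- first$gene
  angles <- NA_real_
  cellset <- boot_cells          # min-cell accumulates from here
  unique_cells <- boot_cells
  records <- list()
  status <- "reached_k"
  lab_train <- labels[train]

  repeat {
    blockJ <- fetch_block(store, train, J)
    state <- fit_linear_svm(blockJ, lab_train, config$C)
    train_acc <- predict_and_score(state, blockJ, lab_train)
    block_test <- fetch_block(store, test, J)
    test_acc <- if (length(test)) predict_and_score(state, block_test, labels[test]) else NA_real_
    release_block(store, block_test)
    it <- length(J)
    records[[it]] <- data.frame(
      iteration = it, gene = J[it], gene_name = store$gene_names[J[it]],
      angle = angles[it], train_accuracy = train_acc,
      test_accuracy = test_acc, cellset_size = length(cellset),
      unique_cells = length(unique_cells))
    if (verbose)
      message(sprintf(
        "iter %d: gene %s angle %.4f train %.3f test %.3f |I| %d unique %d",
        it, store$gene_names[J[it]], angles[it], train_acc, test_acc,
        length(cellset), length(unique_cells)))
    if (length(J) >= config$k) {
      release_block(store, blockJ)
      break
    }

    report <- margin_report(state, blockJ, lab_train, tol = 1e-4)
    release_block(store, blockJ)
    pool_local <- build_pool(report, config$pool_criterion)
    pool <- train[pool_local]   # back to store coordinates
    if (!length(pool)) { status <- "pool_empty"; break }

    iter_seed <- stream_seed(config$seed, "cells", length(J))
    if (config$strategy == "min_complexity") {
      cellset <- sample_min_complexity(pool, config$c_budget, config$sampling,
                                       labels, iter_seed)
    } else {
      cellset <- update_min_cell(pool, cellset, config$c_budget,
                                 config$sampling, labels, iter_seed)
    }
    unique_cells <- union(unique_cells, cellset)
    if (length(unique(labels[cellset])) < 2L) {
      cellset <- sample_cells_multiclass(train, labels,
                                         max(config$c_budget, length(cellset)),
                                         iter_seed + 1L, "cell set")
      unique_cells <- union(unique_cells, cellset)
    }
    sel <- select_next_gene(store, labels, J, cellset, config$C,
                            state_prev = state)
    J <- c(J, sel$gene)
    angles <- c(angles, sel$scores$angle[sel$scores$gene == sel$gene])
  }
  records <- do.call(rbind, records)
  structure(list(gene_indices = J, gene_names = store$gene_names[J],
                 records = records, final_state = state, split = split,
                 config = config, status = status,
                 unique_cells = sort(unique_cells)),
            class = "run_result")
}

iteration_records <- function() {
  data.frame(iteration = integer(0), gene = integer(0),
             gene_name = character(0), angle = numeric(0),
             train_accuracy = numeric(0), test_accuracy = numeric(0),
             cellset_size = integer(0), unique_cells = integer(0))
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("run_result: %d gene(s) [%s, %s sampling, %s]\n",
              length(x$gene_indices), x$config$strategy, x$config$sampling,
              x$status))
  if (nrow(x$records)) {
    last <- x$records[nrow(x$records), ]
    cat(sprintf("  final test accuracy %.3f; %d unique cells examined\n",
                last$test_accuracy, last$unique_cells))
  }
  invisible(x)
}

#' Half-width of a normal-approximation proportion confidence interval
#'
#' `z * sqrt(error_rate * (1 - error_rate) / n)`; with `z = 1.96` this is the
#' 95% interval used for the accuracy curves.
#'
#' @param error_rate observed error proportion in \[0, 1\].
#' @param n number of cells scored.
#' @param z normal quantile (default 1.96).
#' @return the half-width.
#' @examples
#' proportion_ci(0.5, 100) # 0.098
#' @export
proportion_ci <- function(error_rate, n, z = 1.96) {
  stopifnot(error_rate >= 0, error_rate <= 1)
  if (n < 1) stop("n must be at least 1")
  z * sqrt(error_rate * (1 - error_rate) / n)
}

#' Pairwise Pearson correlation of a gene set
#'
#' Computes the gene-gene Pearson correlation matrix over all cells of the
#' store. Constant genes have no defined correlation and get coefficient 0
#' (diagonal stays 1), with a warning.
#'
#' @param store an [expression_store()].
#' @param gene_set gene names or integer indices (length >= 2).
#' @return symmetric correlation matrix with unit diagonal, labelled by gene
#'   name.
#' @export
correlation_matrix <- function(store, gene_set) {
  if (is.character(gene_set)) {
    idx <- match(gene_set, store$gene_names)
    if (anyNA(idx)) stop("unknown gene(s): ",
                         paste(gene_set[is.na(idx)], collapse = ", "))
  } else idx <- as.integer(gene_set)
  if (length(idx) < 2L) stop("gene_set must contain at least two genes")
  if (any(idx < 1L | idx > store$n_genes)) stop("unknown gene index")
  block <- fetch_block(store, seq_len(store$n_cells), idx)
  on.exit(release_block(store, block))
  sds <- apply(block, 2L, stats::sd)
  cm <- suppressWarnings(stats::cor(block))
  if (any(sds == 0)) {
    warning("constant gene(s) in correlation_matrix; coefficients set to 0")
    cm[sds == 0, ] <- 0
    cm[, sds == 0] <- 0
  }
  diag(cm) <- 1
  dimnames(cm) <- list(store$gene_names[idx], store$gene_names[idx])
  cm
}

#' Test accuracy of a fixed gene panel
#'
#' Fits the linear SVM on the training cells restricted to `genes` and scores
#' it on the test cells; the standard way to compare panels from different
#' selectors on equal footing.
#'
#' @param store a preprocessed [expression_store()].
#' @param labels integer labels.
#' @param split a train/test split (see [split_train_test()]).
#' @param genes integer gene indices.
#' @param C soft-margin cost.
#' @return test-set accuracy in \[0, 1\].
#' @export
evaluate_gene_set <- function(store, labels, split, genes, C = 1) {
  train <- split$train_cell_indices
  test <- split$test_cell_indices
  btr <- fetch_block(store, train, genes)
  bte <- fetch_block(store, test, genes)
  on.exit({ release_block(store, btr); release_block(store, bte) })
  st <- fit_linear_svm(btr, labels[train], C)
  predict_and_score(st, bte, labels[test])
}

#' Write a run's outputs to a directory
#'
#' Emits `genes.csv` (rank, gene name, rotation angle), `curves.csv` (the
#' per-iteration records), `correlation.csv` (pairwise Pearson correlations
#' of the selected panel, when it has >= 2 genes), and `run.json` (config
#' echo plus status).
#'
#' @param result a `run_result` from [run_activesvm()].
#' @param store the store the run used (for the correlation matrix).
#' @param out_dir output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_run_outputs <- function(result, store, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genes <- data.frame(rank = seq_along(result$gene_indices),
                      gene = result$gene_names,
                      angle = result$records$angle)
  data.table::fwrite(genes, file.path(out_dir, "genes.csv"))
  data.table::fwrite(result$records, file.path(out_dir, "curves.csv"))
  if (length(result$gene_indices) >= 2L) {
    cm <- correlation_matrix(store, result$gene_indices)
    data.table::fwrite(data.frame(gene = rownames(cm), cm,
                                  check.names = FALSE),
                       file.path(out_dir, "correlation.csv"))
  }
  jsonlite::write_json(
    list(config = unclass(result$config), status = result$status,
         n_genes_selected = length(result$gene_indices),
         unique_cells = length(result$unique_cells)),
    file.path(out_dir, "run.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
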
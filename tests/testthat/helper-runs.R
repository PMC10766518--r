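# Memoised full-scale planted runs shared by the acceptance test file.
# The study conditions: 600 cells, 1,000 genes, 3 classes, 5 markers/class,
# fold-change 6, dispersion 0.5, dropout 0.3; min-complexity, c = 20, C = 1.

.acc_cache <- new.env(parent = emptyenv())

acc_pipeline <- function(seed, fold_change = 6) {
  key <- sprintf("pipe_%d_%g", seed, fold_change)
  if (is.null(.acc_cache[[key]])) {
    sp <- planted_spec(n_cells = 600L, n_genes = 1000L, n_classes = 3L,
                       markers_per_class = 5L, fold_change = fold_change,
                       mu0 = 2, dispersion = 0.5, dropout = 0.3, seed = seed)
    d <- generate_planted(sp)
    de <- drop_empty(d$store)
    .acc_cache[[key]] <- list(store = preprocess(de$store, "l2_only"),
                              labels = d$labels[de$kept_cell_indices],
                              truth = d$truth)
  }
  .acc_cache[[key]]
}

acc_run <- function(seed, strategy = "min_complexity", k = 20L,
                    fold_change = 6) {
  key <- sprintf("run_%s_%d_%d_%g", strategy, seed, k, fold_change)
  if (is.null(.acc_cache[[key]])) {
    p <- acc_pipeline(seed, fold_change)
    cfg <- run_config(strategy, "random", k = k, c_budget = 20L, C = 1,
                      seed = seed, dialect = "l2_only")
    .acc_cache[[key]] <- run_activesvm(cfg, p$store, p$labels)
  }
  .acc_cache[[key]]
}
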
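#' Score one gene against the labels by a baseline statistic
#'
#' Methods:
#' \describe{
#'   \item{`correlation`}{maximum over classes of the absolute Pearson
#'     correlation between the gene and that class's one-vs-rest indicator.}
#'   \item{`mutual_information`}{plug-in mutual information between the gene,
#'     discretized into `bins` equal-width bins, and the class labels (nats).}
#'   \item{`chi2`}{classic chi-squared statistic of the per-class totals of a
#'     non-negative feature against the class-size expectation.}
#'   \item{`tree_importance`}{impurity importance of the gene in a seeded
#'     shallow CART refit on the already-selected genes plus the candidate;
#'     scored via [baseline_select()], where the context genes are supplied.}
#' }
#' Constant genes score 0 for every method.
#'
#' @param method one of the method names above (not `"random"`, which has no
#'   per-gene score).
#' @param values per-cell expression of the gene.
#' @param labels integer class labels.
#' @param bins bin count for mutual information.
#' @param context optional cells x genes matrix of already-selected genes
#'   (tree method only).
#' @param tree_depth maximum CART depth (tree method only).
#' @return a non-negative score.
#' @export
score_gene <- function(method = c("correlation", "mutual_information",
                                  "chi2", "tree_importance"),
                       values, labels, bins = 10L, context = NULL,
                       tree_depth = 10L) {
  method <- match.arg(method)
  values <- as.numeric(values)
  labels <- as.integer(labels)
  stopifnot(length(values) == length(labels))
  if (stats::sd(values) == 0) return(0)
  cls <- sort(unique(labels))
  switch(method,
    correlation = {
      max(vapply(cls, function(z)
        abs(suppressWarnings(stats::cor(values, as.numeric(labels == z)))), 0),
        na.rm = TRUE)
    },
    mutual_information = {
      br <- seq(min(values), max(values), length.out = bins + 1L)
      bx <- cut(values, breaks = br, include.lowest = TRUE, labels = FALSE)
      tab <- table(bx, labels)
      p <- tab / sum(tab)
      px <- rowSums(p); py <- colSums(p)
      nz <- p > 0
      sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
    },
    chi2 = {
      if (any(values < 0))
        stop("chi2 requires non-negative feature values")
      obs <- vapply(cls, function(z) sum(values[labels == z]), 0)
      expd <- sum(values) * tabulate(factor(labels, levels = cls)) /
        length(labels)
      if (any(expd == 0)) return(0)
      sum((obs - expd)^2 / expd)
    },
    tree_importance = {
      x <- if (is.null(context)) matrix(values, ncol = 1L)
           else cbind(context, values)
      colnames(x) <- c(if (!is.null(context)) paste0("s", seq_len(ncol(context))),
                       "cand")
      df <- data.frame(y = factor(labels), x, check.names = FALSE)
      fit <- rpart::rpart(y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(
                            maxdepth = tree_depth, cp = 0, minsplit = 2L,
                            xval = 0L))
      imp <- fit$variable.importance
      if (is.null(imp) || !"cand" %in% names(imp)) 0 else unname(imp["cand"])
    })
}

#' Iterative baseline gene selection under the comparison protocol
#'
#' The comparison selectors share the iterative protocol of the active
#' procedure but with no active learning: each iteration draws `c_budget`
#' training cells uniformly at random (seeded), scores every unselected gene
#' on those cells with the method's statistic, and appends the argmax (ties
#' toward the smallest gene index). The `random` method appends a uniformly
#' drawn unselected gene instead.
#'
#' @param method `"correlation"`, `"mutual_information"`, `"chi2"`,
#'   `"tree_importance"`, or `"random"`.
#' @param store a preprocessed [expression_store()].
#' @param labels integer labels for all cells.
#' @param k number of genes to select.
#' @param c_budget cells sampled per iteration.
#' @param train optional training cell indices (defaults to all cells).
#' @param seed integer seed.
#' @param bins,tree_depth method knobs, as in [score_gene()].
#' @return ordered integer vector of `k` unique gene indices.
#' @export
baseline_select <- function(method = c("correlation", "mutual_information",
                                       "chi2", "tree_importance", "random"),
                            store, labels, k, c_budget = 20L,
                            train = NULL, seed = 0L, bins = 10L,
                            tree_depth = 10L) {
  method <- match.arg(method)
  stopifnot(k >= 1, c_budget >= 1)
  if (is.null(train)) train <- seq_len(store$n_cells)
  labels <- as.integer(labels)
  selected <- integer(0)
  for (it in seq_len(k)) {
    remaining <- setdiff(seq_len(store$n_genes), selected)
    if (!length(remaining)) break
    iter_seed <- stream_seed(seed, paste0("baseline_", method), it)
    if (method == "random") {
      selected <- c(selected, with_seed(iter_seed,
                                        remaining[sample.int(length(remaining), 1L)]))
      next
    }
    cells <- sample_cells_multiclass(train, labels, c_budget, iter_seed,
                                     paste("baseline", method))
    block <- fetch_block(store, cells, remaining)
    ctx <- if (method == "tree_importance" && length(selected))
      fetch_block(store, cells, selected) else NULL
    lab <- labels[cells]
    scores <- vapply(seq_along(remaining), function(jj)
      score_gene(method, block[, jj], lab, bins = bins, context = ctx,
                 tree_depth = tree_depth), 0)
    release_block(store, block)
    if (!is.null(ctx)) release_block(store, ctx)
    selected <- c(selected, remaining[which.max(scores)])
  }
  selected
}
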
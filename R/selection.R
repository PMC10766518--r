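#' Pool of poorly classified cells
#'
#' Collects the training cells eligible for acquisition this iteration:
#' margin violators (the default, cells whose dual coefficient sits at the
#' cost cap, i.e. misclassified or deep inside the margin) or, under the
#' wider criterion, violators together with on-margin support vectors (any
#' positive dual coefficient). Eligibility in any one-vs-rest machine
#' suffices; cells are deduplicated across machines.
#'
#' @param report a [margin_report()].
#' @param criterion `"violators"` or `"violators_or_margin"`.
#' @return sorted integer indices (within the report's cell order). An empty
#'   pool is a valid stopping signal.
#' @export
build_pool <- function(report, criterion = c("violators", "violators_or_margin")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(report, "margin_report"))
  eligible <- report$categories == "violator"
  if (criterion == "violators_or_margin")
    eligible <- eligible | report$categories == "on_margin"
  sort(which(rowSums(eligible) > 0))
}

#' Min-complexity cell sampling
#'
#' Draws this iteration's cell set fresh from the pool: everything if the
#' pool fits the budget, otherwise `c_budget` cells without replacement,
#' uniformly or with class-balanced allocation. Nothing accumulates across
#' iterations.
#'
#' @param pool integer cell indices eligible this iteration.
#' @param c_budget cells per iteration (>= 1).
#' @param mode `"random"` or `"balanced"`.
#' @param labels integer labels for all cells the pool indexes into.
#' @param seed integer seed.
#' @return sorted integer cell indices; the iteration's whole cell set.
#' @export
sample_min_complexity <- function(pool, c_budget, mode = c("random", "balanced"),
                                  labels = NULL, seed = 0L) {
  mode <- match.arg(mode)
  stopifnot(c_budget >= 1)
  if (length(pool) <= c_budget) return(sort(as.integer(pool)))
  if (mode == "random") {
    sort(with_seed(seed, sample(as.integer(pool), c_budget)))
  } else {
    sort(balanced_sample(pool, labels[pool], c_budget, seed))
  }
}

#' Min-cell accumulation update
#'
#' Reuses previously acquired misclassified cells with highest priority. With
#' `a` pool cells already in the accumulated set and `b` new pool cells: if
#' `a >= c_budget` nothing is added; otherwise `min(c_budget - a, b)` new
#' cells are sampled from the unseen part of the pool (uniformly or
#' balanced). Gene selection then uses the whole accumulated set, so the
#' unique-cell count never decreases.
#'
#' @param pool integer cell indices eligible this iteration.
#' @param acquired integer cell indices accumulated so far.
#' @param c_budget cells per iteration (>= 1).
#' @inheritParams sample_min_complexity
#' @return sorted updated accumulated cell set.
#' @export
update_min_cell <- function(pool, acquired, c_budget,
                            mode = c("random", "balanced"),
                            labels = NULL, seed = 0L) {
  mode <- match.arg(mode)
  stopifnot(c_budget >= 1)
  pool <- as.integer(pool)
  acquired <- as.integer(acquired)
  a <- sum(pool %in% acquired)
  fresh <- setdiff(pool, acquired)
  need <- c_budget - a
  if (need <= 0 || !length(fresh)) return(sort(acquired))
  add <- if (length(fresh) <= need) {
    fresh
  } else if (mode == "random") {
    with_seed(seed, sample(fresh, need))
  } else {
    balanced_sample(fresh, labels[fresh], need, seed)
  }
  sort(union(acquired, add))
}

#' Class-balanced allocation of a cell budget
#'
#' Splits a sampling budget across classes, visiting classes from smallest to
#' largest candidate count: a class whose pool fits its even share
#' `(budget - taken) / (classes remaining)` is taken whole; larger classes
#' receive the floor of the share, with remainders flowing to the later
#' (larger) classes. The total allocated is `min(budget, sum(sizes))`.
#'
#' @param sizes candidate counts per class, in ascending order.
#' @param c_prime total budget (> 0).
#' @return integer allocation per class, same order as `sizes`.
#' @examples
#' balanced_allocation(c(2, 10, 30), 12) # 2 5 5
#' balanced_allocation(c(1, 1, 100), 6)  # 1 1 4
#' @export
balanced_allocation <- function(sizes, c_prime) {
  if (c_prime <= 0) stop("budget must be positive")
  sizes <- as.integer(sizes)
  if (is.unsorted(sizes)) stop("sizes must be in ascending order")
  Z <- length(sizes)
  take <- integer(Z)
  taken <- 0L
  for (z in seq_len(Z)) {
    share <- (c_prime - taken) / (Z - z + 1L)
    take[z] <- if (sizes[z] <= share) sizes[z]
               else min(sizes[z], as.integer(floor(share)))
    taken <- taken + take[z]
  }
  take
}

# Sample `budget` cells from `cells` with per-class balanced allocation.
balanced_sample <- function(cells, cell_labels, budget, seed) {
  stopifnot(length(cells) == length(cell_labels))
  by_class <- split(as.integer(cells), as.integer(cell_labels))
  ord <- order(lengths(by_class), as.integer(names(by_class)))
  by_class <- by_class[ord]
  alloc <- balanced_allocation(lengths(by_class), budget)
  with_seed(seed, {
    unlist(lapply(seq_along(by_class), function(z) {
      pool_z <- by_class[[z]]
      if (alloc[z] >= length(pool_z)) pool_z else sample(pool_z, alloc[z])
    }), use.names = FALSE)
  })
}

#' Margin rotation angle of one added gene dimension
#'
#' The previous weight vector (over the current gene set) is padded with a
#' trailing zero for the candidate dimension; the angle to the candidate
#' weight vector is `acos` of their cosine similarity, clamped to \[-1, 1\].
#' If either vector is all-zero there is no direction to compare and the
#' angle is defined as 0.
#'
#' @param w_prev numeric weight vector of length `|J|`.
#' @param w_cand numeric weight vector of length `|J| + 1`.
#' @return angle in radians, in \[0, pi\].
#' @examples
#' margin_rotation_angle(1, c(1, 1)) # pi/4
#' margin_rotation_angle(1, c(0, 1)) # pi/2
#' @export
margin_rotation_angle <- function(w_prev, w_cand) {
  if (length(w_cand) != length(w_prev) + 1L)
    stop("w_cand must have exactly one more dimension than w_prev")
  padded <- c(w_prev, 0)
  np <- sqrt(sum(padded^2))
  nc <- sqrt(sum(w_cand^2))
  if (np == 0 || nc == 0) return(0)
  acos(min(1, max(-1, sum(padded * w_cand) / (np * nc))))
}

#' Multiclass margin rotation: sum of per-machine angles
#'
#' Under the one-vs-rest scheme each class contributes the rotation of its
#' own decision boundary; the gene's score is the sum over classes, so it
#' lies in \[0, Z * pi\]. Zero-norm components contribute 0.
#'
#' @param state_prev `svm_state` on the current gene set.
#' @param state_cand `svm_state` on the gene set plus one candidate.
#' @return total rotation angle in radians.
#' @export
multiclass_rotation <- function(state_prev, state_cand) {
  stopifnot(inherits(state_prev, "svm_state"), inherits(state_cand, "svm_state"))
  if (!identical(state_prev$machines, state_cand$machines))
    stop("class sets of the two states differ")
  sum(vapply(seq_along(state_prev$machines), function(k)
    margin_rotation_angle(state_prev$W[k, ], state_cand$W[k, ]), 0))
}

#' Select the next gene by maximizing margin rotation
#'
#' For every candidate gene, refits an SVM on the acquired cell set with
#' that one extra dimension and scores the induced rotation of the margin
#' ([multiclass_rotation()]) relative to the current weight vector. The
#' reference weights are those of the step SVM trained on all training
#' cells when supplied via `state_prev` (the driver's usage: the rotation is
#' measured against the machine that actually selected the cells); when
#' absent, a reference fit on the cell set itself is used. The candidate
#' with the largest total angle wins; ties break toward the smallest gene
#' index.
#'
#' @param store an [expression_store()].
#' @param labels integer labels for all cells of the store.
#' @param J integer indices of already-selected genes (length >= 1).
#' @param I integer indices of the acquired cell set (>= 2 cells, >= 2
#'   classes).
#' @param C soft-margin cost.
#' @param candidate_genes integer gene indices to score (defaults to all
#'   genes not in `J`).
#' @param fitter fitting function with the signature of [fit_linear_svm()];
#'   the default production solver can be swapped for a reference solver.
#' @param state_prev optional `svm_state` on the gene set `J` serving as the
#'   rotation reference; its machine set must cover the classes present in
#'   `I`.
#' @return list with `gene` (chosen index), `scores` (data.frame of gene and
#'   angle in candidate order).
#' @export
select_next_gene <- function(store, labels, J, I, C = 1,
                             candidate_genes = NULL,
                             fitter = fit_linear_svm,
                             state_prev = NULL) {
  stopifnot(length(J) >= 1L, length(I) >= 2L)
  if (is.null(candidate_genes))
    candidate_genes <- setdiff(seq_len(store$n_genes), J)
  candidate_genes <- sort(as.integer(setdiff(candidate_genes, J)))
  if (!length(candidate_genes)) stop("no candidate genes remaining")
  lab_I <- as.integer(labels[I])
  if (length(unique(lab_I)) < 2L)
    stop("single-class cell set: cannot score candidate genes")
  blockJ <- fetch_block(store, I, J)
  blockC <- fetch_block(store, I, candidate_genes)
  on.exit({ release_block(store, blockJ); release_block(store, blockC) })
  if (is.null(state_prev)) state_prev <- fitter(blockJ, lab_I, C)
  cand_machines <- machines_for(lab_I)
  ref <- subset_machines(state_prev, cand_machines)
  angles <- vapply(seq_along(candidate_genes), function(jj) {
    x <- cbind(blockJ, blockC[, jj])
    multiclass_rotation(ref, fitter(x, lab_I, C))
  }, 0)
  best <- candidate_genes[which.max(angles)]
  list(gene = best,
       scores = data.frame(gene = candidate_genes, angle = angles))
}

# Machine set a fit on these labels will produce (one-vs-rest; the larger
# class id alone for binary).
machines_for <- function(labels) {
  cls <- sort(unique(as.integer(labels)))
  if (length(cls) == 2L) cls[2L] else cls
}

# Restrict an svm_state to the given machines (e.g. when the acquired cell
# set lacks some class present in the full training data).
subset_machines <- function(state, machines) {
  idx <- match(machines, state$machines)
  if (anyNA(idx))
    stop("rotation reference lacks machine(s): ",
         paste(machines[is.na(idx)], collapse = ", "))
  state$W <- state$W[idx, , drop = FALSE]
  state$b <- state$b[idx]
  state$machines <- machines
  state
}

#' Naive reference gene selection (independent oracle)
#'
#' Re-scores every candidate with the slow dual-QP solver
#' ([fit_linear_svm_qp()]), sequentially, sharing no solver code with
#' [select_next_gene()]'s default path. Intended for validation on small
#' instances.
#'
#' @inheritParams select_next_gene
#' @return same shape as [select_next_gene()].
#' @export
select_next_gene_naive <- function(store, labels, J, I, C = 1,
                                   candidate_genes = NULL, state_prev = NULL) {
  select_next_gene(store, labels, J, I, C, candidate_genes,
                   fitter = function(block, lab, cost) fit_linear_svm_qp(block, lab, cost),
                   state_prev = state_prev)
}

#' Bootstrap: select the first gene by 1-D training accuracy
#'
#' The margin-rotation score needs an existing weight vector, so the first
#' gene is chosen differently: on a seeded random cell sample, every
#' candidate gene is scored by the training accuracy of the 1-D SVM fit on
#' it alone; the best (ties toward the smallest index) seeds the panel.
#'
#' @param store an [expression_store()].
#' @param labels integer labels.
#' @param initial_cells integer cell indices (>= 2 classes present).
#' @param C soft-margin cost.
#' @param candidate_genes integer gene indices (defaults to all).
#' @return list with `gene` and `accuracy` (its 1-D training accuracy).
#' @export
select_first_gene <- function(store, labels, initial_cells, C = 1,
                              candidate_genes = NULL) {
  if (is.null(candidate_genes)) candidate_genes <- seq_len(store$n_genes)
  candidate_genes <- sort(as.integer(candidate_genes))
  lab <- as.integer(labels[initial_cells])
  if (length(unique(lab)) < 2L)
    stop("single-class initial cell sample")
  block <- fetch_block(store, initial_cells, candidate_genes)
  on.exit(release_block(store, block))
  acc <- vapply(seq_along(candidate_genes), function(jj) {
    x <- block[, jj, drop = FALSE]
    if (stats::var(x) == 0) return(0)
    st <- fit_linear_svm(x, lab, C)
    predict_and_score(st, x, lab)
  }, 0)
  best <- which.max(acc)
  list(gene = candidate_genes[best], accuracy = acc[best])
}
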
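test_that("rotation angle reproduces closed-form cases and invariances", {
  expect_equal(margin_rotation_angle(1, c(1, 1)), pi / 4)
  expect_equal(margin_rotation_angle(1, c(1, 0)), 0)
  expect_equal(margin_rotation_angle(1, c(0, 1)), pi / 2)
  expect_equal(margin_rotation_angle(numeric(0), 1), 0) # zero-norm previous
  expect_equal(margin_rotation_angle(c(1, 2), c(0, 0, 0)), 0)
  expect_error(margin_rotation_angle(c(1, 2), c(1, 2)), "one more dimension")
  # invariance to positive rescaling, range [0, pi]
  set.seed(4)
  for (i in 1:20) {
    a <- rnorm(5); b <- rnorm(6)
    ang <- margin_rotation_angle(a, b)
    expect_gte(ang, 0)
    expect_lte(ang, pi)
    expect_equal(margin_rotation_angle(a * runif(1, 0.1, 9),
                                       b * runif(1, 0.1, 9)), ang,
                 tolerance = 1e-12)
  }
})

test_that("multiclass rotation sums per-class angles", {
  mk_state <- function(W) structure(
    list(classes = 1:2, machines = 1:2, W = W, b = c(0, 0), C = 1,
         binary = FALSE), class = "svm_state")
  prev <- mk_state(rbind(c(1), c(1)))
  cand <- mk_state(rbind(c(1, 1), c(0, 1)))
  expect_equal(multiclass_rotation(prev, cand), pi / 4 + pi / 2)
  ident <- mk_state(rbind(c(1, 0), c(1, 0)))
  expect_equal(multiclass_rotation(prev, ident), 0)
  bad <- mk_state(rbind(c(1, 1), c(0, 1))); bad$machines <- 2:3
  expect_error(multiclass_rotation(prev, bad), "class sets")
})

test_that("pool construction follows the margin categories", {
  toy <- toy_1d()
  st <- fit_linear_svm(toy$x, toy$y, C = 1e6)
  rep <- margin_report(st, toy$x, toy$y)
  expect_length(build_pool(rep, "violators"), 0)
  expect_setequal(build_pool(rep, "violators_or_margin"), c(2L, 3L))
  x <- rbind(toy$x, 0.5); y <- c(toy$y, -1L)
  st2 <- fit_linear_svm(x, y, C = 1)
  rep2 <- margin_report(st2, x, y)
  expect_true(5L %in% build_pool(rep2, "violators"))
})

test_that("min-complexity sampling is budgeted, seeded and fresh", {
  expect_equal(sample_min_complexity(c(4L, 9L, 2L, 7L, 5L), 10), c(2L, 4L, 5L, 7L, 9L))
  pool <- sample.int(500, 200)
  s1 <- sample_min_complexity(pool, 20, seed = 8)
  s2 <- sample_min_complexity(pool, 20, seed = 8)
  s3 <- sample_min_complexity(pool, 20, seed = 9)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
  expect_length(s1, 20)
  expect_true(all(s1 %in% pool))
})

test_that("min-cell accumulation follows the a/b/c reuse rule", {
  acquired <- 1:40
  pool <- c(1:40, 101:180) # a = 40, b = 80
  up <- update_min_cell(pool, acquired, 100, seed = 1)
  expect_length(up, 100)
  expect_true(all(acquired %in% up))
  # a >= c: unchanged
  expect_identical(update_min_cell(c(1:40), acquired, 30, seed = 1),
                   sort(acquired))
  # shortfall: all new cells added
  up2 <- update_min_cell(c(1:10, 201:205), 1:10, 100, seed = 1)
  expect_identical(up2, sort(c(1:10, 201:205)))
})

test_that("balanced allocation matches the hand-traced recurrence", {
  expect_equal(balanced_allocation(c(2, 10, 30), 12), c(2L, 5L, 5L))
  expect_equal(balanced_allocation(c(4, 4, 4), 12), c(4L, 4L, 4L))
  expect_equal(balanced_allocation(c(1, 1, 100), 6), c(1L, 1L, 4L))
  expect_error(balanced_allocation(c(1, 2), 0), "positive")
  expect_error(balanced_allocation(c(5, 2), 4), "ascending")
  # properties: totals, caps, near-even spread over non-exhausted classes
  set.seed(10)
  for (i in 1:50) {
    sizes <- sort(sample.int(40, sample(2:6, 1), replace = TRUE))
    budget <- sample.int(60, 1)
    al <- balanced_allocation(sizes, budget)
    expect_equal(sum(al), min(budget, sum(sizes)))
    expect_true(all(al <= sizes))
    open <- al < sizes
    if (sum(open) > 1) expect_lte(diff(range(al[open])), 1)
  }
})

test_that("balanced min-complexity sampling allocates budget across classes", {
  labels <- rep(1:3, times = c(5, 40, 80))
  pool <- seq_along(labels)
  s <- sample_min_complexity(pool, 12, mode = "balanced", labels = labels,
                             seed = 3)
  expect_equal(as.vector(table(labels[s])), c(4L, 4L, 4L))
  expect_length(s, 12)
})

test_that("gene selection agrees with the naive dual-QP oracle", {
  # one marker per class among noise; the panel holds class 1's marker, so
  # the clear rotation winner is the complementary class-2 marker
  sp <- small_planted(seed = 21L, n_cells = 50L, n_genes = 21L,
                      n_classes = 2L, markers_per_class = 1L)
  I <- seq_len(sp$store$n_cells)
  J <- sp$truth$marker_indices[[1L]]
  fast <- select_next_gene(sp$store, sp$labels, J, I, C = 1)
  slow <- select_next_gene_naive(sp$store, sp$labels, J, I, C = 1)
  expect_equal(fast$gene, slow$gene)
  expect_equal(fast$scores$angle, slow$scores$angle, tolerance = 1e-2)
  expect_equal(fast$gene, sp$truth$marker_indices[[2L]])
})

test_that("gene selection edge cases: single candidate, constant gene, ties", {
  sp <- small_planted(seed = 22L, n_cells = 40L, n_genes = 12L,
                      n_classes = 2L, markers_per_class = 2L)
  I <- seq_len(sp$store$n_cells)
  single <- select_next_gene(sp$store, sp$labels, 5L, I,
                             candidate_genes = 9L)
  expect_equal(single$gene, 9L)
  expect_error(select_next_gene(sp$store, sp$labels, 5L, I,
                                candidate_genes = 5L), "no candidate")
  expect_error(select_next_gene(sp$store, sp$labels, 5L,
                                which(sp$labels == 1L), C = 1),
               "single-class")
  # constant candidate scores rotation 0
  m <- cbind(c(-2, -1, 1, 2), 1)
  st <- expression_store(m)
  out <- select_next_gene(st, c(1L, 1L, 2L, 2L), 1L, 1:4, C = 10,
                          candidate_genes = 2L)
  expect_lt(out$scores$angle, 1e-3)
})

test_that("first-gene bootstrap maximizes 1-D training accuracy", {
  sp <- small_planted(seed = 23L, n_cells = 60L, n_genes = 30L,
                      n_classes = 2L, markers_per_class = 3L)
  out <- select_first_gene(sp$store, sp$labels, seq_len(sp$store$n_cells),
                           C = 1)
  expect_true(sp$store$gene_names[out$gene] %in%
                unlist(sp$truth$marker_names))
  # independent exhaustive oracle: brute-force 1-D accuracy scan
  accs <- vapply(seq_len(sp$store$n_genes), function(j) {
    x <- fetch_block(sp$store, seq_len(sp$store$n_cells), j)
    if (stats::var(x) == 0) return(0)
    st <- fit_linear_svm_qp(x, sp$labels, C = 1)
    predict_and_score(st, x, sp$labels)
  }, 0)
  expect_equal(out$accuracy, max(accs), tolerance = 1e-6)
  # all-constant genes tie toward the smallest index
  cst <- expression_store(matrix(1, 6, 3))
  tie <- select_first_gene(cst, rep(1:2, 3), 1:6)
  expect_equal(tie$gene, 1L)
  expect_error(select_first_gene(sp$store, rep(1L, sp$store$n_cells),
                                 1:10), "single-class")
})
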
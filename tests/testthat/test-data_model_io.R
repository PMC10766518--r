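test_that("dense CSV loads in cells x genes orientation with names", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("cell,gA,gB,gC", "c1,1,0,2", "c2,0,3,0"), f)
  st <- load_expression(f, "csv")
  expect_equal(dim(st), c(2L, 3L))
  expect_equal(st$gene_names, c("gA", "gB", "gC"))
  expect_equal(st$cell_names, c("c1", "c2"))
  expect_equal(sum(fetch_block(st, 1:2, 1:3) != 0), 3)
})

test_that("mtx triplet round-trips exactly and honors orientation", {
  m <- Matrix::Matrix(matrix(c(1, 0, 2, 0, 3, 0), 2, 3, byrow = TRUE),
                      sparse = TRUE)
  st <- expression_store(m, c("gA", "gB", "gC"), c("c1", "c2"))
  d <- tempfile()
  write_expression(st, d, "mtx")
  back <- load_expression(file.path(d, "matrix.mtx"), "mtx")
  expect_identical(fetch_block(back, 1:2, 1:3), fetch_block(st, 1:2, 1:3))
  expect_equal(back$gene_names, st$gene_names)
  # same file declared genes x cells: result is the transpose, still c x g
  tr <- load_expression(file.path(d, "matrix.mtx"), "mtx",
                        orientation = "genes_x_cells",
                        gene_file = file.path(d, "barcodes.tsv"),
                        cell_file = file.path(d, "genes.tsv"))
  expect_equal(fetch_block(tr, 1:3, 1:2),
               t(fetch_block(st, 1:2, 1:3)))
})

test_that("malformed mtx and sidecar mismatches are rejected", {
  d <- tempfile(); dir.create(d)
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "2 3 5", "1 1 1", "1 3 2", "2 2 3"),
             file.path(d, "matrix.mtx"))
  writeLines(c("gA", "gB", "gC"), file.path(d, "genes.tsv"))
  writeLines(c("c1", "c2"), file.path(d, "barcodes.tsv"))
  expect_error(load_expression(file.path(d, "matrix.mtx"), "mtx"),
               "malformed")
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "2 3 3", "1 1 1", "1 3 2", "2 2 3"),
             file.path(d, "matrix.mtx"))
  writeLines(c("gA", "gB"), file.path(d, "genes.tsv"))
  expect_error(load_expression(file.path(d, "matrix.mtx"), "mtx"),
               "sidecar mismatch")
  expect_error(load_expression(tempfile(), "csv"), "not found")
})

test_that("drop_empty removes exactly the all-zero rows/columns with maps", {
  m <- matrix(c(1, 0, 0, 2,
                0, 0, 0, 0,
                3, 0, 0, 1), 3, 4, byrow = TRUE)
  st <- expression_store(m, paste0("g", 1:4), paste0("c", 1:3))
  de <- drop_empty(st)
  expect_equal(de$kept_gene_indices, c(1L, 4L))
  expect_equal(de$kept_cell_indices, c(1L, 3L))
  expect_equal(fetch_block(de$store, 1:2, 1:2),
               m[c(1, 3), c(1, 4)], ignore_attr = TRUE)
  # identity on a store with no empties
  st2 <- expression_store(matrix(1:4, 2, 2), c("a", "b"), c("x", "y"))
  de2 <- drop_empty(st2)
  expect_equal(de2$kept_gene_indices, 1:2)
  expect_equal(de2$kept_cell_indices, 1:2)
  expect_error(drop_empty(expression_store(matrix(0, 2, 2))), "degenerate")
})

test_that("column normalization divides by gene totals then log1p", {
  m <- matrix(c(1, 2, 3, 6), 2, 2) # gene totals 3 and 9
  st <- normalize_column_log(expression_store(m))
  expect_equal(fetch_block(st, 1:2, 1:2),
               log1p(cbind(c(1, 2) / 3, c(3, 6) / 9)), ignore_attr = TRUE)
  # invariant: per-gene sum of expm1 equals 1
  sp <- small_planted(seed = 7L, dialect = "colnorm_log_l2")
  raw <- generate_planted(planted_spec(n_cells = 150L, n_genes = 60L,
                                       n_classes = 2L, markers_per_class = 3L,
                                       seed = 7L))
  de <- drop_empty(raw$store)
  nn <- normalize_column_log(de$store)
  b <- fetch_block(nn, seq_len(nn$n_cells), seq_len(nn$n_genes))
  expect_lt(max(abs(colSums(expm1(b)) - 1)), 1e-9)
  expect_error(normalize_column_log(expression_store(matrix(c(-1, 1), 1, 2))),
               "negative")
})

test_that("row l2 normalization yields unit cells and tolerates zero rows", {
  st <- expression_store(matrix(c(3, 4, 1, 0, 0, 0), 3, 2, byrow = TRUE))
  expect_warning(out <- l2_normalize_rows(st), "all-zero")
  b <- fetch_block(out, 1:3, 1:2)
  expect_equal(b[1, ], c(0.6, 0.8))
  expect_equal(b[2, ], c(1, 0))
  expect_equal(b[3, ], c(0, 0))
  # full dialect leaves every cell row at unit norm
  sp <- small_planted(seed = 3L)
  bb <- fetch_block(sp$store, seq_len(sp$store$n_cells),
                    seq_len(sp$store$n_genes))
  expect_lt(max(abs(sqrt(rowSums(bb^2)) - 1)), 1e-9)
})

test_that("train/test split is seeded, disjoint, complete and warns on lost classes", {
  lab <- rep(1:2, 5)
  s1 <- split_train_test(10, lab, 0.8, seed = 11)
  s2 <- split_train_test(10, lab, 0.8, seed = 11)
  expect_identical(s1, s2)
  expect_length(s1$train_cell_indices, 8)
  expect_length(intersect(s1$train_cell_indices, s1$test_cell_indices), 0)
  expect_setequal(c(s1$train_cell_indices, s1$test_cell_indices), 1:10)
  s3 <- split_train_test(10, lab, 0.8, seed = 12)
  expect_false(identical(s1$train_cell_indices, s3$train_cell_indices))
  expect_error(split_train_test(10, lab, 1.0), "between 0 and 1")
  # 3 classes, 2 training cells: some class is always absent from training
  expect_warning(split_train_test(3, 1:3, 0.5, seed = 5), "absent")
})

test_that("fetch_block honors ranges, degenerate shapes and instrumentation", {
  m <- matrix(rpois(30, 2), 5, 6)
  st <- expression_store(m)
  expect_equal(fetch_block(st, 1:5, 1:6), m, ignore_attr = TRUE)
  expect_equal(dim(fetch_block(st, 1:3, integer(0))), c(3L, 0L))
  expect_equal(fetch_block(st, 2, 3)[1, 1], m[2, 3])
  expect_error(fetch_block(st, 6, 1), "out of range")
  reset_resident_counter(st)
  b1 <- fetch_block(st, 1:5, 1:2)
  b2 <- fetch_block(st, 1:2, 1:6)
  expect_equal(peak_resident_entries(st), 22)
  release_block(st, b1)
  release_block(st, b2)
  b3 <- fetch_block(st, 1, 1)
  expect_equal(peak_resident_entries(st), 22) # peak is sticky
})

test_that("on-disk store reproduces blocks of its in-memory source", {
  sp <- small_planted(seed = 9L)
  d <- tempfile()
  write_disk_store(sp$store, d)
  disk <- open_disk_store(d)
  expect_equal(disk$backing, "on-disk")
  expect_equal(dim(disk), dim(sp$store))
  full <- fetch_block(sp$store, seq_len(sp$store$n_cells),
                      seq_len(sp$store$n_genes))
  # row-oriented, column-oriented and scattered blocks
  expect_equal(fetch_block(disk, 3:7, seq_len(disk$n_genes)),
               full[3:7, , drop = FALSE], ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(fetch_block(disk, seq_len(disk$n_cells), c(2L, 5L, 44L)),
               full[, c(2, 5, 44)], ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(fetch_block(disk, c(10L, 2L, 99L), c(7L, 1L)),
               full[c(10, 2, 99), c(7, 1)], ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("labels load from aligned and name-keyed files", {
  st <- expression_store(matrix(1:6, 3, 2), c("g1", "g2"), c("c1", "c2", "c3"))
  f1 <- tempfile(); writeLines(c("2", "1", "2"), f1)
  expect_equal(load_labels(f1, st), c(2L, 1L, 2L))
  f2 <- tempfile(); writeLines(c("cell,label", "c3,7", "c1,5", "c2,6"), f2)
  expect_equal(load_labels(f2, st), c(5L, 6L, 7L))
  f3 <- tempfile(); writeLines(c("1", "2"), f3)
  expect_error(load_labels(f3, st), "2 entries")
})
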
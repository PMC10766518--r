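test_that("hard-margin 1-D toy recovers w = 1, b = 0 and its margins", {
  toy <- toy_1d()
  st <- fit_linear_svm(toy$x, toy$y, C = 1e6)
  expect_equal(drop(st$W), 1, tolerance = 1e-6)
  expect_equal(st$b, 0, tolerance = 1e-6)
  rep <- margin_report(st, toy$x, toy$y, tol = 1e-4)
  expect_equal(drop(rep$functional_margins), c(2, 1, 1, 2), tolerance = 1e-5)
  expect_equal(drop(rep$categories),
               c("outside", "on_margin", "on_margin", "outside"))
  expect_equal(predict_and_score(st, toy$x, toy$y), 1.0)
  expect_equal(predict_and_score(st, toy$x, -toy$y), 0.0)
})

test_that("single-class input and empty gene sets are rejected", {
  toy <- toy_1d()
  expect_error(fit_linear_svm(toy$x, rep(1L, 4), C = 1), "single-class")
  expect_error(fit_linear_svm(toy$x[, 0, drop = FALSE], toy$y), "empty gene set")
  expect_error(margin_report(fit_linear_svm(toy$x, toy$y),
                             cbind(toy$x, toy$x), toy$y),
               "expects")
})

test_that("duplicating every training cell leaves the solution unchanged", {
  toy <- toy_1d()
  st1 <- fit_linear_svm(toy$x, toy$y, C = 1e6)
  st2 <- fit_linear_svm(rbind(toy$x, toy$x), c(toy$y, toy$y), C = 1e6)
  expect_equal(st1$W, st2$W, tolerance = 1e-5)
  expect_equal(st1$b, st2$b, tolerance = 1e-5)
})

test_that("an added margin violator is categorized as such", {
  toy <- toy_1d()
  x <- rbind(toy$x, 0.5)
  y <- c(toy$y, -1L)
  st <- fit_linear_svm(x, y, C = 1)
  rep <- margin_report(st, x, y, tol = 1e-4)
  expect_equal(drop(rep$categories)[5], "violator")
  expect_lt(rep$functional_margins[5, 1], 1)
})

test_that("hinge loss is max(0, 1 - margin)", {
  expect_equal(hinge_loss(c(2, 0, -1, 1)), c(0, 1, 2, 0))
  expect_error(hinge_loss(NaN), "finite")
})

test_that("production weights match the dual-QP reference on random toys", {
  for (seed in 1:6) {
    inst <- random_svm_instance(seed + 100)
    st <- fit_linear_svm(inst$x, inst$y, C = inst$C)
    qp <- svm_dual_qp(inst$x, ifelse(inst$y == 1, 1, -1), inst$C)
    expect_lt(sqrt(sum((drop(st$W) - qp$w)^2)) / (sqrt(sum(qp$w^2)) + 1e-12),
              1e-3)
  }
})

test_that("margin categories agree with the dual coefficients of the QP", {
  inst <- random_svm_instance(42)
  st <- fit_linear_svm(inst$x, inst$y, C = inst$C)
  qp <- svm_dual_qp(inst$x, ifelse(inst$y == 1, 1, -1), inst$C)
  rep <- margin_report(st, inst$x, inst$y, tol = 1e-4)
  cats <- drop(rep$categories)
  eps <- 1e-4 * inst$C
  # clearly interior alphas must be on the margin; bound alphas on their side
  # (numerically safe slack for the cross-solver comparison)
  expect_true(all(rep$functional_margins[qp$alpha < eps] > 1 - 1e-3))
  expect_true(all(rep$functional_margins[qp$alpha > inst$C - eps] < 1 + 1e-3))
})

test_that("feature rescaling rescales weights inversely on separable toys", {
  toy <- toy_1d()
  s <- 4
  st1 <- fit_linear_svm(toy$x, toy$y, C = 1e6)
  st2 <- fit_linear_svm(toy$x * s, toy$y, C = 1e6)
  expect_equal(st2$W * s, st1$W, tolerance = 1e-5)
})

test_that("multiclass one-vs-rest prediction is argmax with smallest-id ties", {
  set.seed(2)
  n <- 90
  lab <- rep(1:3, each = n / 3)
  x <- matrix(rnorm(n * 2, sd = 0.2), n, 2)
  x[lab == 2, 1] <- x[lab == 2, 1] + 3
  x[lab == 3, 2] <- x[lab == 3, 2] + 3
  st <- fit_linear_svm(x, lab, C = 10)
  expect_equal(nrow(st$W), 3L)
  expect_gt(predict_and_score(st, x, lab), 0.95)
  # random labels score near chance on held-out-style data
  set.seed(3)
  lab_r <- sample(1:3, n, replace = TRUE)
  xr <- matrix(rnorm(n * 4), n, 4)
  str <- fit_linear_svm(xr, lab_r, C = 1)
  acc <- predict_and_score(str, matrix(rnorm(n * 4), n, 4),
                           sample(1:3, n, replace = TRUE))
  expect_lt(abs(acc - 1 / 3), 1.96 * sqrt((1 / 3) * (2 / 3) / n) + 0.12)
})
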
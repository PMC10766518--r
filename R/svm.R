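#' Fit a linear soft-margin SVM (one-vs-rest for multiclass)
#'
#' Minimizes the L2-regularized hinge objective on a dense cells x genes
#' block. With two classes a single binary machine is fit with the larger
#' class id as the positive class; with Z > 2 classes one binary machine is
#' fit per class against the rest. Weights are oriented so that a positive
#' decision value votes for the machine's class.
#'
#' @param block dense matrix, cells x selected genes.
#' @param labels integer class labels for those cells.
#' @param C positive soft-margin cost (trade-off between margin width and
#'   violations); default 1.
#' @param tolerance solver convergence tolerance.
#' @return an object of class `svm_state`: list with `classes` (the machine
#'   class ids; for binary a single machine for the larger class id), `W`
#'   (machines x genes weight matrix), `b` (per-machine bias), `C`, `binary`.
#' @examples
#' x <- matrix(c(-2, -1, 1, 2), ncol = 1)
#' fit_linear_svm(x, c(-1, -1, 1, 1), C = 1e6)
#' @export
fit_linear_svm <- function(block, labels, C = 1, tolerance = 1e-6) {
  block <- as.matrix(block)
  if (ncol(block) < 1L) stop("empty gene set")
  stopifnot(nrow(block) == length(labels), C > 0)
  cls <- sort(unique(as.integer(labels)))
  if (length(cls) < 2L) stop("single-class input: cannot fit an SVM")
  binary <- length(cls) == 2L
  machines <- if (binary) cls[2L] else cls
  W <- matrix(0, length(machines), ncol(block))
  b <- numeric(length(machines))
  for (k in seq_along(machines)) {
    ypm <- ifelse(labels == machines[k], 1, -1)
    fit <- fit_binary_svm(block, ypm, C, tolerance)
    W[k, ] <- fit$w
    b[k] <- fit$b
  }
  structure(list(classes = cls, machines = machines, W = W, b = b,
                 C = C, binary = binary),
            class = "svm_state")
}

# One binary machine: y in {-1, +1}. libsvm orients its decision value toward
# the first label it encounters, so the extracted (w, b) is flipped when that
# label is the negative class.
fit_binary_svm <- function(x, ypm, C, tolerance = 1e-6) {
  f <- factor(ypm, levels = c(-1, 1))
  m <- e1071::svm(x, f, kernel = "linear", cost = C, scale = FALSE,
                  tolerance = tolerance)
  w <- drop(crossprod(m$coefs, m$SV))
  b <- -m$rho
  if (m$levels[m$labels[1L]] != "1") {
    w <- -w
    b <- -b
  }
  list(w = w, b = b)
}

#' @export
print.svm_state <- function(x, ...) {
  cat(sprintf("linear svm_state: %d machine(s), %d gene(s), C = %g\n",
              nrow(x$W), ncol(x$W), x$C))
  invisible(x)
}

#' Hinge loss of a functional margin
#'
#' `max(0, 1 - functional_margin)` where the functional margin of cell i is
#' `y_i (w' x_i + b)`.
#'
#' @param functional_margin numeric vector.
#' @return elementwise hinge loss.
#' @export
hinge_loss <- function(functional_margin) {
  stopifnot(all(is.finite(functional_margin)))
  pmax(0, 1 - functional_margin)
}

#' Per-cell margin status under the KKT complementarity conditions
#'
#' For every training cell and every one-vs-rest machine, computes the
#' functional margin `y (w' x + b)` (with y = +1 for the machine's class and
#' -1 otherwise) and classifies it: greater than `1 + tol` means the cell lies
#' outside the margin (dual coefficient 0), less than `1 - tol` means it
#' violates the margin (dual coefficient at the cost cap C), anything else is
#' on the margin (dual coefficient strictly between 0 and C). A cell is
#' pool-eligible when it is a violator for at least one machine (or a
#' violator-or-on-margin cell, under the wider criterion).
#'
#' @param state an `svm_state` from [fit_linear_svm()].
#' @param block dense cells x genes matrix with `ncol(block) == ncol(state$W)`.
#' @param labels integer labels for the block's cells.
#' @param tol category tolerance at the functional-margin boundary 1.
#' @return an object of class `margin_report`: list with `functional_margins`
#'   (cells x machines), `categories` (character matrix, values `"outside"`,
#'   `"on_margin"`, `"violator"`), `machines`.
#' @export
margin_report <- function(state, block, labels, tol = 1e-4) {
  stopifnot(inherits(state, "svm_state"))
  block <- as.matrix(block)
  if (ncol(block) != ncol(state$W))
    stop("block has ", ncol(block), " genes but state expects ", ncol(state$W))
  stopifnot(nrow(block) == length(labels))
  dec <- block %*% t(state$W)
  dec <- sweep(dec, 2L, state$b, "+")
  ysign <- outer(as.integer(labels), state$machines,
                 function(l, m) ifelse(l == m, 1, -1))
  fm <- ysign * dec
  cat_m <- matrix("on_margin", nrow(fm), ncol(fm))
  cat_m[fm > 1 + tol] <- "outside"
  cat_m[fm < 1 - tol] <- "violator"
  structure(list(functional_margins = fm, categories = cat_m,
                 machines = state$machines, tol = tol),
            class = "margin_report")
}

#' Predict classes and score accuracy
#'
#' Binary states predict the positive class when the decision value is
#' non-negative; multiclass states take the argmax over per-class decision
#' values, with ties broken toward the smallest class id.
#'
#' @param state an `svm_state`.
#' @param block dense cells x genes matrix.
#' @param labels true integer labels.
#' @return fraction of correctly classified cells, in \[0, 1\].
#' @export
predict_and_score <- function(state, block, labels) {
  pred <- predict_classes(state, block)
  mean(pred == as.integer(labels))
}

predict_classes <- function(state, block) {
  stopifnot(inherits(state, "svm_state"))
  block <- as.matrix(block)
  if (ncol(block) != ncol(state$W))
    stop("block has ", ncol(block), " genes but state expects ", ncol(state$W))
  dec <- sweep(block %*% t(state$W), 2L, state$b, "+")
  if (state$binary) {
    ifelse(drop(dec) >= 0, state$classes[2L], state$classes[1L])
  } else {
    state$classes[max.col(dec, ties.method = "first")]
  }
}
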
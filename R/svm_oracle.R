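#' Reference soft-margin SVM via the dual quadratic program
#'
#' Solves the box-constrained dual of the linear soft-margin SVM
#' (maximize `sum(alpha) - 0.5 * alpha' Q alpha` with `0 <= alpha <= C`,
#' `sum(alpha * y) = 0`, `Q = (y y') * (X X')`) with the interior-point
#' solver `kernlab::ipop`, then reconstructs `w = sum_i alpha_i y_i x_i` and
#' the bias from the complementarity conditions. This is a slow generic
#' solver kept as an independent cross-check of [fit_linear_svm()]; it shares
#' no code path with the production solver.
#'
#' @param x dense cells x genes matrix.
#' @param ypm labels in `{-1, +1}`.
#' @param C positive cost.
#' @param ridge small diagonal added to `Q` for numerical stability.
#' @return list with `alpha`, `w`, `b`.
#' @export
svm_dual_qp <- function(x, ypm, C, ridge = 1e-8) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(length(ypm) == n, all(ypm %in% c(-1, 1)), C > 0)
  K <- tcrossprod(x)
  yy <- ypm %o% ypm
  alpha <- NULL
  # ipop can hit singular interior-point systems on poorly scaled kernels;
  # escalate the ridge, then fall back to the pure-R SMO ascent
  for (r in unique(c(ridge, 1e-6, 1e-4) * max(1, mean(diag(K))))) {
    sol <- tryCatch(
      kernlab::ipop(c = rep(-1, n), H = yy * K + diag(r, n),
                    A = matrix(as.double(ypm), 1L), b = 0,
                    l = rep(0, n), u = rep(as.double(C), n), r = 0,
                    sigf = 9, maxiter = 400),
      error = function(e) NULL)
    if (!is.null(sol)) {
      alpha <- pmin(pmax(kernlab::primal(sol), 0), C)
      break
    }
  }
  if (is.null(alpha)) alpha <- smo_dual(K, ypm, C)$alpha
  w <- drop(crossprod(x, alpha * ypm))
  m <- drop(x %*% w)
  eps <- max(1e-6, 1e-6 * C)
  free <- alpha > eps & alpha < C - eps
  g <- ypm - m
  b <- if (any(free)) {
    mean(g[free])
  } else {
    # b is bracketed by the complementarity inequalities of the bound alphas:
    # alpha = 0 needs y(m + b) >= 1, alpha = C needs y(m + b) <= 1
    at_zero <- alpha <= eps
    at_cap <- alpha >= C - eps
    lo <- suppressWarnings(max(c(g[at_zero & ypm == 1],
                                 g[at_cap & ypm == -1], -Inf)))
    up <- suppressWarnings(min(c(g[at_zero & ypm == -1],
                                 g[at_cap & ypm == 1], Inf)))
    if (is.finite(lo) && is.finite(up)) (lo + up) / 2
    else if (is.finite(lo)) lo else if (is.finite(up)) up else 0
  }
  list(alpha = alpha, w = w, b = b)
}

#' Reference one-vs-rest linear SVM fit via the dual QP
#'
#' Same return shape as [fit_linear_svm()], but every machine is solved with
#' [svm_dual_qp()]. Used by tests and the naive gene-selection oracle.
#'
#' @inheritParams fit_linear_svm
#' @return an `svm_state`, plus an `alpha` matrix (machines x cells).
#' @export
fit_linear_svm_qp <- function(block, labels, C = 1) {
  block <- as.matrix(block)
  cls <- sort(unique(as.integer(labels)))
  if (length(cls) < 2L) stop("single-class input: cannot fit an SVM")
  binary <- length(cls) == 2L
  machines <- if (binary) cls[2L] else cls
  W <- matrix(0, length(machines), ncol(block))
  b <- numeric(length(machines))
  A <- matrix(0, length(machines), nrow(block))
  for (k in seq_along(machines)) {
    ypm <- ifelse(labels == machines[k], 1, -1)
    fit <- svm_dual_qp(block, ypm, C)
    W[k, ] <- fit$w
    b[k] <- fit$b
    A[k, ] <- fit$alpha
  }
  st <- structure(list(classes = cls, machines = machines, W = W, b = b,
                       C = C, binary = binary),
                  class = "svm_state")
  st$alpha <- A
  st
}

# Deterministic sequential-minimal-optimization ascent on the same dual,
# used when the interior-point solver cannot factor its system. Pure R,
# independent of the production solver's code path.
smo_dual <- function(K, y, C, tol = 1e-6, max_iter = 2e5) {
  n <- length(y)
  a <- numeric(n)
  b <- 0
  quiet_passes <- 0L
  it <- 0L
  while (quiet_passes < 3L && it < max_iter) {
    changed <- 0L
    E_all <- drop(K %*% (a * y)) + b - y
    for (i in seq_len(n)) {
      Ei <- sum(a * y * K[, i]) + b - y[i]
      if (!((y[i] * Ei < -tol && a[i] < C - 1e-12) ||
            (y[i] * Ei > tol && a[i] > 1e-12))) next
      E_all <- drop(K %*% (a * y)) + b - y
      # try partners in order of decreasing |Ei - Ej| until one admits a step
      for (j in order(-abs(E_all - Ei))) {
        if (j == i) next
        Ej <- E_all[j]
        ai_old <- a[i]; aj_old <- a[j]
        if (y[i] != y[j]) {
          L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
        } else {
          L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
        }
        if (L >= H) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= -1e-14) next
        aj <- min(H, max(L, aj_old - y[j] * (Ei - Ej) / eta))
        if (abs(aj - aj_old) < 1e-10) next
        ai <- ai_old + y[i] * y[j] * (aj_old - aj)
        b1 <- b - Ei - y[i] * (ai - ai_old) * K[i, i] -
          y[j] * (aj - aj_old) * K[i, j]
        b2 <- b - Ej - y[i] * (ai - ai_old) * K[i, j] -
          y[j] * (aj - aj_old) * K[j, j]
        b <- if (ai > 1e-12 && ai < C - 1e-12) b1
             else if (aj > 1e-12 && aj < C - 1e-12) b2
             else (b1 + b2) / 2
        a[i] <- ai; a[j] <- aj
        changed <- changed + 1L
        it <- it + 1L
        break
      }
    }
    quiet_passes <- if (changed == 0L) quiet_passes + 1L else 0L
  }
  list(alpha = a, b = b)
}
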
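#' Discrete image gradient (backward differences)
#'
#' Computes backward finite differences along columns (`gx`, the x
#' direction) and rows (`gy`, the y direction). Differences that would
#' reference a pixel outside the grid are set to zero, so the first column
#' of `gx` and the first row of `gy` are zero and the gradient of a constant
#' image vanishes exactly.
#'
#' @param f numeric matrix, at least 2 x 2.
#' @return A list of class `gradient_field` with matrices `gx`, `gy`.
#' @export
grad <- function(f) {
  if (!is.matrix(f) || nrow(f) < 2 || ncol(f) < 2) {
    stop_invalid("'f' must be a matrix of size at least 2x2")
  }
  gx <- f
  gx[, 1] <- 0
  gx[, -1] <- f[, -1, drop = FALSE] - f[, -ncol(f), drop = FALSE]
  gy <- f
  gy[1, ] <- 0
  gy[-1, ] <- f[-1, , drop = FALSE] - f[-nrow(f), , drop = FALSE]
  structure(list(gx = gx, gy = gy), class = "gradient_field")
}

## single-direction differences (used by the reconstruction loops)
grad_x <- function(f) {
  g <- f
  g[, 1] <- 0
  g[, -1] <- f[, -1, drop = FALSE] - f[, -ncol(f), drop = FALSE]
  g
}

grad_y <- function(f) {
  g <- f
  g[1, ] <- 0
  g[-1, ] <- f[-1, , drop = FALSE] - f[-nrow(f), , drop = FALSE]
  g
}

## exact adjoints of grad_x / grad_y (transposes of the difference matrices)
grad_x_adj <- function(g) {
  N <- ncol(g)
  out <- g
  out[, N] <- g[, N]
  out[, -N] <- g[, -N, drop = FALSE] - g[, -1, drop = FALSE]
  out[, 1] <- -g[, 2]
  out
}

grad_y_adj <- function(g) {
  M <- nrow(g)
  out <- g
  out[M, ] <- g[M, ]
  out[-M, ] <- g[-M, , drop = FALSE] - g[-1, , drop = FALSE]
  out[1, ] <- -g[2, ]
  out
}

#' Adjoint of the discrete gradient
#'
#' Applies the exact adjoint (negative divergence with the matching boundary
#' convention) of [grad()], so that
#' `sum(grad(f)$gx * g$gx) + sum(grad(f)$gy * g$gy) == sum(f * grad_adjoint(g))`.
#'
#' @param g a `gradient_field` (or a list with matrices `gx`, `gy`).
#' @return Numeric matrix of the image shape.
#' @export
grad_adjoint <- function(g) {
  if (!is.list(g) || is.null(g$gx) || is.null(g$gy)) {
    stop_invalid("'g' must be a gradient_field with components gx and gy")
  }
  if (!all(dim(g$gx) == dim(g$gy))) stop_invalid("gx and gy shapes differ")
  grad_x_adj(g$gx) + grad_y_adj(g$gy)
}

#' Total variation of an image
#'
#' Anisotropically-discretized isotropic-magnitude TV: the sum over pixels of
#' `sqrt(gx^2 + gy^2)` with the backward-difference gradient of [grad()].
#'
#' @param f numeric matrix, at least 2 x 2.
#' @return Nonnegative scalar; zero iff `f` is constant.
#' @export
tv <- function(f) {
  g <- grad(f)
  sum(sqrt(g$gx^2 + g$gy^2))
}

#' Soft-thresholding (shrinkage) operator
#'
#' Elementwise `sign(x) * max(|x| - t, 0)`, the proximal operator of
#' `t * |.|`. Used for the L1 subproblem updates of the Split-Bregman
#' iteration.
#'
#' @param x numeric scalar, vector or matrix.
#' @param t threshold, a single value >= 0.
#' @return Object shaped like `x`.
#' @examples
#' shrink(c(5, -1, 0.5), 2)
#' @export
shrink <- function(x, t) {
  if (!is.numeric(t) || length(t) != 1 || is.na(t) || t < 0) {
    stop_invalid("'t' must be a single threshold >= 0")
  }
  sign(x) * pmax(abs(x) - t, 0)
}
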
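## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths: plain loops, explicit matrices, dense
## numerical integration.

## per-pixel, per-ellipse membership rasterizer (double loop)
brute_force_phantom <- function(size) {
  ell <- shepp_logan_ellipses()
  f <- matrix(0, size, size)
  for (i in seq_len(size)) {
    for (j in seq_len(size)) {
      x <- (j - 0.5) / size * 2 - 1
      y <- 1 - (i - 0.5) / size * 2
      v <- 0
      for (e in seq_len(nrow(ell))) {
        th <- ell$phi[e] * pi / 180
        u <- (x - ell$x0[e]) * cos(th) + (y - ell$y0[e]) * sin(th)
        w <- -(x - ell$x0[e]) * sin(th) + (y - ell$y0[e]) * cos(th)
        if ((u / ell$a[e])^2 + (w / ell$b[e])^2 <= 1) v <- v + ell$A[e]
      }
      f[i, j] <- v
    }
  }
  f
}

## explicit sparse matrices of the backward-difference operators on an
## M x N grid (column-major vectorization), zero first column/row
grad_matrices <- function(M, N) {
  dcol <- function(n) {
    D <- diag(n)
    D[1, 1] <- 0
    for (i in 2:n) D[i, i - 1] <- -1
    D
  }
  list(
    Dx = kronecker(dcol(N), diag(M)),  # differences across columns
    Dy = kronecker(diag(N), dcol(M))   # differences across rows
  )
}

## dense ray-marching line integral of an image for a parallel ray at
## 'angle_deg' and detector offset s (pixel units), matching the package's
## geometry conventions (image centred on the origin, row 1 on top)
ray_march <- function(f, angle_deg, s, h = 0.001) {
  M <- nrow(f); N <- ncol(f)
  th <- angle_deg * pi / 180
  ux <- cos(th); uy <- sin(th)
  vx <- -uy; vy <- ux
  tmax <- sqrt(M^2 + N^2) / 2 + 1
  t <- seq(-tmax, tmax, by = h)
  x <- s * ux + t * vx
  y <- s * uy + t * vy
  j <- floor(x + N / 2) + 1
  i <- floor(M / 2 - y) + 1
  ok <- i >= 1 & i <= M & j >= 1 & j <= N
  sum(f[cbind(i[ok], j[ok])]) * h
}

## classic single-regularizer Split-Bregman denoiser with exact diagonal
## f-solves (A = I, Phi = I): min lambda||f-p||^2 + |f|_1 surrogate
reference_split_bregman <- function(p, lambda, mu, thresh, n_iter = 400) {
  f <- p
  d <- f * 0
  b <- f * 0
  for (k in seq_len(n_iter)) {
    f <- (lambda * p + mu * (d - b)) / (lambda + mu)
    d <- shrink(f + b, thresh)
    b <- b + f - d
  }
  list(f = f, d = d, b = b)
}

## shared small tomography fixture
small_problem <- function(size = 32, n_views = 12, seed = 1) {
  ph <- make_phantom(size)
  g <- projection_geometry(n_views = n_views, n_detectors = size)
  A <- build_system_matrix(dim(ph), g)
  list(phantom = ph, geometry = g, A = A, p = project(A, ph))
}
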
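test_that("a single Kaczmarz update projects onto the row hyperplane", {
  f <- art_sweep(c(0, 0), matrix(c(1, 0), 1, 2), 2)
  expect_equal(f, c(2, 0))
  ## after the sweep, the last row's equation holds exactly
  set.seed(16)
  A <- matrix(rnorm(48), 6, 8)
  p <- rnorm(6)
  f <- art_sweep(rep(0, 8), A, p)
  expect_lt(abs(sum(A[6, ] * f) - p[6]), 1e-12)
})

test_that("repeated sweeps solve a consistent system", {
  A <- matrix(c(2, 1, 1, 3), 2, 2)
  xstar <- c(1, -2)
  p <- as.numeric(A %*% xstar)
  f <- c(0, 0)
  for (i in 1:100) f <- art_sweep(f, A, p)
  expect_lt(sqrt(sum((A %*% f - p)^2)), 1e-8)
  expect_equal(f, xstar, tolerance = 1e-6)
})

test_that("art_sweep rejects an all-zero system matrix", {
  expect_error(art_sweep(c(0, 0), matrix(0, 2, 2), c(1, 1)),
               class = "nactct_invalid_argument")
})

test_that("positivity clamps negatives and never increases a pixel", {
  expect_equal(positivity(matrix(c(-1, 0, 2, -3), 2, 2)),
               matrix(c(0, 0, 2, 0), 2, 2))
  x <- matrix(runif(25), 5)
  expect_identical(positivity(x), x)
  y <- matrix(rnorm(25), 5)
  expect_true(all(positivity(y) >= y))
})

test_that("ART converges on a small consistent tomography problem", {
  set.seed(17)
  fstar <- matrix(runif(64, 0.2, 1), 8, 8)  # strictly positive ground truth
  g <- projection_geometry(n_views = 32, n_detectors = 8)
  A <- build_system_matrix(c(8, 8), g)
  p <- project(A, fstar)
  f <- art_reconstruct(A, p, recon_params(n_outer = 500))
  expect_lt(rmse(fstar, f), 1e-3)
})

test_that("zero sinogram reconstructs the zero image with every algorithm", {
  prob <- small_problem(16, 6)
  p0 <- matrix(0, 6, 16)
  pr <- recon_params(n_outer = 3, k_inner = 2)
  expect_equal(max(abs(art_reconstruct(prob$A, p0, pr))), 0)
  expect_equal(max(abs(art_tv_reconstruct(prob$A, p0, pr))), 0)
  sp <- nact_spec(c(16, 16), levels = 2)
  expect_equal(max(abs(spbr_nact_reconstruct(prob$A, p0, pr,
                                             nact_transform(sp)))), 0)
})

test_that("data-only gradient matches central finite differences", {
  set.seed(18)
  prob <- small_problem(16, 6)
  f <- matrix(runif(256), 16)
  pv <- nactct:::sino_to_rays(prob$p)
  params <- recon_params(lambda = 1000)
  m <- 3
  gr <- spbr_gradient(f, prob$A, prob$p, m = m, state = list(),
                      params = params)
  rows <- ((m - 1) * 16 + 1):(m * 16)
  Am <- prob$A$A[rows, , drop = FALSE]
  obj <- function(x) {
    params$lambda * sum((as.numeric(Am %*% as.numeric(x)) - pv[rows])^2)
  }
  h <- 1e-5
  for (idx in c(1, 50, 137, 256)) {
    fp <- f; fp[idx] <- fp[idx] + h
    fm <- f; fm[idx] <- fm[idx] - h
    num <- (obj(fp) - obj(fm)) / (2 * h)
    expect_lt(abs(gr$g[idx] - num) / (abs(num) + 1e-8), 1e-5)
  }
  ## normalized direction has unit norm whenever g is nonzero
  expect_equal(sum(gr$ghat^2), 1, tolerance = 1e-12)
})

test_that("gradient vanishes at the solution of the quadratic subproblem", {
  set.seed(19)
  M <- 4; N <- 4; npix <- 16
  A <- matrix(rnorm(10 * npix), 10, npix)
  p <- rnorm(10)
  mats <- grad_matrices(M, N)
  params <- recon_params(lambda = 2, gamma = 3, mu = 5)
  dx <- matrix(rnorm(npix), M); dy <- matrix(rnorm(npix), M)
  bx <- matrix(rnorm(npix), M); by <- matrix(rnorm(npix), M)
  dphi <- matrix(rnorm(npix), M); bphi <- matrix(rnorm(npix), M)
  ## normal equations of lambda||Af-p||^2 + gamma||dx - Dx f - bx||^2
  ##   + gamma||dy - Dy f - by||^2 + mu||dphi - f - bphi||^2
  H <- 2 * params$lambda * crossprod(A) +
    2 * params$gamma * (crossprod(mats$Dx) + crossprod(mats$Dy)) +
    2 * params$mu * diag(npix)
  rhs <- 2 * params$lambda * crossprod(A, p) +
    2 * params$gamma * (t(mats$Dx) %*% as.numeric(dx - bx) +
                          t(mats$Dy) %*% as.numeric(dy - by)) +
    2 * params$mu * as.numeric(dphi - bphi)
  fstar <- matrix(solve(H, rhs), M, N)
  state <- list(dx = dx, dy = dy, bx = bx, by = by,
                dphi = dphi, bphi = bphi, transform = identity_transform())
  gr <- spbr_gradient(fstar, A, p, m = 1, state = state, params = params)
  expect_lt(sqrt(sum(gr$g^2)) / sqrt(sum(rhs^2)), 1e-8)
})

test_that("compiled inner sweep agrees with the reference R gradient loop", {
  set.seed(20)
  prob <- small_problem(16, 6)
  sp <- nact_spec(c(16, 16), levels = 2, dirs_per_level = c(4, 8))
  tr <- nact_transform(sp)
  params <- recon_params(lambda = 1000, gamma = 30, mu = 30)
  f0 <- positivity(matrix(rnorm(256, 0.3, 0.2), 16))
  dx <- grad(f0)$gx + 0.1; dy <- grad(f0)$gy - 0.05
  bx <- matrix(rnorm(256, 0, 0.01), 16); by <- matrix(rnorm(256, 0, 0.01), 16)
  dphi <- nact_forward(f0 + 0.1, sp)
  bphi <- nact_forward(matrix(rnorm(256, 0, 0.01), 16), sp)
  step <- 0.07
  ## reference: sequential per-view updates with the R gradient
  f_ref <- f0
  state <- list(dx = dx, dy = dy, bx = bx, by = by,
                dphi = dphi, bphi = bphi, transform = tr)
  for (m in 1:6) {
    gr <- spbr_gradient(f_ref, prob$A, prob$p, m = m, state = state,
                        params = params)
    f_ref <- f_ref - step * gr$ghat
  }
  ## compiled path with the per-iteration precomputations
  tx <- nactct:::grad_x_adj(dx - bx)
  ty <- nactct:::grad_y_adj(dy - by)
  rphi <- nact_adjoint(nactct:::tc_sub(dphi, bphi), sp)
  fv <- nactct:::spbr_inner_sweep_csr(
    prob$A$csr$row_ptr, prob$A$csr$cols, prob$A$csr$vals,
    nactct:::sino_to_rays(prob$p), as.numeric(f0), 16L, 16L, 16L,
    as.numeric(tx), as.numeric(ty), as.numeric(rphi),
    params$lambda, params$gamma, params$mu, step
  )
  expect_equal(matrix(fv, 16, 16), f_ref, tolerance = 1e-8)
})

test_that("reconstructions are nonnegative and data fidelity is monotone", {
  prob <- small_problem(32, 10)
  pr <- recon_params(n_outer = 12)
  f <- art_tv_reconstruct(prob$A, prob$p, pr, reference = prob$phantom)
  expect_true(all(f >= 0))
  res <- attr(f, "metrics")$residual
  expect_true(all(diff(res) <= 0.01 * res[-length(res)]))
  fs <- spbr_nact_reconstruct(prob$A, prob$p, recon_params(n_outer = 6),
                              transform = nact_transform(nact_spec(c(32, 32))))
  expect_true(all(fs >= 0))
})

test_that("the residual stopping rule halts the outer loop", {
  prob <- small_problem(16, 10)
  ## large sigma: the very first outer iteration already satisfies the bound
  pr <- recon_params(n_outer = 30, sigma = sqrt(sum(unclass(prob$p)^2)))
  f <- art_tv_reconstruct(prob$A, prob$p, pr, reference = prob$phantom)
  expect_equal(nrow(attr(f, "metrics")), 1)
})

test_that("classic Split-Bregman fixed point is stationary for the engine", {
  ## identity system + identity transform: the engine's gradient must vanish
  ## at the converged state of an independent exact-solve implementation
  set.seed(22)
  truth <- matrix(runif(256, 0, 1), 16)
  noisy <- truth + matrix(rnorm(256, 0, 0.1), 16)
  lambda <- 10; mu <- 5; thresh <- 1 / mu
  ref <- reference_split_bregman(noisy, lambda, mu, thresh, n_iter = 500)
  state <- list(dphi = ref$d, bphi = ref$b, transform = identity_transform())
  gr <- spbr_gradient(ref$f, diag(256), as.numeric(noisy), m = 1,
                      state = state,
                      params = recon_params(lambda = lambda, mu = mu))
  expect_lt(sqrt(sum(gr$g^2)) / sqrt(sum(ref$f^2)), 1e-6)
})
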
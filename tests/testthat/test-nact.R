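test_that("pyramid windows satisfy the complementarity identities", {
  np <- design_npfb(c(64, 64), a = 0.2 * pi)
  expect_lt(max(abs(np$D0^2 + np$L0^2 - 1)), 1e-12)
  expect_lt(max(abs(np$D1^2 + np$L1^2 / 4 - 1)), 1e-12)
  ## DC: low-pass passes, high-pass blocks
  expect_equal(np$L0[1, 1], 1)
  expect_equal(np$D0[1, 1], 0)
  expect_equal(np$L1[1, 1], 2)
  expect_equal(np$D1[1, 1], 0)
  ## band edges derived from the mixing width
  expect_lt(np$edges$ws1, pi / 2)
  expect_equal((np$edges$wp0 + np$edges$ws0) / 2, pi / 2)
  expect_equal((np$edges$wp1 + np$edges$ws1) / 2, pi / 4)
})

test_that("npfb design rejects invalid mixing widths and grids", {
  expect_error(design_npfb(c(64, 64), a = 0), class = "nactct_invalid_argument")
  expect_error(design_npfb(c(64, 64), a = pi), class = "nactct_invalid_argument")
  expect_error(design_npfb(c(4, 4)), class = "nactct_invalid_argument")
})

test_that("directional windows form an exact squared partition of unity", {
  for (n in c(4, 8)) {
    wins <- dfb_windows(c(32, 48), n)
    ssum <- Reduce(`+`, lapply(wins, function(w) w^2))
    expect_lt(max(abs(ssum - 1)), 1e-12)
    ## symmetry W(-omega) = W(omega): required for real subbands
    for (w in wins) {
      expect_equal(w, w[c(1, 32:2), c(1, 48:2)], tolerance = 1e-14)
    }
  }
})

test_that("round trip is exact for all tested configurations", {
  configs <- list(
    list(shape = c(16, 16), levels = 1, dirs = 4),
    list(shape = c(32, 32), levels = 2, dirs = c(4, 8)),
    list(shape = c(40, 40), levels = 3, dirs = c(4, 8, 8)),
    list(shape = c(24, 32), levels = 2, dirs = c(8, 4))
  )
  set.seed(99)
  for (cf in configs) {
    sp <- nact_spec(cf$shape, levels = cf$levels, dirs_per_level = cf$dirs)
    for (rep in 1:25) {
      f <- matrix(rnorm(prod(cf$shape)), cf$shape[1], cf$shape[2])
      co <- nact_forward(f, sp)
      expect_lt(max(abs(nact_inverse(co, sp) - f)), 1e-6)
    }
  }
})

test_that("the frame is Parseval: energy preserved, adjoint equals inverse", {
  set.seed(5)
  sp <- nact_spec(c(32, 32), levels = 3)
  f <- matrix(rnorm(32^2), 32)
  co <- nact_forward(f, sp)
  ## tight-frame identities
  expect_equal(nactct:::coef_norm2(co), sum(f^2), tolerance = 1e-12)
  expect_lt(max(abs(nact_adjoint(co, sp) - nact_inverse(co, sp))), 1e-12)
  expect_lt(max(abs(nact_adjoint(co, sp) - f)), 1e-10)
  ## redundant frame: more coefficients than pixels
  expect_gte(coef_length(co), length(f))
  ## impulse energy balance (1-level, 4-direction configuration)
  sp1 <- nact_spec(c(16, 16), levels = 1, dirs_per_level = 4)
  imp <- matrix(0, 16, 16); imp[8, 8] <- 1
  ci <- nact_forward(imp, sp1)
  expect_lt(abs(nactct:::coef_norm2(ci) / sum(imp^2) - 1), 0.01)
})

test_that("adjoint satisfies the inner-product identity", {
  set.seed(21)
  sp <- nact_spec(c(32, 32), levels = 2, dirs_per_level = c(4, 8))
  f <- matrix(rnorm(32^2), 32)
  c2 <- nact_forward(matrix(rnorm(32^2), 32), sp)
  lhs <- nactct:::coef_inner(nact_forward(f, sp), c2)
  rhs <- sum(f * nact_adjoint(c2, sp))
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-8)
})

test_that("constant images produce zero detail subbands", {
  sp <- nact_spec(c(32, 32), levels = 3)
  co <- nact_forward(matrix(2.5, 32, 32), sp)
  for (lev in co$details) {
    for (d in lev) expect_lt(max(abs(d)), 1e-10)
  }
  ## all-zero coefficients reconstruct the zero image
  z <- nactct:::coef_zero_like(co)
  expect_equal(max(abs(nact_inverse(z, sp))), 0)
})

test_that("keeping only the approximation equals the cascaded low-pass filter", {
  set.seed(31)
  sp <- nact_spec(c(32, 32), levels = 2, dirs_per_level = c(4, 8))
  f <- make_phantom(32)
  co <- nact_forward(f, sp)
  co_lp <- nactct:::coef_map2(co, nactct:::coef_zero_like(co),
                              function(a, b) b)
  co_lp$approx <- co$approx
  rec <- nact_inverse(co_lp, sp)
  ## oracle: direct FFT-domain application of L0, then L1 with the
  ## decimate/zero-insert pair (spectral alias folding)
  n <- 32^2
  X <- stats::fft(f)
  Y1 <- X * sp$stages[[1]]$L
  Y2 <- Y1 * sp$stages[[2]]$L
  y2 <- Re(stats::fft(Y2, inverse = TRUE)) / n
  dec <- y2[seq(1, 32, 2), seq(1, 32, 2)]
  up <- matrix(0, 32, 32)
  up[seq(1, 32, 2), seq(1, 32, 2)] <- dec
  oracle <- Re(stats::fft(stats::fft(up) * sp$stages[[2]]$L *
                            sp$stages[[1]]$L, inverse = TRUE)) / n
  expect_lt(max(abs(rec - oracle)), 1e-10)
})

test_that("shifting the input shifts the approximation on the coarse grid", {
  set.seed(8)
  sp <- nact_spec(c(32, 32), levels = 3)
  f <- matrix(rnorm(32^2), 32)
  dec <- 2^(sp$levels - 1)
  fs <- f[, c((32 - dec + 1):32, 1:(32 - dec))]  # circular shift by dec cols
  a0 <- nact_forward(f, sp)$approx
  a1 <- nact_forward(fs, sp)$approx
  nc <- ncol(a0)
  expect_equal(a1, a0[, c(nc, 1:(nc - 1))], tolerance = 1e-10)
})

test_that("oriented lines land in the matching directional subband", {
  sp <- nact_spec(c(32, 32), levels = 1, dirs_per_level = 4)
  draw_line <- function(alpha_deg) {
    f <- matrix(0, 32, 32)
    th <- alpha_deg * pi / 180
    for (t in seq(-14, 14, by = 0.25)) {
      j <- round(16.5 + t * cos(th))
      i <- round(16.5 - t * sin(th))
      if (i >= 1 && i <= 32 && j >= 1 && j <= 32) f[i, j] <- 1
    }
    f
  }
  ## a spatial line at angle alpha (drawn with y up; matrix rows run
  ## downward, flipping the sign of the frequency-domain angle)
  ## concentrates its spectrum in the wedge at 90 - alpha degrees;
  ## wedge k is centred at (k-1)*45 degrees
  cases <- list(c(90, 1), c(45, 2), c(0, 3), c(135, 4))
  for (cs in cases) {
    co <- nact_forward(draw_line(cs[1]), sp)
    energies <- vapply(co$details[[1]], function(d) sum(d^2), numeric(1))
    expect_equal(which.max(energies), cs[2])
  }
})

test_that("shape and divisibility preconditions are enforced", {
  expect_error(nact_spec(c(30, 30), levels = 3),
               class = "nactct_invalid_argument")
  sp <- nact_spec(c(16, 16), levels = 2)
  expect_error(nact_forward(matrix(0, 8, 8), sp),
               class = "nactct_invalid_argument")
  co <- nact_forward(matrix(0, 16, 16), sp)
  co$details[[1]] <- co$details[[1]][-1]
  expect_error(nact_adjoint(co, sp), class = "nactct_invalid_argument")
})
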
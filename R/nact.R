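## Non-aliasing contourlet transform (NACT)
##
## The transform composes a non-aliasing pyramid (radial frequency windows
## whose squared magnitudes are complementary, so the frame is tight and the
## decimated low-pass branch is free of aliasing) with directional frequency
## windows that partition each high-pass annulus into orientation wedges.
## Everything is realized multiplicatively on the FFT grid with periodic
## boundary handling; the whole map is a Parseval frame, so the adjoint
## equals the inverse.

## Meyer smooth step: nu(0)=0, nu(1)=1, C3 at both ends
meyer_nu <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t^4 * (35 - 84 * t + 70 * t^2 - 20 * t^3)
}

## angular frequencies of an n-point FFT grid, in (-pi, pi]
fft_omega <- function(n) {
  k <- seq_len(n) - 1
  k[k >= n / 2] <- k[k >= n / 2] - n
  2 * pi * k / n
}

## radial low-pass window on an M x N FFT grid: 1 inside wp, Meyer
## raised-cosine roll-off to 0 at ws, times 'gain'
radial_window <- function(M, N, wp, ws, gain = 1) {
  wx <- matrix(fft_omega(N), M, N, byrow = TRUE)
  wy <- matrix(fft_omega(M), M, N)
  r <- sqrt(wx^2 + wy^2)
  t <- (r - wp) / (ws - wp)
  gain * cos(pi / 2 * meyer_nu(t))
}

## index permutation mapping FFT bin k to -k (mod n)
fft_reverse_index <- function(n) c(1L, seq(n, 2L))

#' Design the non-aliasing pyramidal filter bank
#'
#' Builds the first-stage (`L0`, `D0`) and subsequent-stage (`L1`, `D1`)
#' frequency windows on an FFT grid. The low-pass windows are radial
#' Meyer-type raised cosines; the high-pass windows are defined as the exact
#' magnitude complements, `D0 = sqrt(1 - L0^2)` and `D1 = sqrt(1 - L1^2/4)`,
#' so the complementarity identities hold to machine precision by
#' construction. Band edges are derived from the directional mixing width
#' `a`: `ws0 = pi - a`, `wp0 = a`, `ws1 = (pi - a)/2`, `wp1 = a/2`, which
#' places the transition midpoints at `pi/2` and `pi/4` and keeps the
#' decimated low-pass branch alias-free (`ws1 < pi/2`).
#'
#' @param grid_shape integer vector `c(M, N)`, both >= 8.
#' @param a mixing width in radians, `0 < a < pi/2`.
#' @param transition transition profile; only `"meyer"` is implemented.
#' @return An object of class `npfb_spec` with window matrices `L0`, `D0`,
#'   `L1`, `D1` and the band edges.
#' @export
design_npfb <- function(grid_shape, a = 0.2 * pi, transition = "meyer") {
  if (length(grid_shape) != 2 || any(grid_shape < 8)) {
    stop_invalid("'grid_shape' must be c(M, N) with both >= 8")
  }
  if (!is.numeric(a) || length(a) != 1 || is.na(a) || a <= 0 || a >= pi / 2) {
    stop_invalid("'a' must lie strictly between 0 and pi/2")
  }
  transition <- match.arg(transition)
  M <- as.integer(grid_shape[1]); N <- as.integer(grid_shape[2])
  edges <- list(
    wp0 = a, ws0 = pi - a,
    wp1 = a / 2, ws1 = (pi - a) / 2
  )
  stopifnot(
    edges$ws1 < pi / 2,
    abs((edges$wp0 + edges$ws0) / 2 - pi / 2) < 1e-12,
    abs((edges$wp1 + edges$ws1) / 2 - pi / 4) < 1e-12,
    edges$ws0 <= pi - a + 1e-12,
    edges$ws1 <= (pi - a) / 2 + 1e-12
  )
  L0 <- radial_window(M, N, edges$wp0, edges$ws0)
  D0 <- sqrt(pmax(1 - L0^2, 0))
  L1 <- radial_window(M, N, edges$wp1, edges$ws1, gain = 2)
  D1 <- sqrt(pmax(1 - L1^2 / 4, 0))
  structure(
    list(L0 = L0, D0 = D0, L1 = L1, D1 = D1, edges = edges, a = a,
         grid_shape = c(M, N)),
    class = "npfb_spec"
  )
}

#' Directional frequency windows
#'
#' Partitions the frequency plane into `n_dirs` antipodally-symmetric
#' orientation wedges whose squared magnitudes sum to one everywhere.
#' Wedge `k` is centred on the spectral orientation `(k-1) * pi / n_dirs`
#' (measured from the positive x frequency axis) with Meyer raised-cosine
#' angular roll-off into its two neighbours. The windows are explicitly
#' symmetrized on the FFT grid and renormalized so both the real-output and
#' the partition property hold to machine precision.
#'
#' @param grid_shape integer vector `c(M, N)`.
#' @param n_dirs number of directional wedges (>= 2).
#' @return List of `n_dirs` window matrices.
#' @export
dfb_windows <- function(grid_shape, n_dirs) {
  if (length(grid_shape) != 2 || any(grid_shape < 4)) {
    stop_invalid("'grid_shape' must be c(M, N) with both >= 4")
  }
  if (!is.numeric(n_dirs) || n_dirs < 2) {
    stop_invalid("'n_dirs' must be >= 2")
  }
  M <- as.integer(grid_shape[1]); N <- as.integer(grid_shape[2])
  n_dirs <- as.integer(n_dirs)
  wx <- matrix(fft_omega(N), M, N, byrow = TRUE)
  wy <- matrix(fft_omega(M), M, N)
  phi <- atan2(wy, wx) %% pi
  ri <- fft_reverse_index(M); ci <- fft_reverse_index(N)
  wins <- vector("list", n_dirs)
  for (k in seq_len(n_dirs)) {
    centre <- (k - 1) * pi / n_dirs
    d <- abs(((phi - centre + pi / 2) %% pi) - pi / 2)  # circular distance mod pi
    w <- ifelse(d <= pi / n_dirs, cos(pi / 2 * meyer_nu(d * n_dirs / pi)), 0)
    wins[[k]] <- (w + w[ri, ci]) / 2  # enforce W(-omega) = W(omega)
  }
  s <- sqrt(Reduce(`+`, lapply(wins, function(w) w^2)))
  s[s == 0] <- 1
  lapply(wins, function(w) w / s)
}

#' Specify a full NACT decomposition
#'
#' Combines the pyramid windows of [design_npfb()] with directional windows
#' at every level. Level 1 (the finest scale) uses the undecimated
#' first-stage pair `L0`/`D0`; levels `2..levels` use the `L1`/`D1` pair on
#' successively halved grids, decimating the low-pass branch by two after
#' each stage. The approximation subband therefore lives on a grid reduced
#' by `2^(levels-1)`, and the image dimensions must be divisible by that
#' factor.
#'
#' @param image_shape integer vector `c(M, N)`.
#' @param levels decomposition depth (>= 1).
#' @param dirs_per_level direction count per level (each a power of two);
#'   recycled or truncated to `levels` entries.
#' @param a mixing width in radians passed to [design_npfb()].
#' @return An object of class `nact_spec`.
#' @export
nact_spec <- function(image_shape, levels = 3, dirs_per_level = c(4, 8, 8),
                      a = 0.2 * pi) {
  if (length(image_shape) != 2 || any(image_shape < 8)) {
    stop_invalid("'image_shape' must be c(M, N) with both >= 8")
  }
  if (levels < 1) stop_invalid("'levels' must be >= 1")
  M <- as.integer(image_shape[1]); N <- as.integer(image_shape[2])
  dec <- 2^(levels - 1)
  if (M %% dec != 0 || N %% dec != 0) {
    stop_invalid("image dimensions must be divisible by 2^(levels-1)")
  }
  dirs_per_level <- rep_len(as.integer(dirs_per_level), levels)
  stages <- vector("list", levels)
  for (j in seq_len(levels)) {
    fac <- if (j <= 2) 1L else 2L^(j - 2L)
    gm <- M %/% fac; gn <- N %/% fac
    np <- design_npfb(c(gm, gn), a = a)
    if (j == 1) {
      L <- np$L0; D <- np$D0; decimate <- FALSE
    } else {
      L <- np$L1; D <- np$D1; decimate <- TRUE
    }
    stages[[j]] <- list(
      L = L, D = D, decimate = decimate,
      dirs = dfb_windows(c(gm, gn), dirs_per_level[j]),
      grid = c(gm, gn)
    )
  }
  structure(
    list(stages = stages, levels = levels, dirs_per_level = dirs_per_level,
         a = a, image_shape = c(M, N)),
    class = "nact_spec"
  )
}

## unitary 2-D FFT helpers
ufft <- function(x) stats::fft(x) / sqrt(length(x))
uifft <- function(x) stats::fft(x, inverse = TRUE) / sqrt(length(x))

#' Forward NACT
#'
#' Decomposes an image into one approximation subband and, per level, a list
#' of directional detail subbands. The frame is Parseval-tight: total
#' coefficient energy equals image energy and [nact_adjoint()] inverts the
#' map exactly.
#'
#' @param f numeric image matrix matching `spec$image_shape`.
#' @param spec a [nact_spec()].
#' @return An object of class `nact_coefficients` with elements `approx`
#'   (matrix) and `details` (list of per-level lists of matrices).
#' @export
nact_forward <- function(f, spec) {
  if (!inherits(spec, "nact_spec")) stop_invalid("'spec' must be a nact_spec")
  if (!is.matrix(f) || !all(dim(f) == spec$image_shape)) {
    stop_invalid("image shape does not match the transform spec")
  }
  x <- f
  details <- vector("list", spec$levels)
  for (j in seq_len(spec$levels)) {
    st <- spec$stages[[j]]
    X <- ufft(x)
    XD <- X * st$D
    details[[j]] <- lapply(st$dirs, function(W) Re(uifft(W * XD)))
    low <- Re(uifft(X * st$L))
    if (st$decimate) {
      low <- low[seq(1, nrow(low), 2), seq(1, ncol(low), 2), drop = FALSE]
    }
    x <- low
  }
  structure(
    list(approx = x, details = details, levels = spec$levels,
         dirs_per_level = spec$dirs_per_level, image_shape = spec$image_shape),
    class = "nact_coefficients"
  )
}

#' Adjoint (= inverse) NACT
#'
#' Applies the adjoint of [nact_forward()]. Because the transform is a
#' Parseval tight frame, the adjoint is also the exact inverse; both
#' [nact_adjoint()] and [nact_inverse()] return the same image.
#'
#' @param coef an `nact_coefficients` object.
#' @param spec the [nact_spec()] used for the forward transform.
#' @return Numeric image matrix.
#' @export
nact_adjoint <- function(coef, spec) {
  if (!inherits(spec, "nact_spec")) stop_invalid("'spec' must be a nact_spec")
  check_coef(coef, spec)
  x <- coef$approx
  for (j in rev(seq_len(spec$levels))) {
    st <- spec$stages[[j]]
    if (st$decimate) {
      up <- matrix(0, st$grid[1], st$grid[2])
      up[seq(1, st$grid[1], 2), seq(1, st$grid[2], 2)] <- x
      x <- up
    }
    Xacc <- ufft(x) * st$L
    for (k in seq_along(st$dirs)) {
      Xacc <- Xacc + ufft(coef$details[[j]][[k]]) * (st$dirs[[k]] * st$D)
    }
    x <- Re(uifft(Xacc))
  }
  x
}

#' @rdname nact_adjoint
#' @export
nact_inverse <- function(coef, spec) nact_adjoint(coef, spec)

check_coef <- function(coef, spec) {
  if (!inherits(coef, "nact_coefficients")) {
    stop_invalid("'coef' must be an nact_coefficients object")
  }
  if (length(coef$details) != spec$levels) {
    stop_invalid("coefficient levels do not match the spec")
  }
  for (j in seq_len(spec$levels)) {
    st <- spec$stages[[j]]
    if (length(coef$details[[j]]) != length(st$dirs)) {
      stop_invalid("direction counts do not match the spec")
    }
    for (d in coef$details[[j]]) {
      if (!all(dim(d) == st$grid)) stop_invalid("subband shape mismatch")
    }
  }
  lastg <- spec$stages[[spec$levels]]$grid
  fac <- if (spec$stages[[spec$levels]]$decimate) 2L else 1L
  if (!all(dim(coef$approx) == lastg %/% fac)) {
    stop_invalid("approximation subband shape mismatch")
  }
  invisible(TRUE)
}

## ---- elementwise arithmetic on coefficient objects ----------------------

coef_map <- function(a, fun) {
  a$approx <- fun(a$approx)
  a$details <- lapply(a$details, function(lev) lapply(lev, fun))
  a
}

coef_map2 <- function(a, b, fun) {
  a$approx <- fun(a$approx, b$approx)
  a$details <- lapply(seq_along(a$details), function(j) {
    lapply(seq_along(a$details[[j]]), function(k) {
      fun(a$details[[j]][[k]], b$details[[j]][[k]])
    })
  })
  a
}

coef_zero_like <- function(a) coef_map(a, function(x) x * 0)

coef_inner <- function(a, b) {
  s <- sum(a$approx * b$approx)
  for (j in seq_along(a$details)) {
    for (k in seq_along(a$details[[j]])) {
      s <- s + sum(a$details[[j]][[k]] * b$details[[j]][[k]])
    }
  }
  s
}

coef_norm2 <- function(a) coef_inner(a, a)

#' Number of coefficients in an NACT decomposition
#'
#' @param coef an `nact_coefficients` object.
#' @return Integer total count over all subbands.
#' @export
coef_length <- function(coef) {
  length(coef$approx) +
    sum(vapply(coef$details, function(lev) {
      sum(vapply(lev, length, integer(1)))
    }, numeric(1)))
}

#' @exportS3Method print nact_coefficients
print.nact_coefficients <- function(x, ...) {
  cat(sprintf(
    "NACT coefficients: %d levels, directions (%s), approx %dx%d, %d coefficients\n",
    x$levels, paste(x$dirs_per_level, collapse = ", "),
    nrow(x$approx), ncol(x$approx), coef_length(x)
  ))
  invisible(x)
}
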
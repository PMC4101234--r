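#' Reconstruction parameters
#'
#' Bundles the weights and loop counts of the iterative reconstructions.
#' `lambda` weighs the data-fidelity term, `gamma` the total-variation
#' channel, `mu` the contourlet channel; `step_a` scales the normalized
#' steepest-descent step; `k_inner` is the number of inner Split-Bregman
#' iterations per outer ART pass; `n_outer` the number of outer iterations.
#' `sigma` is the data-residual stopping tolerance: iteration stops early
#' once `||A f - p||^2 < sigma^2` (use `NULL` to always run `n_outer`
#' iterations). `threshold_convention` selects the shrinkage thresholds:
#' `"as_printed"` uses `1/lambda` for the gradient channels and `1/mu` for
#' the contourlet channel; `"weight_consistent"` uses `1/(2*gamma)` and
#' `1/(2*mu)`, the thresholds implied by the quadratic penalty weights.
#'
#' @param lambda data weight (> 0).
#' @param gamma TV weight (> 0).
#' @param mu contourlet weight (> 0).
#' @param step_a descent step scale (> 0).
#' @param k_inner inner iterations (>= 1).
#' @param n_outer outer iterations (>= 1).
#' @param sigma stopping tolerance on the data residual norm, or `NULL`.
#' @param threshold_convention `"as_printed"` or `"weight_consistent"`.
#' @return An object of class `recon_params`.
#' @export
recon_params <- function(lambda = 1000, gamma = 30, mu = 30, step_a = 0.2,
                         k_inner = 10, n_outer = 50, sigma = NULL,
                         threshold_convention = c("as_printed",
                                                  "weight_consistent")) {
  threshold_convention <- match.arg(threshold_convention)
  for (nm in c("lambda", "gamma", "mu", "step_a")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0) {
      stop_invalid("'", nm, "' must be a single positive number")
    }
  }
  if (k_inner < 1 || n_outer < 1) {
    stop_invalid("'k_inner' and 'n_outer' must be >= 1")
  }
  if (!is.null(sigma) && (!is.numeric(sigma) || sigma < 0)) {
    stop_invalid("'sigma' must be NULL or a nonnegative number")
  }
  structure(
    list(lambda = lambda, gamma = gamma, mu = mu, step_a = step_a,
         k_inner = as.integer(k_inner), n_outer = as.integer(n_outer),
         sigma = sigma, threshold_convention = threshold_convention),
    class = "recon_params"
  )
}

## ---- sparsifying-transform abstraction ----------------------------------

#' Identity sparsifying transform
#'
#' A trivial transform whose forward and adjoint maps are the identity;
#' useful for reducing the Split-Bregman machinery to its classic
#' single-regularizer form in tests and toy problems.
#'
#' @return An object of class `ct_transform`.
#' @export
identity_transform <- function() {
  structure(
    list(forward = function(f) f, adjoint = function(x) x, name = "identity"),
    class = "ct_transform"
  )
}

#' NACT sparsifying transform
#'
#' Wraps [nact_forward()] / [nact_adjoint()] for use inside the
#' reconstruction loops.
#'
#' @param spec a [nact_spec()].
#' @return An object of class `ct_transform`.
#' @export
nact_transform <- function(spec) {
  if (!inherits(spec, "nact_spec")) stop_invalid("'spec' must be a nact_spec")
  structure(
    list(
      forward = function(f) nact_forward(f, spec),
      adjoint = function(x) nact_adjoint(x, spec),
      spec = spec, name = "nact"
    ),
    class = "ct_transform"
  )
}

## elementwise helpers working on either plain matrices or nact coefficients
tc_map <- function(x, fun) {
  if (inherits(x, "nact_coefficients")) coef_map(x, fun) else fun(x)
}
tc_map2 <- function(x, y, fun) {
  if (inherits(x, "nact_coefficients")) coef_map2(x, y, fun) else fun(x, y)
}
tc_add <- function(x, y) tc_map2(x, y, `+`)
tc_sub <- function(x, y) tc_map2(x, y, `-`)
tc_shrink <- function(x, t) tc_map(x, function(v) shrink(v, t))
tc_zero <- function(x) tc_map(x, function(v) v * 0)

## ---- system-matrix coercion --------------------------------------------

## accept a full system_matrix or any (sparse) matrix, treated as one view
as_sysmat <- function(A) {
  if (inherits(A, "system_matrix")) return(A)
  Am <- methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE),
                                "generalMatrix"), "CsparseMatrix")
  g <- projection_geometry(n_detectors = nrow(Am), angles = 0)
  Ar <- methods::as(Am, "RsparseMatrix")
  csr <- list(row_ptr = Ar@p, cols = Ar@j, vals = Ar@x,
              row_norm2 = Matrix::rowSums(Am^2))
  ## image shape is unknown for a generic operator; keep a 1 x ncol layout
  structure(
    list(A = Am, csr = csr, geometry = g, image_shape = c(1L, ncol(Am))),
    class = "system_matrix"
  )
}

as_ray_vector <- function(p, sm) {
  n_rays <- nrow(sm$A)
  pv <- if (is.matrix(p) &&
            all(dim(p) == c(sm$geometry$n_views, sm$geometry$n_detectors))) {
    sino_to_rays(p)
  } else {
    as.numeric(p)
  }
  if (length(pv) != n_rays) stop_invalid("projection data length mismatch")
  pv
}

## image container matching the system matrix (or the given shape)
image_shape_of <- function(sm, f = NULL) {
  if (!is.null(f) && is.matrix(f)) return(dim(f))
  sm$image_shape
}

## ---- elementary operations ---------------------------------------------

#' One Kaczmarz (ART) sweep
#'
#' Performs sequential row-action updates
#' `f <- f + A_m (p_m - A_m f) / (A_m . A_m)` over every ray, in view order
#' (detectors fastest). Rays whose row is identically zero are skipped.
#' After the update of a row its equation holds exactly.
#'
#' @param f starting image (matrix matching the system matrix, or a numeric
#'   vector).
#' @param A a [build_system_matrix()] result or any matrix.
#' @param p projection data (sinogram matrix or ray-ordered vector).
#' @return Updated image, shaped like `f`.
#' @export
art_sweep <- function(f, A, p) {
  sm <- as_sysmat(A)
  if (all(sm$csr$row_norm2 == 0)) stop_invalid("system matrix is identically zero")
  pv <- as_ray_vector(p, sm)
  fv <- as.numeric(f)
  if (length(fv) != ncol(sm$A)) stop_invalid("image size mismatch")
  out <- kaczmarz_sweep_csr(sm$csr$row_ptr, sm$csr$cols, sm$csr$vals,
                            pv, fv, sm$csr$row_norm2)
  if (is.matrix(f)) matrix(out, nrow(f), ncol(f)) else out
}

#' Positivity constraint
#'
#' Elementwise `max(f, 0)`.
#'
#' @param f numeric image (matrix or vector).
#' @return Object shaped like `f` with negative entries clamped to zero.
#' @export
positivity <- function(f) pmax(f, 0)

#' ART reconstruction
#'
#' `n_outer` repetitions of one full Kaczmarz sweep followed by the
#' positivity constraint, starting from the zero image.
#'
#' @param A a [build_system_matrix()] result.
#' @param p projection data.
#' @param params a [recon_params()]; only `n_outer` is used.
#' @param reference optional ground-truth image; when given, per-iteration
#'   RMSE/UQI are recorded in the `metrics` attribute of the result.
#' @return Reconstructed nonnegative image matrix.
#' @export
art_reconstruct <- function(A, p, params = recon_params(), reference = NULL) {
  sm <- as_sysmat(A)
  pv <- as_ray_vector(p, sm)
  shp <- sm$image_shape
  f <- matrix(0, shp[1], shp[2])
  log <- if (is.null(reference)) NULL else
    data.frame(iteration = integer(), rmse = numeric(), uqi = numeric(),
               residual = numeric())
  for (n in seq_len(params$n_outer)) {
    f <- positivity(art_sweep(f, sm, pv))
    if (!is.null(reference)) {
      log[n, ] <- c(n, rmse(reference, f), uqi(reference, f),
                    sqrt(l2sq(sm$A %*% as.numeric(f) - pv)))
    }
  }
  attr(f, "metrics") <- log
  f
}

#' Split-Bregman descent gradient for one view block
#'
#' Evaluates the steepest-descent direction of the quadratic Split-Bregman
#' subproblem restricted to view `m`:
#' `g = 2*lambda*A_m^T (A_m f - p_m) - 2*gamma*Dx^T(dx - Dx f - bx)
#'      - 2*gamma*Dy^T(dy - Dy f - by) - 2*mu*Phi^T(dphi - Phi f - bphi)`,
#' and its L2-normalized version `ghat = g / ||g||` (zero when `g` is zero).
#' This is the reference formulation; the main loops use an equivalent
#' compiled kernel.
#'
#' @param f current image matrix.
#' @param A a [build_system_matrix()] result or plain matrix (then treated
#'   as a single view).
#' @param p projection data.
#' @param m view index (1-based).
#' @param state list with `dx`, `dy`, `bx`, `by` (matrices) and optionally
#'   `dphi`, `bphi`, `transform` for the sparsifying-transform channel.
#' @param params a [recon_params()]; set `gamma` or `mu` to a tiny value and
#'   the corresponding state entries to `NULL` to drop a channel (a channel
#'   is used only when its state entries are present).
#' @return List with `g`, `ghat` (matrices shaped like `f`) and `norm`.
#' @export
spbr_gradient <- function(f, A, p, m = 1, state = list(), params = recon_params()) {
  sm <- as_sysmat(A)
  pv <- as_ray_vector(p, sm)
  nd <- sm$geometry$n_detectors
  rows <- ((m - 1) * nd + 1):(m * nd)
  if (m < 1 || m > sm$geometry$n_views) stop_invalid("view index out of range")
  Am <- sm$A[rows, , drop = FALSE]
  res <- as.numeric(Am %*% as.numeric(f)) - pv[rows]
  g <- 2 * params$lambda * as.numeric(Matrix::crossprod(Am, res))
  g <- matrix(g, nrow(f), ncol(f))
  if (!is.null(state$dx)) {
    g <- g - 2 * params$gamma * grad_x_adj(state$dx - grad_x(f) - state$bx)
    g <- g - 2 * params$gamma * grad_y_adj(state$dy - grad_y(f) - state$by)
  }
  if (!is.null(state$dphi)) {
    tr <- state$transform
    resid <- tc_sub(tc_sub(state$dphi, tr$forward(f)), state$bphi)
    g <- g - 2 * params$mu * tr$adjoint(resid)
  }
  nrm <- sqrt(l2sq(g))
  list(g = g, ghat = if (nrm > 0) g / nrm else g * 0, norm = nrm)
}

## ---- the shared two-loop engine ----------------------------------------

## Outer loop: ART sweep + positivity; inner loop: K normalized-descent
## passes over the view blocks with shrinkage/Bregman updates of the TV
## channels and (optionally) the sparsifying-transform channel.
two_loop_recon <- function(A, p, params, transform = NULL, reference = NULL) {
  sm <- as_sysmat(A)
  if (all(sm$csr$row_norm2 == 0)) stop_invalid("system matrix is identically zero")
  pv <- as_ray_vector(p, sm)
  shp <- sm$image_shape
  M <- shp[1]; N <- shp[2]
  nd <- sm$geometry$n_detectors
  use_phi <- !is.null(transform)
  mu_eff <- if (use_phi) params$mu else 0
  thr <- switch(params$threshold_convention,
    as_printed = list(xy = 1 / params$lambda, phi = 1 / params$mu),
    weight_consistent = list(xy = 1 / (2 * params$gamma), phi = 1 / (2 * params$mu))
  )
  csr <- sm$csr
  f <- matrix(0, M, N)
  zero_rphi <- numeric(M * N)
  guard0 <- NULL
  log <- if (is.null(reference)) NULL else
    data.frame(iteration = integer(), rmse = numeric(), uqi = numeric(),
               residual = numeric())
  for (n in seq_len(params$n_outer)) {
    f_start <- f
    fv <- kaczmarz_sweep_csr(csr$row_ptr, csr$cols, csr$vals, pv,
                             as.numeric(f), csr$row_norm2)
    f <- positivity(matrix(fv, M, N))
    dn <- sqrt(l2sq(f_start - f))
    if (dn > 0) {
      dx <- grad_x(f); dy <- grad_y(f)
      bx <- matrix(0, M, N); by <- matrix(0, M, N)
      if (use_phi) {
        dphi <- transform$forward(f)
        bphi <- tc_zero(dphi)
      }
      for (k in seq_len(params$k_inner)) {
        tx <- grad_x_adj(dx - bx)
        ty <- grad_y_adj(dy - by)
        rphi <- if (use_phi) {
          as.numeric(transform$adjoint(tc_sub(dphi, bphi)))
        } else zero_rphi
        fv <- spbr_inner_sweep_csr(csr$row_ptr, csr$cols, csr$vals, pv,
                                   as.numeric(f), M, N, nd,
                                   as.numeric(tx), as.numeric(ty), rphi,
                                   params$lambda, params$gamma, mu_eff,
                                   params$step_a * dn)
        f <- positivity(matrix(fv, M, N))
        gxf <- grad_x(f); gyf <- grad_y(f)
        dx <- shrink(gxf + bx, thr$xy)
        dy <- shrink(gyf + by, thr$xy)
        bx <- bx + gxf - dx
        by <- by + gyf - dy
        if (use_phi) {
          phif <- transform$forward(f)
          dphi <- tc_shrink(tc_add(phif, bphi), thr$phi)
          bphi <- tc_add(bphi, tc_sub(phif, dphi))
        }
      }
    }
    res2 <- l2sq(sm$A %*% as.numeric(f) - pv)
    rr <- sqrt(res2 / length(pv))
    if (is.null(guard0)) {
      guard0 <- rr
    } else if (guard0 > 0 && rr > 10 * guard0) {
      stop(sprintf(
        "reconstruction diverged at outer iteration %d: data RMSE %.3g exceeds 10x its starting value %.3g",
        n, rr, guard0
      ))
    }
    if (!is.null(reference)) {
      log[nrow(log) + 1, ] <- c(n, rmse(reference, f), uqi(reference, f),
                                sqrt(res2))
    }
    if (!is.null(params$sigma) && res2 < params$sigma^2) break
  }
  attr(f, "metrics") <- log
  f
}

#' ART-TV reconstruction
#'
#' The two-loop scheme of [spbr_nact_reconstruct()] with the contourlet
#' channel removed: outer ART sweeps with positivity, inner Split-Bregman
#' descent regularized by total variation only. Serves as the baseline that
#' isolates the contribution of the contourlet channel.
#'
#' @inheritParams art_reconstruct
#' @return Reconstructed nonnegative image matrix.
#' @export
art_tv_reconstruct <- function(A, p, params = recon_params(), reference = NULL) {
  two_loop_recon(A, p, params, transform = NULL, reference = reference)
}

#' Split-Bregman reconstruction with TV and contourlet regularization
#'
#' The full two-loop algorithm. Each outer iteration `n` runs one Kaczmarz
#' sweep over all view blocks followed by the positivity constraint; the
#' norm `d(n)` of the change produced by that pass scales the inner descent
#' steps. Each of the `k_inner` inner iterations performs one normalized
#' steepest-descent pass over the view blocks on the quadratic Split-Bregman
#' subproblem (data term plus TV and contourlet quadratic couplings),
#' applies positivity, then updates the auxiliary variables by shrinkage and
#' the Bregman variables by residual accumulation. Iteration stops after
#' `n_outer` outer loops or once `||A f - p||^2 < sigma^2`.
#'
#' @inheritParams art_reconstruct
#' @param transform a `ct_transform`; defaults to the 3-level NACT of
#'   [nact_spec()] on the image grid.
#' @return Reconstructed nonnegative image matrix. If `reference` is given,
#'   per-outer-iteration metrics are attached as attribute `metrics`.
#' @export
spbr_nact_reconstruct <- function(A, p, params = recon_params(),
                                  transform = NULL, reference = NULL) {
  sm <- as_sysmat(A)
  if (is.null(transform)) {
    transform <- nact_transform(nact_spec(sm$image_shape))
  }
  two_loop_recon(sm, p, params, transform = transform, reference = reference)
}
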
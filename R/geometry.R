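#' Interleaved view-angle schedule
#'
#' Produces the two-pass interleaved angle list used for sparse-view scans:
#' the first half covers `1 + 360*(i-1)/n_views` degrees for
#' `i = 1..n_views/2`, the second half covers `182 + 360*j/n_views` for
#' `j = 1..n_views/2`. The two passes interleave so that opposite half-turns
#' are sampled on staggered grids.
#'
#' @param n_views even number of views (>= 2).
#' @return Numeric vector of `n_views` angles in degrees.
#' @examples
#' make_angles(60)[c(1, 30, 31, 60)]
#' @export
make_angles <- function(n_views) {
  if (!is.numeric(n_views) || length(n_views) != 1 || is.na(n_views) ||
      n_views < 2 || n_views %% 2 != 0) {
    stop_invalid("'n_views' must be a single even number >= 2")
  }
  n_views <- as.integer(n_views)
  half <- n_views / 2
  first <- 1 + 360 * (seq_len(half) - 1) / n_views
  second <- 182 + 360 * seq_len(half) / n_views
  c(first, second)
}

#' Parallel pencil-beam projection geometry
#'
#' One ray per detector bin, detectors spaced `spacing` pixels apart and
#' centred on the image. When `angles` is omitted they are generated with
#' [make_angles()].
#'
#' @param n_views number of views (ignored when `angles` is given).
#' @param n_detectors number of detector bins per view.
#' @param angles optional explicit angle list in degrees.
#' @param spacing detector spacing in pixel units.
#' @return An object of class `projection_geometry`.
#' @export
projection_geometry <- function(n_views = NULL, n_detectors, angles = NULL,
                                spacing = 1) {
  if (is.null(angles)) {
    if (is.null(n_views)) stop_invalid("give either 'n_views' or 'angles'")
    angles <- make_angles(n_views)
  }
  angles <- as.numeric(angles)
  if (length(angles) < 1 || anyNA(angles)) {
    stop_invalid("angle list must be nonempty and finite")
  }
  if (!is.numeric(n_detectors) || n_detectors < 1) {
    stop_invalid("'n_detectors' must be a positive count")
  }
  structure(
    list(
      n_views = length(angles),
      angles = angles,
      n_detectors = as.integer(n_detectors),
      spacing = as.numeric(spacing)
    ),
    class = "projection_geometry"
  )
}

#' @exportS3Method print projection_geometry
print.projection_geometry <- function(x, ...) {
  cat(sprintf(
    "parallel pencil-beam geometry: %d views x %d detectors (spacing %g px)\n",
    x$n_views, x$n_detectors, x$spacing
  ))
  invisible(x)
}

#' Build the sparse ray/pixel system matrix
#'
#' Traces one parallel ray per (view, detector) pair through the pixel grid
#' with Siddon's algorithm and records the exact intersection length of the
#' ray with every pixel it crosses. Rows are ordered view-by-view, detectors
#' fastest, so the row block of view `m` is directly addressable.
#'
#' @param image_shape integer vector `c(n_rows, n_cols)` of the image grid.
#' @param geometry a [projection_geometry()].
#' @return An object of class `system_matrix` with elements:
#'   \describe{
#'     \item{A}{`dgCMatrix` of size `(n_views*n_detectors) x (n_rows*n_cols)`;
#'       columns follow R's column-major image layout.}
#'     \item{csr}{row-compressed copy (`row_ptr`, `cols`, `vals`, 0-based)
#'       used by the compiled iteration kernels.}
#'     \item{geometry, image_shape}{the inputs.}
#'   }
#' @export
build_system_matrix <- function(image_shape, geometry) {
  if (!inherits(geometry, "projection_geometry")) {
    stop_invalid("'geometry' must be a projection_geometry")
  }
  if (length(image_shape) != 2 || any(image_shape < 1)) {
    stop_invalid("'image_shape' must be c(n_rows, n_cols)")
  }
  M <- as.integer(image_shape[1])
  N <- as.integer(image_shape[2])
  csr <- siddon_trace(
    M, N, geometry$angles, geometry$n_detectors, geometry$spacing
  )
  n_rays <- geometry$n_views * geometry$n_detectors
  A <- Matrix::sparseMatrix(
    i = rep.int(seq_len(n_rays), diff(csr$row_ptr)),
    j = csr$cols + 1L,
    x = csr$vals,
    dims = c(n_rays, M * N)
  )
  csr$row_norm2 <- Matrix::rowSums(A^2)
  structure(
    list(A = A, csr = csr, geometry = geometry, image_shape = c(M, N)),
    class = "system_matrix"
  )
}

#' @exportS3Method print system_matrix
print.system_matrix <- function(x, ...) {
  cat(sprintf(
    "system matrix: %d rays x %d pixels, %d nonzeros\n",
    nrow(x$A), ncol(x$A), length(x$csr$vals)
  ))
  invisible(x)
}

#' Forward projection
#'
#' Applies the system matrix to an image, producing the sinogram
#' `p = A f` arranged as a `(view, detector)` matrix.
#'
#' @param A a [build_system_matrix()] result.
#' @param f image matrix matching `A$image_shape`.
#' @return A numeric matrix of class `sinogram` with the geometry attached
#'   as attribute `geometry`.
#' @export
project <- function(A, f) {
  if (!inherits(A, "system_matrix")) stop_invalid("'A' must be a system_matrix")
  if (!is.matrix(f) || !all(dim(f) == A$image_shape)) {
    stop_invalid("image shape does not match the system matrix")
  }
  p <- as.numeric(A$A %*% as.numeric(f))
  g <- A$geometry
  p <- matrix(p, nrow = g$n_views, ncol = g$n_detectors, byrow = TRUE)
  structure(p, class = c("sinogram", "matrix"), geometry = g)
}

## flatten a (view, detector) sinogram into ray order (detector fastest),
## matching the system-matrix row order
sino_to_rays <- function(p) as.numeric(t(unclass(p)))

rays_to_sino <- function(x, geometry) {
  structure(
    matrix(x, nrow = geometry$n_views, ncol = geometry$n_detectors,
           byrow = TRUE),
    class = c("sinogram", "matrix"), geometry = geometry
  )
}

#' Add white Gaussian noise at a prescribed SNR
#'
#' Adds zero-mean white Gaussian noise to projection data. With
#' `reference = "measured"` (the default) the noise variance is set so that
#' `10*log10(mean(p^2) / noise variance) = snr_db`, i.e. SNR is measured
#' against the mean square of the noise-free data (DC included). With
#' `reference = "unit"` the signal power is taken as 1 regardless of the
#' data, so the noise variance is simply `10^(-snr_db/10)`; this is the
#' convention used by the reproduced noisy head-phantom experiments (see the
#' methods vignette for why). `snr_db = Inf` returns the input unchanged.
#'
#' @param p sinogram (or any numeric array) of noise-free projections.
#' @param snr_db target signal-to-noise ratio in decibels.
#' @param seed integer seed; the global RNG state is left untouched.
#' @param reference `"measured"` or `"unit"` signal-power reference.
#' @return Object of the same shape with noise added.
#' @export
add_noise <- function(p, snr_db, seed = 0,
                      reference = c("measured", "unit")) {
  reference <- match.arg(reference)
  if (length(p) == 0) stop_invalid("'p' must be nonempty")
  if (length(snr_db) != 1 || is.na(snr_db)) {
    stop_invalid("'snr_db' must be a single finite number (or Inf)")
  }
  if (is.infinite(snr_db) && snr_db > 0) return(p)
  if (!is.finite(snr_db)) stop_invalid("'snr_db' must be finite or +Inf")
  sig <- if (reference == "measured") mean(as.numeric(p)^2) else 1
  sigma2 <- sig * 10^(-snr_db / 10)
  e <- with_seed(seed, rnorm(length(p), mean = 0, sd = sqrt(sigma2)))
  out <- p
  out[] <- as.numeric(p) + e
  out
}
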
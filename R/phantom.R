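#' Ellipse parameters of the modified Shepp-Logan head phantom
#'
#' Each row describes one ellipse: additive intensity `A`, semi-axes `a`
#' (horizontal) and `b` (vertical), centre `(x0, y0)` in the unit square
#' `[-1, 1]^2`, and rotation `phi` in degrees (counterclockwise). The
#' intensities are the contrast-enhanced ("modified") values, chosen so the
#' composite image lies in `[0, 1]`.
#'
#' @return A data frame with columns `A`, `a`, `b`, `x0`, `y0`, `phi`.
#' @export
shepp_logan_ellipses <- function() {
  data.frame(
    A   = c(1, -0.8, -0.2, -0.2, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1),
    a   = c(0.69, 0.6624, 0.11, 0.16, 0.21, 0.046, 0.046, 0.046, 0.023, 0.023),
    b   = c(0.92, 0.874, 0.31, 0.41, 0.25, 0.046, 0.046, 0.023, 0.023, 0.046),
    x0  = c(0, 0, 0.22, -0.22, 0, 0, 0, -0.08, 0, 0.06),
    y0  = c(0, -0.0184, 0, 0, 0.35, 0.1, -0.1, -0.605, -0.606, -0.605),
    phi = c(0, 0, -18, 18, 0, 0, 0, 0, 0, 0)
  )
}

#' Rasterize the head phantom
#'
#' Generates the standard modified (contrast-enhanced) Shepp-Logan head
#' phantom at `size` x `size` pixels. Each ellipse contributes its intensity
#' to every pixel whose centre lies inside it; the composite intensities lie
#' in `[0, 1]`. Pixel `(1, 1)` is the top-left corner; the ellipse set is
#' inscribed in the unit square mapped onto the full image.
#'
#' @param size edge length in pixels (>= 16).
#' @return A `size` x `size` numeric matrix.
#' @examples
#' f <- make_phantom(64)
#' range(f)
#' @export
make_phantom <- function(size) {
  if (!is.numeric(size) || length(size) != 1 || is.na(size) || size < 16) {
    stop_invalid("'size' must be a single number >= 16")
  }
  size <- as.integer(size)
  ## pixel-centre coordinates in [-1, 1]; row 1 is the top of the image
  xs <- (seq_len(size) - 0.5) / size * 2 - 1
  ys <- 1 - (seq_len(size) - 0.5) / size * 2
  x <- matrix(xs, size, size, byrow = TRUE)
  y <- matrix(ys, size, size)
  f <- matrix(0, size, size)
  ell <- shepp_logan_ellipses()
  for (e in seq_len(nrow(ell))) {
    th <- ell$phi[e] * pi / 180
    dx <- x - ell$x0[e]
    dy <- y - ell$y0[e]
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    inside <- (u / ell$a[e])^2 + (v / ell$b[e])^2 <= 1
    f <- f + ell$A[e] * inside
  }
  ## overlapping ellipse intensities cancel to 0/0.2/...; clamp the
  ## floating-point dust so the phantom is exactly nonnegative
  f[abs(f) < 1e-12] <- 0
  f
}
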
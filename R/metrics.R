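#' Root-mean-square error between two images
#'
#' `sqrt(mean((f - fR)^2))` over all pixels.
#'
#' @param f reference image matrix.
#' @param fR reconstructed image matrix of the same shape.
#' @return Nonnegative scalar.
#' @export
rmse <- function(f, fR) {
  if (!all(dim(f) == dim(fR))) stop_invalid("image shapes differ")
  sqrt(mean((f - fR)^2))
}

#' Universal quality index (global, single window)
#'
#' The Wang-Bovik index evaluated once over the whole image:
#' `4 * cov(f, fR) * mean(f) * mean(fR) /
#'  ((var(f) + var(fR)) * (mean(f)^2 + mean(fR)^2))`,
#' with sample (n-1) variance normalization. It combines loss of
#' correlation, luminance distortion and contrast distortion and lies in
#' `[-1, 1]`, reaching 1 only when the images are identical.
#'
#' If the denominator vanishes (both images constant) the index is defined
#' as 1 for equal constants and 0 otherwise, with a warning.
#'
#' @param f reference image matrix.
#' @param fR reconstructed image matrix of the same shape.
#' @return Scalar in `[-1, 1]`.
#' @export
uqi <- function(f, fR) {
  if (!all(dim(f) == dim(fR))) stop_invalid("image shapes differ")
  n <- length(f)
  mf <- mean(f)
  mr <- mean(fR)
  vf <- sum((f - mf)^2) / (n - 1)
  vr <- sum((fR - mr)^2) / (n - 1)
  cv <- sum((f - mf) * (fR - mr)) / (n - 1)
  den <- (vf + vr) * (mf^2 + mr^2)
  if (den == 0) {
    warning("UQI denominator is zero (constant images); using the degenerate-value rule")
    return(if (isTRUE(all.equal(as.numeric(f), as.numeric(fR)))) 1 else 0)
  }
  4 * cv * mf * mr / den
}

#' Evaluate both quality metrics at once
#'
#' @param f reference image matrix.
#' @param fR reconstructed image matrix.
#' @return A list with elements `rmse` and `uqi`.
#' @export
metric_report <- function(f, fR) {
  list(rmse = rmse(f, fR), uqi = uqi(f, fR))
}
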
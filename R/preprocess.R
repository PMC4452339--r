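#' Gray-threshold soft-tissue extraction
#'
#' Vessels, airways and nodules are brighter than lung parenchyma, so a
#' single gray threshold separates soft tissue from background. The
#' default threshold of 130 is interpreted on the 8-bit intensity scale;
#' images with values above 255 are rescaled to 8-bit range before
#' thresholding. The comparison is `>=`: boundary pixels are assigned to
#' the foreground.
#'
#' @param image [image2d()] or numeric matrix.
#' @param threshold gray threshold (default 130 on the 8-bit scale).
#' @return [binary_mask()] of the same shape.
#' @export
extract_soft_tissue <- function(image, threshold = 130) {
  m <- as_plain_matrix(image)
  hi <- max(255, max(m))
  if (hi > 255) m <- m * (255 / hi)
  if (threshold < 0 || threshold > 255) {
    stop("extract_soft_tissue: threshold outside the representable range [0, 255]",
         call. = FALSE)
  }
  binary_mask(m >= threshold, spacing_mm(image))
}

#' Gaussian smoothing
#'
#' Convolution with a normalized, separable 2D Gaussian kernel, truncated
#' at 4 sigma, reflective boundary handling. `sigma = 0` returns the input
#' unchanged.
#'
#' @param image [image2d()] or numeric matrix.
#' @param sigma kernel scale in pixels (`>= 0`).
#' @return smoothed [image2d()].
#' @export
gaussian_smooth <- function(image, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0) {
    stop("gaussian_smooth: `sigma` must be a single non-negative number",
         call. = FALSE)
  }
  m <- as_plain_matrix(image)
  if (sigma == 0) return(image2d(m, spacing_mm(image)))
  k <- gauss_kernel(sigma, 0L)
  image2d(conv_sep(m, k, k), spacing_mm(image))
}
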
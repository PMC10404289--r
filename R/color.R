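#' Convert 8-bit sRGB pixels to CIE Lab
#'
#' Pixels are interpreted as sRGB under the D65 standard illuminant, the
#' convention used throughout the package (stain normalization, tissue
#' masking, texture features).
#'
#' @param px numeric matrix with three columns (R, G, B) on the 0..255 scale,
#'   or an H x W x 3 array.
#' @return an n x 3 matrix of L (0..100), a, b values.
#' @export
rgb_to_lab <- function(px) {
  if (length(dim(px)) == 3L) px <- pixel_matrix(px)
  grDevices::convertColor(px / 255, from = "sRGB", to = "Lab", scale.in = 1)
}

#' Convert CIE Lab values back to 8-bit sRGB
#'
#' Out-of-gamut values are clipped to [0, 255] after the inverse transform.
#'
#' @param lab an n x 3 matrix of L, a, b values.
#' @return an n x 3 matrix of R, G, B values on the 0..255 scale.
#' @export
lab_to_rgb <- function(lab) {
  out <- grDevices::convertColor(lab, from = "Lab", to = "sRGB", scale.out = 1)
  clamp(out * 255, 0, 255)
}

# Scalar luminance in [0,1] (Rec. 601 weights) for masking heuristics.
luminance01 <- function(px) {
  (0.299 * px[, 1] + 0.587 * px[, 2] + 0.114 * px[, 3]) / 255
}

# HSV-style saturation in [0,1].
saturation01 <- function(px) {
  mx <- pmax(px[, 1], px[, 2], px[, 3])
  mn <- pmin(px[, 1], px[, 2], px[, 3])
  s <- (mx - mn) / mx
  s[mx == 0] <- 0
  s
}
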
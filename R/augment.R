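#' Bilinear affine resampling of an image
#'
#' The shared primitive behind the augmentation ops: output pixel at centred
#' coordinate `q` (pixels, origin at the image centre) takes the bilinear
#' sample of the input at `A %*% q + b`. Out-of-range samples are zero
#' (`pad = "zero"`) or clamped to the border (`pad = "edge"`).
#'
#' @param img Numeric matrix (first index x, second y).
#' @param A 2x2 matrix mapping output to input pixel coordinates.
#' @param b Length-2 offset, input pixels.
#' @param out_dim Output size (length 1 or 2), pixels.
#' @param pad `"zero"` or `"edge"`.
#' @return A numeric matrix of size `out_dim`.
#' @export
resample_affine <- function(img, A = diag(2), b = c(0, 0),
                            out_dim = dim(img), pad = c("zero", "edge")) {
  pad <- match.arg(pad)
  out_dim <- rep_len(as.integer(out_dim), 2L)
  .resample_affine_cpp(as.matrix(img), A, as.double(b),
                       out_dim[1], out_dim[2], match(pad, c("zero", "edge")) - 1L)
}

#' In-plane rotation augmentation
#'
#' Emulates a detector rotation by `gamma` degrees as an image rotation
#' followed by a centre crop to the inscribed region (factor `1/sqrt(2)`),
#' which removes border interpolation artefacts for every rotation angle.
#' The physical detector rotation `gamma` becomes the sample's in-plane
#' label.
#'
#' @param img Numeric square matrix.
#' @param gamma Rotation, degrees.
#' @param crop Crop factor applied after rotation (default `1/sqrt(2)`).
#' @return The rotated, cropped matrix of side `round(n * crop)`.
#' @export
augment_inplane <- function(img, gamma, crop = 1 / sqrt(2)) {
  stopifnot(nrow(img) == ncol(img))
  g <- deg2rad(gamma)
  A <- matrix(c(cos(g), sin(g), -sin(g), cos(g)), 2, 2) # column-major: Rz(g)
  out <- floor(nrow(img) * crop) # floor keeps every sample inside the disc
  resample_affine(img, A, c(0, 0), out, pad = "zero")
}

#' Detector-translation augmentation
#'
#' Emulates a detector offset `t = (tx, ty)` mm by cropping a window whose
#' centre is shifted by `t` converted to pixels at the detector pixel pitch.
#' If the shifted window leaves the image, border pixels are repeated and a
#' warning is raised.
#'
#' @param img Numeric matrix.
#' @param t Length-2 translation, mm (componentwise within the sampling
#'   law's range).
#' @param pitch_mm Detector pixel pitch of `img`, mm per pixel.
#' @param out_dim Output window size, pixels (default: input size).
#' @return The cropped matrix; the emulated detector offset `t` becomes the
#'   sample's translation label.
#' @export
augment_translation <- function(img, t, pitch_mm, out_dim = dim(img)) {
  t_px <- as.double(t) / pitch_mm
  out_dim <- rep_len(as.integer(out_dim), 2L)
  half <- (out_dim - 1) / 2
  ctr_in <- (dim(img) - 1) / 2
  if (any(abs(t_px) + half > ctr_in + 0.5)) { # more than half a pixel outside
    warning("translation crop exceeds image bounds; padding with edge values")
  }
  resample_affine(img, diag(2), t_px, out_dim, pad = "edge")
}

#' Scale augmentation
#'
#' Rescales the image content by factor `s` about the centre (values
#' `s < 1` shrink the content, emulating a shorter source-to-anatomy
#' distance or smaller bone; larger-than-1 factors are excluded because
#' zooming in emulates a clinically unused, higher-dose geometry). Border
#' samples repeat edge values.
#'
#' @param img Numeric matrix.
#' @param s Scale factor in (0, 1].
#' @return Matrix of the same size.
#' @export
augment_scale <- function(img, s) {
  stopifnot(s > 0, s <= 1)
  resample_affine(img, diag(2) / s, c(0, 0), dim(img), pad = "edge")
}

#' Contrast augmentation
#'
#' Rescales pixel deviations about the image mean: `p <- (p - mu) * c + mu`,
#' where `mu` is the image-wide mean. The mean is preserved exactly and
#' `c = 1` is the identity.
#'
#' @param img Numeric matrix.
#' @param c_factor Contrast factor.
#' @return Matrix of the same size.
#' @export
augment_contrast <- function(img, c_factor) {
  mu <- mean(img)
  (img - mu) * c_factor + mu
}

#' Resize an image to a target resolution
#'
#' Bilinear rescale covering the same field of view.
#'
#' @param img Numeric matrix.
#' @param out_dim Target size, pixels (length 1 or 2).
#' @return Resized matrix.
#' @export
resize_image <- function(img, out_dim) {
  out_dim <- rep_len(as.integer(out_dim), 2L)
  A <- diag((dim(img) - 1) / pmax(out_dim - 1, 1))
  resample_affine(img, A, c(0, 0), out_dim, pad = "edge")
}

#' Network input preprocessing
#'
#' Converts an intensity-domain image to the network input: a negative log
#' transform (back to the line-integral domain, shrinking the dynamic
#' range) followed by per-image min-max normalization to \[0, 1\]. A
#' constant image maps to all zeros; non-positive intensities are clamped
#' to the smallest positive pixel with a warning.
#'
#' @param img Numeric matrix of strictly positive intensities.
#' @return Matrix with values in \[0, 1\]; min 0 and max 1 unless the input
#'   was constant.
#' @export
preprocess <- function(img) {
  li <- neg_log(img)
  rng <- range(li)
  if (rng[2] - rng[1] < .Machine$double.eps * max(abs(rng), 1)) {
    return(array(0, dim(img)))
  }
  (li - rng[1]) / (rng[2] - rng[1])
}

#' Full augmentation chain from a rendered projection to a network input
#'
#' Applies the in-plane rotation (`gamma`), the translation crop (`t_mm`,
#' converted at the detector pixel pitch), scale and contrast augmentation
#' and the preprocessing in one pass. The geometric part is a single fused
#' bilinear resample (the rotation and the shifted crop window compose into
#' one affine map), so the op is cheap enough to run per batch during
#' training — augmentation can then be drawn fresh for every batch, exactly
#' as data are augmented online during training at full scale.
#'
#' @param img Intensity-domain projection matrix (square).
#' @param gamma In-plane rotation, degrees.
#' @param t_mm Length-2 detector translation, mm.
#' @param s Scale factor in (0, 1].
#' @param c_factor Contrast factor.
#' @param pitch_mm Pixel pitch of `img`, mm.
#' @param final_size Output side, pixels.
#' @return A `final_size` matrix in \[0, 1\].
#' @export
augment_projection <- function(img, gamma, t_mm, s, c_factor, pitch_mm,
                               final_size) {
  g <- deg2rad(gamma)
  A <- matrix(c(cos(g), sin(g), -sin(g), cos(g)), 2, 2)
  b <- A %*% (as.double(t_mm) / pitch_mm)
  out <- resample_affine(img, A, b, final_size, pad = "edge")
  out <- preprocess(out)
  out <- augment_contrast(augment_scale(out, s), c_factor)
  pmin(1, pmax(0, out))
}

#' Horizontally flip an image (laterality mirroring)
#'
#' @param img Numeric matrix (first index x).
#' @return The matrix flipped along x.
#' @export
flip_image <- function(img) img[nrow(img):1, , drop = FALSE]
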
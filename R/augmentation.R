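# Training-data augmentation for 8-bit grayscale ultrasound frames: bounded
# random rotation plus a linear brightness/contrast transform with an 8-bit
# saturating cast. Defaults reproduce a 21-fold expansion of the input set.

#' 8-bit saturating cast
#'
#' Rounds half away from zero, then clamps to the 8-bit intensity range
#' `[0, 255]`. This is the cast applied after the gain/offset transform
#' `dst = src * alpha + beta`.
#'
#' @param value Numeric vector/matrix.
#' @return Integer values in `[0, 255]`, shape preserved.
#' @export
#' @examples
#' saturate_cast(200 * 1.3 + 30)  # 255
saturate_cast <- function(value) {
  out <- pmin.int(pmax.int(sign(value) * floor(abs(value) + 0.5), 0), 255)
  storage.mode(out) <- "integer"
  dim(out) <- dim(value)
  out
}

as_gray_image <- function(image) {
  if (!is.matrix(image))
    caliper_abort("invalid_image", "image must be a matrix")
  v <- as.vector(image)
  if (anyNA(v) || any(v != as.integer(v)) || any(v < 0) || any(v > 255))
    caliper_abort("invalid_image",
                  "image must be 8-bit grayscale: integer values in [0, 255]")
  storage.mode(image) <- "integer"
  image
}

#' Brightness/contrast adjustment
#'
#' Element-wise `dst(I) = saturate_cast(src(I) * alpha + beta)`: `alpha` is
#' the contrast gain (study range 0.7-1.3), `beta` the brightness offset in
#' intensity levels (study range -30 to 30). `alpha = 1`, `beta = 0` is the
#' exact identity.
#'
#' @param image 8-bit grayscale image (integer matrix, values 0-255).
#' @param alpha Gain.
#' @param beta Offset.
#' @return Transformed image, same shape, integer 0-255.
#' @export
adjust_brightness_contrast <- function(image, alpha, beta) {
  image <- as_gray_image(image)
  out <- saturate_cast(image * alpha + beta)
  dim(out) <- dim(image)
  out
}

#' Rotate an image or label mask about its center
#'
#' Canvas size is preserved; pixels rotated in from outside the canvas are
#' filled with 0 (background). Images are interpolated bilinearly and re-cast
#' to 8 bits; masks use nearest-neighbor so the class alphabet is preserved
#' exactly. Angles beyond the study's +/- 15 degree augmentation range are
#' allowed with a warning.
#'
#' @param x Integer matrix: grayscale image or label mask.
#' @param angle Rotation angle in degrees.
#' @param is_mask `TRUE` for label masks (nearest-neighbor).
#' @return Rotated integer matrix, same dimensions.
#' @export
rotate_frame <- function(x, angle, is_mask = FALSE) {
  x <- if (is_mask) as_label_mask(x) else as_gray_image(x)
  if (abs(angle) > 15)
    caliper_warn("angle_out_of_range",
                 sprintf("angle %.1f outside the +/- 15 degree augmentation range", angle))
  if (angle %% 360 == 0) return(x)
  y <- EBImage::rotate(x, angle,
                       filter = if (is_mask) "none" else "bilinear",
                       output.dim = dim(x), bg.col = 0)
  y <- EBImage::imageData(y)
  if (is_mask) {
    y <- matrix(as.integer(round(y)), nrow(x), ncol(x))
  } else {
    y <- saturate_cast(y)
    dim(y) <- dim(x)
  }
  y
}

#' Draw augmentation parameters
#'
#' One row per variant: rotation angle uniform on +/- 15 degrees, gain
#' `alpha` uniform on `[0.7, 1.3]`, offset `beta` uniform on `[-30, 30]`.
#' Reproducible given `seed`.
#'
#' @param n Number of parameter draws.
#' @param seed Optional integer seed.
#' @return Data frame with columns `angle`, `alpha`, `beta`.
#' @export
draw_augmentation_params <- function(n, seed = NULL) {
  draw <- function() data.frame(angle = stats::runif(n, -15, 15),
                                alpha = stats::runif(n, 0.7, 1.3),
                                beta = stats::runif(n, -30, 30))
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Augment an image set
#'
#' Returns the originals plus `n_variants` independently drawn
#' (angle, alpha, beta) variants per image, so the output holds
#' `(1 + n_variants)` times the input count — 21-fold with the default 20
#' variants. When paired masks are supplied, each variant applies the
#' identical angle to image and mask (masks get no intensity transform).
#'
#' @param images List of 8-bit grayscale images.
#' @param masks Optional list of label masks paired with `images`.
#' @param n_variants Variants per image, default 20.
#' @param seed Optional integer seed; the same seed reproduces the output
#'   bit-exactly.
#' @return List with `images` (length `|images| * (1 + n_variants)`), `masks`
#'   (same length, or `NULL`) and `params` (data frame `image`, `variant`,
#'   `angle`, `alpha`, `beta`; variant 0 is the untouched original).
#' @export
#' @examples
#' imgs <- replicate(2, matrix(100L, 8, 8), simplify = FALSE)
#' length(augment_set(imgs, n_variants = 20, seed = 1)$images)  # 42
augment_set <- function(images, masks = NULL, n_variants = 20, seed = NULL) {
  stopifnot(is.list(images), n_variants >= 0)
  if (!is.null(masks)) stopifnot(is.list(masks), length(masks) == length(images))
  n_img <- length(images)
  params <- draw_augmentation_params(n_img * n_variants, seed = seed)
  params <- cbind(data.frame(image = rep(seq_len(n_img), each = n_variants),
                             variant = rep(seq_len(max(n_variants, 0L)),
                                           times = n_img)[seq_len(n_img * n_variants)]),
                  params)
  out_img <- vector("list", n_img * (1 + n_variants))
  out_msk <- if (is.null(masks)) NULL else vector("list", n_img * (1 + n_variants))
  pos <- 0L
  for (i in seq_len(n_img)) {
    pos <- pos + 1L
    out_img[[pos]] <- as_gray_image(images[[i]])
    if (!is.null(masks)) out_msk[[pos]] <- as_label_mask(masks[[i]])
    prm <- params[params$image == i, , drop = FALSE]
    for (v in seq_len(n_variants)) {
      pos <- pos + 1L
      img <- adjust_brightness_contrast(images[[i]], prm$alpha[v], prm$beta[v])
      out_img[[pos]] <- rotate_frame(img, prm$angle[v])
      if (!is.null(masks))
        out_msk[[pos]] <- rotate_frame(masks[[i]], prm$angle[v], is_mask = TRUE)
    }
  }
  originals <- data.frame(image = seq_len(n_img), variant = 0L,
                          angle = 0, alpha = 1, beta = 0)
  params <- rbind(originals, params)
  params <- params[order(params$image, params$variant), ]
  rownames(params) <- NULL
  list(images = out_img, masks = out_msk, params = params)
}
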
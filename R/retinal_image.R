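#' Retinal image container
#'
#' A light wrapper around a numeric array holding one retinal raster together
#' with the metadata the pipeline tracks: modality, physical scale and the
#' coordinate frame the pixels live in. Coordinates throughout the package are
#' 0-based `(row, col)` with pixel centres at integers; `frame` distinguishes
#' rasters expressed in the fundus photograph's frame from native (unaligned)
#' OCT-A rasters.
#'
#' @param pixels numeric matrix (`H x W`) or array (`H x W x C`). Fundus images
#'   carry 3 channels; all other modalities a single channel.
#' @param modality one of `"fundus"`, `"octa"`, `"synthetic_octa"`, `"mask"`.
#' @param px_per_mm pixels per millimetre (positive).
#' @param frame `"fundus_frame"` or `"octa_native"`.
#' @return An object of class `retinal_image`.
#' @export
retinal_image <- function(pixels, modality = c("fundus", "octa",
                                               "synthetic_octa", "mask"),
                          px_per_mm = NA_real_, frame = "fundus_frame") {
  modality <- match.arg(modality)
  if (is.matrix(pixels)) dim(pixels) <- c(dim(pixels), 1L)
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L)
  nc <- dim(pixels)[3L]
  if (modality == "fundus" && nc != 3L)
    stop("fundus images must have 3 channels, got ", nc)
  if (modality != "fundus" && nc != 1L)
    stop(modality, " images must have 1 channel, got ", nc)
  if (!is.na(px_per_mm) && px_per_mm <= 0) stop("px_per_mm must be positive")
  if (!frame %in% c("fundus_frame", "octa_native"))
    stop("unknown frame: ", frame)
  structure(list(pixels = pixels, modality = modality,
                 px_per_mm = px_per_mm, frame = frame),
            class = "retinal_image")
}

#' @export
print.retinal_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<retinal_image> %s %dx%dx%d, %s, %s px/mm\n", x$modality,
              d[1], d[2], d[3], x$frame,
              if (is.na(x$px_per_mm)) "?" else format(x$px_per_mm)))
  invisible(x)
}

#' @export
dim.retinal_image <- function(x) dim(x$pixels)

img_channels <- function(img) dim(img$pixels)[3L]

as_retinal_pixels <- function(x) {
  if (inherits(x, "retinal_image")) x$pixels else x
}

#' Similarity (rigid + scale) transform
#'
#' Parameterises the alignment between OCT-A and fundus frames: a rotation
#' about the geometric image centre (counter-clockwise positive, in the
#' displayed image), followed by isotropic scaling, followed by a translation
#' in pixels. Acting on `(row, col)` offsets from the centre the rotation
#' matrix is `[[cos, -sin], [sin, cos]]` (degrees converted internally).
#'
#' @param scale positive isotropic scale factor.
#' @param rotation_deg rotation angle in degrees, counter-clockwise positive.
#' @param tx,ty translation in pixels along columns (`tx`) and rows (`ty`).
#' @return An object of class `similarity_transform`.
#' @export
similarity_transform <- function(scale = 1, rotation_deg = 0, tx = 0, ty = 0) {
  if (scale <= 0) stop("scale must be positive")
  structure(list(scale = scale, rotation_deg = rotation_deg,
                 tx = tx, ty = ty), class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("<similarity_transform> scale=%.4g rot=%.4g deg t=(%.4g, %.4g) px\n",
              x$scale, x$rotation_deg, x$tx, x$ty))
  invisible(x)
}

is_identity_transform <- function(t, tol = 1e-12) {
  abs(t$scale - 1) < tol && abs(t$rotation_deg) < tol &&
    abs(t$tx) < tol && abs(t$ty) < tol
}

# 2x2 rotation acting on (row, col) offsets; positive angle moves a point to
# the right of centre upward (smaller row) in the displayed image.
rotation_matrix <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

#' Invert a similarity transform
#'
#' @param t a [similarity_transform()].
#' @return The analytic inverse, again a `similarity_transform`.
#' @export
invert_transform <- function(t) {
  # p = s R q + d  =>  q = (1/s) R^-1 (p - d)
  R <- rotation_matrix(-t$rotation_deg)
  d <- c(t$ty, t$tx)                      # (row, col)
  di <- -(R %*% d) / t$scale
  similarity_transform(scale = 1 / t$scale, rotation_deg = -t$rotation_deg,
                       tx = di[2], ty = di[1])
}

#' Compose two similarity transforms
#'
#' `compose_transforms(t2, t1)` is the transform applying `t1` first, then
#' `t2` (both about the same centre).
#'
#' @param t2,t1 [similarity_transform()] objects.
#' @return The composed `similarity_transform`.
#' @export
compose_transforms <- function(t2, t1) {
  # p = s2 R2 (s1 R1 q + d1) + d2
  R2 <- rotation_matrix(t2$rotation_deg)
  d1 <- c(t1$ty, t1$tx)
  d <- t2$scale * (R2 %*% d1) + c(t2$ty, t2$tx)
  similarity_transform(scale = t2$scale * t1$scale,
                       rotation_deg = t2$rotation_deg + t1$rotation_deg,
                       tx = d[2], ty = d[1])
}

# Map (row, col) points through t about the given centre (0-based coords).
transform_points <- function(t, pts, center) {
  R <- rotation_matrix(t$rotation_deg)
  off <- sweep(pts, 2, center)
  out <- t$scale * (off %*% t(R))
  sweep(out, 2, center + c(t$ty, t$tx), "+")
}
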
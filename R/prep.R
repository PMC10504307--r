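#' Region-of-interest specification
#'
#' Describes one of the OCT-A fields of view as a square window in the fundus
#' frame: the 4.5 mm optic-disc field and the 6 mm macular field are delivered
#' at 400 px, the 3 mm macular field at 304 px.
#'
#' @param name `"disc"`, `"macula3"` or `"macula6"`.
#' @param center numeric length-2, `(row, col)` centre in the fundus frame
#'   (0-based pixel coordinates).
#' @param side_mm,output_px window side; defaults follow `name`.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(name = c("disc", "macula3", "macula6"), center,
                     side_mm = NULL, output_px = NULL) {
  name <- match.arg(name)
  defaults <- list(disc = c(4.5, 400), macula3 = c(3.0, 304),
                   macula6 = c(6.0, 400))[[name]]
  if (is.null(side_mm)) side_mm <- defaults[1]
  if (is.null(output_px)) output_px <- defaults[2]
  stopifnot(length(center) == 2, side_mm > 0, output_px >= 2)
  structure(list(name = name, center = as.numeric(center),
                 side_mm = side_mm, output_px = as.integer(output_px)),
            class = "roi_spec")
}

#' Background mask of a fundus photograph
#'
#' Retains pixels whose channel-mean intensity exceeds a fraction of the image
#' maximum, keeps the largest connected component and fills its holes, giving
#' a single connected retina region that excludes the dark surround of the
#' 45-degree field.
#'
#' @param fundus a fundus [retinal_image()] (8-bit intensities).
#' @param threshold_fraction fraction of the maximum channel-mean intensity
#'   below which pixels are treated as surround. Default 0.1.
#' @return Binary matrix (`H x W`, values 0/1) of class `background_mask`.
#' @export
compute_background_mask <- function(fundus, threshold_fraction = 0.1) {
  stopifnot(inherits(fundus, "retinal_image"), fundus$modality == "fundus")
  px <- fundus$pixels
  lum <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
  thr <- threshold_fraction * max(lum)
  fg <- lum > thr
  if (!any(fg)) stop("no foreground found")
  lab <- EBImage::bwlabel(fg * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- (lab == which.max(sizes)) * 1
  filled <- EBImage::fillHull(keep)
  m <- matrix(as.numeric(filled > 0), nrow(fg), ncol(fg))
  class(m) <- c("background_mask", class(m))
  m
}

#' Map 8-bit intensities to the [-1, 1] training range
#'
#' Applies `v / 127.5 - 1` per channel, so 0 maps to -1 and 255 to +1.
#'
#' @param img a [retinal_image()] with 8-bit intensities, or a bare array.
#' @return Same type as the input, with float pixels in `[-1, 1]`.
#' @export
normalize_intensity <- function(img) {
  if (inherits(img, "retinal_image")) {
    img$pixels <- img$pixels / 127.5 - 1
    return(img)
  }
  img / 127.5 - 1
}

#' Map normalized intensities back to 8-bit
#'
#' Inverse of [normalize_intensity()]: values are clipped to `[-1, 1]`,
#' affinely mapped to `[0, 255]` and rounded half away from zero (so the
#' midpoint 0 becomes 128).
#'
#' @param img normalized [retinal_image()] or array.
#' @return Same type as the input with integer-valued 8-bit pixels.
#' @export
denormalize_intensity <- function(img) {
  f <- function(v) {
    v <- pmax(pmin(v, 1), -1)
    floor((v + 1) * 127.5 + 0.5)      # half-away-from-zero on nonnegatives
  }
  if (inherits(img, "retinal_image")) {
    img$pixels <- f(img$pixels)
    return(img)
  }
  f(img)
}

# Inverse-mapping resampler shared by the transform and crop operations.
# src: H x W x C array; rows/cols: output-pixel source coordinates (0-based,
# fractional); bilinear or nearest. Out-of-field samples are 0 and flagged.
resample_grid <- function(src, rows, cols, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  H <- dim(src)[1]; W <- dim(src)[2]; C <- dim(src)[3]
  ho <- length(rows); wo <- length(cols)
  R <- matrix(rows, ho, wo)
  Cl <- matrix(cols, ho, wo, byrow = TRUE)
  out <- resample_warp(src, R, Cl, method)
  out
}

#' Resample an OCT-A image into the fundus frame
#'
#' Applies a stored [similarity_transform()] (rotation about the geometric
#' image centre, then isotropic scale, then translation) by inverse-mapping
#' resampling: bilinear interpolation for intensity images, nearest-neighbour
#' for masks. Pixels whose source falls outside the input field are set to 0
#' and reported in the `"valid"` attribute of the result's pixels.
#'
#' @param octa a [retinal_image()] in the `octa_native` frame (masks allowed).
#' @param t the [similarity_transform()] taking native coordinates to
#'   fundus-frame coordinates.
#' @param out_shape integer length-2 output size `(H, W)`; defaults to the
#'   input size.
#' @return A [retinal_image()] in `fundus_frame`.
#' @export
apply_similarity_transform <- function(octa, t, out_shape = NULL) {
  stopifnot(inherits(octa, "retinal_image"),
            inherits(t, "similarity_transform"))
  if (t$scale <= 0) stop("scale must be positive")
  src <- octa$pixels
  H <- dim(src)[1]; W <- dim(src)[2]
  if (is.null(out_shape)) out_shape <- c(H, W)
  method <- if (octa$modality == "mask") "nearest" else "bilinear"
  if (is_identity_transform(t) && all(out_shape == c(H, W))) {
    out <- src
    attr(out, "valid") <- matrix(1, H, W)
  } else {
    ti <- invert_transform(t)
    c_in <- c((H - 1) / 2, (W - 1) / 2)
    c_out <- c((out_shape[1] - 1) / 2, (out_shape[2] - 1) / 2)
    # q = c_in + (1/s) R(-theta) (p - c_out - d)
    R <- rotation_matrix(ti$rotation_deg)
    pr <- seq_len(out_shape[1]) - 1; pc <- seq_len(out_shape[2]) - 1
    g <- expand.grid(row = pr, col = pc)
    off <- cbind(g$row - c_out[1] - t$ty, g$col - c_out[2] - t$tx)
    q <- (off %*% t(R)) / t$scale
    qr <- matrix(q[, 1] + c_in[1], out_shape[1], out_shape[2])
    qc <- matrix(q[, 2] + c_in[2], out_shape[1], out_shape[2])
    out <- resample_warp(src, qr, qc, method)
  }
  res <- retinal_image(out, modality = octa$modality,
                       px_per_mm = octa$px_per_mm, frame = "fundus_frame")
  attr(res$pixels, "valid") <- attr(out, "valid")
  res
}

# gather-based resampler: qr/qc give each output pixel's (fractional) source
# coordinate as ho x wo matrices
resample_warp <- function(src, qr, qc, method) {
  H <- dim(src)[1]; W <- dim(src)[2]; C <- dim(src)[3]
  ho <- nrow(qr); wo <- ncol(qr)
  out <- array(0, c(ho, wo, C))
  gather <- function(s, ri, ci) {
    matrix(s[cbind(as.vector(ri) + 1, as.vector(ci) + 1)], ho, wo)
  }
  if (method == "nearest") {
    ri <- round(qr); ci <- round(qc)
    ok <- ri >= 0 & ri <= H - 1 & ci >= 0 & ci <= W - 1
    ric <- pmin(pmax(ri, 0), H - 1); cic <- pmin(pmax(ci, 0), W - 1)
    for (c in seq_len(C)) {
      v <- gather(src[, , c], ric, cic)
      v[!ok] <- 0
      out[, , c] <- v
    }
  } else {
    r0 <- floor(qr); c0 <- floor(qc)
    fr <- qr - r0; fc <- qc - c0
    ok <- qr >= 0 & qr <= H - 1 & qc >= 0 & qc <= W - 1
    r0c <- pmin(pmax(r0, 0), H - 1); c0c <- pmin(pmax(c0, 0), W - 1)
    r1c <- pmin(r0c + 1, H - 1);     c1c <- pmin(c0c + 1, W - 1)
    for (c in seq_len(C)) {
      s <- src[, , c]
      v <- (1 - fr) * ((1 - fc) * gather(s, r0c, c0c) +
                       fc * gather(s, r0c, c1c)) +
           fr * ((1 - fc) * gather(s, r1c, c0c) +
                 fc * gather(s, r1c, c1c))
      v[!ok] <- 0
      out[, , c] <- v
    }
  }
  attr(out, "valid") <- matrix(as.numeric(ok), ho, wo)
  out
}

#' Crop a physical region of interest from a fundus-frame image
#'
#' Cuts a square window of physical side `side_mm` centred at the ROI centre
#' (window side in pixels is `side_mm * px_per_mm`) and resamples it to the
#' ROI's delivery resolution. The crop box is recorded in the `"crop_box"`
#' attribute (`row0`, `col0`, `side_px`, all 0-based, possibly fractional) so
#' crops can be re-inserted later.
#'
#' @param img a [retinal_image()] in `fundus_frame` with known `px_per_mm`.
#' @param roi a [roi_spec()].
#' @return A [retinal_image()] of size `output_px`, with
#'   `px_per_mm = output_px / side_mm`.
#' @export
crop_roi <- function(img, roi) {
  stopifnot(inherits(img, "retinal_image"), inherits(roi, "roi_spec"))
  if (is.na(img$px_per_mm)) stop("image has no px_per_mm scale")
  if (img$frame != "fundus_frame") stop("crop_roi expects a fundus_frame image")
  H <- dim(img$pixels)[1]; W <- dim(img$pixels)[2]
  side_px <- roi$side_mm * img$px_per_mm
  r0 <- roi$center[1] - side_px / 2
  c0 <- roi$center[2] - side_px / 2
  if (r0 < -0.5) stop("ROI window exceeds the top image edge")
  if (c0 < -0.5) stop("ROI window exceeds the left image edge")
  if (r0 + side_px > H - 0.5) stop("ROI window exceeds the bottom image edge")
  if (c0 + side_px > W - 0.5) stop("ROI window exceeds the right image edge")
  n <- roi$output_px
  # pixel-area mapping: pixel u spans [u - .5, u + .5), so output pixel u
  # samples source coordinate r0 + (u + .5) * side_px / n
  rows <- r0 + (seq_len(n) - 0.5) * side_px / n
  cols <- c0 + (seq_len(n) - 0.5) * side_px / n
  method <- if (img$modality == "mask") "nearest" else "bilinear"
  out <- resample_grid(img$pixels, rows, cols, method)
  attr(out, "valid") <- NULL
  res <- retinal_image(out, modality = img$modality,
                       px_per_mm = n / roi$side_mm, frame = "fundus_frame")
  attr(res, "crop_box") <- c(row0 = r0, col0 = c0, side_px = side_px)
  res
}
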
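#' Sliding-window stitching configuration
#'
#' @param patch_px generator patch side.
#' @param stride_px window step in pixels along both axes (default 8).
#' @param background `"zero_fill"` sets pixels outside the background mask to
#'   the minimum normalized intensity; `"skip_outside_mask"` additionally
#'   skips windows that lie entirely outside the mask.
#' @return An object of class `stitch_config`.
#' @export
stitch_config <- function(patch_px = 512, stride_px = 8,
                          background = c("zero_fill", "skip_outside_mask")) {
  if (stride_px < 1 || stride_px > patch_px)
    stop("stride_px must lie in [1, patch_px]")
  structure(list(patch_px = as.integer(patch_px),
                 stride_px = as.integer(stride_px),
                 background = match.arg(background)),
            class = "stitch_config")
}

# window origins: left-to-right at the stride, plus a final window flush with
# the far edge so the whole extent is covered without padding
window_origins <- function(extent, patch, stride) {
  o <- seq(0L, extent - patch, by = stride)
  if (o[length(o)] != extent - patch) o <- c(o, extent - patch)
  o
}

#' Stitch a full-field synthetic OCT-A image
#'
#' Applies the generator to every sliding window (left-to-right, then
#' top-to-bottom, at the configured stride, with final windows flush against
#' the right/bottom edges so coverage is complete), accumulates outputs in
#' normalized float space, and divides by the per-pixel coverage count.
#' Pixels outside the background mask are set to -1, the normalized minimum.
#'
#' @param fundus a fundus [retinal_image()] (8-bit).
#' @param mask optional background mask matrix (1 = retina); `NULL` keeps the
#'   whole field.
#' @param G an `octa_generator`, an `octa_cgan` fit, or a plain function
#'   mapping a normalized `S x S x 3` patch to an `S x S` (or `S x S x 1`)
#'   output.
#' @param cfg a [stitch_config()].
#' @return A `synthetic_octa` [retinal_image()] in the fundus frame with
#'   normalized float pixels in `[-1, 1]` and the coverage count matrix in
#'   the `"coverage"` attribute.
#' @export
synthesize_full <- function(fundus, mask = NULL, G,
                            cfg = stitch_config(patch_px = 64)) {
  stopifnot(inherits(fundus, "retinal_image"))
  H <- dim(fundus$pixels)[1]; W <- dim(fundus$pixels)[2]
  S <- cfg$patch_px
  if (H < S || W < S) stop("image sides must be at least patch_px")
  x <- normalize_intensity(fundus$pixels)
  gfun <- generator_as_function(G)
  acc <- matrix(0, H, W)
  cnt <- matrix(0, H, W)
  for (r0 in window_origins(H, S, cfg$stride_px)) {
    rows <- r0 + seq_len(S)
    for (c0 in window_origins(W, S, cfg$stride_px)) {
      cols <- c0 + seq_len(S)
      if (cfg$background == "skip_outside_mask" && !is.null(mask) &&
          all(mask[rows, cols] == 0)) next
      out <- gfun(x[rows, cols, , drop = FALSE])
      acc[rows, cols] <- acc[rows, cols] + as.vector(out)
      cnt[rows, cols] <- cnt[rows, cols] + 1
    }
  }
  res <- matrix(-1, H, W)
  inside <- cnt > 0
  res[inside] <- acc[inside] / cnt[inside]
  if (!is.null(mask)) res[mask == 0] <- -1
  img <- retinal_image(res, "synthetic_octa", fundus$px_per_mm,
                       "fundus_frame")
  attr(img$pixels, "coverage") <- cnt
  img
}

generator_as_function <- function(G) {
  if (inherits(G, "octa_cgan")) G <- G$generator
  if (inherits(G, "octa_generator"))
    function(x) generator_forward(G, x)
  else if (is.function(G)) G
  else stop("G must be an octa_generator, octa_cgan, or function")
}

#' Crop evaluation regions from a full-field synthetic image
#'
#' @param synthetic a fundus-frame [retinal_image()].
#' @param rois list of [roi_spec()] objects.
#' @return List of cropped [retinal_image()]s in the input order.
#' @export
crop_eval_rois <- function(synthetic, rois) {
  if (inherits(rois, "roi_spec")) rois <- list(rois)
  lapply(rois, function(r) crop_roi(synthetic, r))
}
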
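#' Vessel binarizer configuration
#'
#' The default method is unsupervised multiscale Hessian vesselness (bright
#' tubular structures), so no trained segmentation model is required;
#' `"global_threshold"` uses rescaled intensity directly, and
#' `"external_map"` ingests a probability map produced by any external
#' segmentation model, preserving that post-processing path for users who
#' have one.
#'
#' @param method `"vesselness_threshold"`, `"global_threshold"` or
#'   `"external_map"`.
#' @param scales Gaussian scales (sigma, in pixels) of the vesselness filter.
#' @param threshold probability cut in (0, 1).
#' @param min_object_px connected components smaller than this are removed.
#' @param beta Frangi-style blobness weight.
#' @return An object of class `binarizer_config`.
#' @export
binarizer_config <- function(method = c("vesselness_threshold",
                                        "global_threshold", "external_map"),
                             scales = c(1, 1.5, 2.5), threshold = 0.5,
                             min_object_px = 10, beta = 0.5) {
  method <- match.arg(method)
  if (any(scales <= 0)) stop("scales must be positive")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  structure(list(method = method, scales = scales, threshold = threshold,
                 min_object_px = as.integer(min_object_px), beta = beta),
            class = "binarizer_config")
}

# Gaussian-derivative filtering of a matrix (replicate boundary).
gauss_kernel_1d <- function(sigma, order = 0) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0) return(g)
  if (order == 1) return(-x / sigma^2 * g)    # zero-sum by symmetry
  k <- (x^2 / sigma^4 - 1 / sigma^2) * g
  k - sum(k) * g          # exact zero response to constants on the lattice
}

filter_sep <- function(m, krow, kcol) {
  f <- EBImage::filter2(m, outer(krow, kcol), boundary = "replicate")
  matrix(as.numeric(f), nrow(m), ncol(m))
}

# Frangi-style vesselness for bright ridges at one scale (sigma-normalized).
vesselness_scale <- function(m, sigma, beta) {
  hrr <- sigma^2 * filter_sep(m, gauss_kernel_1d(sigma, 2),
                              gauss_kernel_1d(sigma, 0))
  hcc <- sigma^2 * filter_sep(m, gauss_kernel_1d(sigma, 0),
                              gauss_kernel_1d(sigma, 2))
  hrc <- sigma^2 * filter_sep(m, gauss_kernel_1d(sigma, 1),
                              gauss_kernel_1d(sigma, 1))
  tr <- hrr + hcc
  disc <- sqrt(pmax(0, (hrr - hcc)^2 + 4 * hrc^2))
  e1 <- (tr + disc) / 2
  e2 <- (tr - disc) / 2
  # order by magnitude: l1 small, l2 large
  swap <- abs(e1) > abs(e2)
  l1 <- ifelse(swap, e2, e1)
  l2 <- ifelse(swap, e1, e2)
  Sg <- sqrt(l1^2 + l2^2)
  c2 <- (max(Sg) / 2)^2
  if (c2 == 0) return(matrix(0, nrow(m), ncol(m)))
  rb2 <- ifelse(l2 != 0, (l1 / l2)^2, 0)
  v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-Sg^2 / (2 * c2)))
  v[l2 >= 0] <- 0                      # bright ridges have l2 < 0
  v
}

#' Vessel probability map of an en face OCT-A image
#'
#' Multiscale Hessian-eigenvalue vesselness (maximum over the configured
#' scales) rescaled to `[0, 1]`; affine intensity changes of the input are
#' absorbed by the min-max rescaling. With `method = "global_threshold"` the
#' rescaled intensity itself is returned.
#'
#' @param img single-channel [retinal_image()] or matrix (raw or synthetic
#'   OCT-A; normalized or 8-bit).
#' @param cfg a [binarizer_config()].
#' @return Matrix in `[0, 1]` with attribute `"method"`.
#' @export
vessel_probability <- function(img, cfg = binarizer_config()) {
  m <- as_retinal_pixels(img)
  if (is.array(m) && length(dim(m)) == 3) {
    if (dim(m)[3] != 1) stop("vessel_probability expects a single channel")
    m <- m[, , 1]
  }
  m <- matrix(as.numeric(m), nrow(m), ncol(m))
  p <- switch(cfg$method,
    global_threshold = m,
    vesselness_threshold = {
      v <- matrix(0, nrow(m), ncol(m))
      if (max(m) > min(m))      # a constant image has no ridges at all
        for (s in cfg$scales) v <- pmax(v, vesselness_scale(m, s, cfg$beta))
      v
    },
    external_map = {
      if (min(m) < 0 || max(m) > 1)
        stop("external maps must already be scaled to [0, 1]")
      m
    })
  if (cfg$method != "external_map") {
    rng <- range(p)
    p <- if (rng[2] > rng[1]) (p - rng[1]) / (rng[2] - rng[1])
         else matrix(0, nrow(p), ncol(p))
  }
  attr(p, "method") <- cfg$method
  p
}

#' Threshold a probability map into a binary vessel mask
#'
#' Pixels strictly above the threshold are vessel; connected components
#' (4-connectivity) smaller than `min_object_px` are removed as speckle.
#'
#' @param p probability map from [vessel_probability()].
#' @param cfg a [binarizer_config()].
#' @return Binary matrix (0/1) of class `vessel_mask`.
#' @export
binarize_vessels <- function(p, cfg = binarizer_config()) {
  b <- p > cfg$threshold
  if (any(b) && cfg$min_object_px > 1) {
    lab <- EBImage::bwlabel(b * 1)
    sizes <- tabulate(lab[lab > 0])
    small <- which(sizes < cfg$min_object_px)
    if (length(small) > 0) b[matrix(lab %in% small, nrow(b))] <- FALSE
  }
  m <- matrix(as.numeric(b), nrow(b), ncol(b))
  class(m) <- c("vessel_mask", class(m))
  m
}
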
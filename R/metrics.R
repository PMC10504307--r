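#' Mean absolute error between two images
#'
#' Computed on whatever scale the inputs share; synthesis evaluation uses the
#' 8-bit 0-255 scale.
#'
#' @param a,b numeric arrays of identical shape.
#' @return Nonnegative scalar.
#' @export
mae <- function(a, b) {
  a <- as_retinal_pixels(a); b <- as_retinal_pixels(b)
  if (length(a) != length(b)) stop("shape mismatch")
  mean(abs(a - b))
}

#' Structural similarity index
#'
#' Local-window SSIM: means, unbiased variances and covariance over every
#' complete `window_px` x `window_px` window, combined with the standard
#' stabilizers `C1 = (k1 L)^2`, `C2 = (k2 L)^2`, averaged over windows.
#'
#' @param a,b single-channel images of identical shape (matrices or 1-channel
#'   arrays), at least `window_px` on each side.
#' @param window_px odd window side (default 7).
#' @param k1,k2 stabilizer constants (defaults 0.01, 0.03).
#' @param data_range dynamic range `L` (255 for 8-bit).
#' @return Scalar in `[-1, 1]`.
#' @export
ssim <- function(a, b, window_px = 7, k1 = 0.01, k2 = 0.03,
                 data_range = 255) {
  a <- drop_single_channel(a); b <- drop_single_channel(b)
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  if (any(dim(a) < window_px)) stop("image smaller than the SSIM window")
  w <- window_px
  N <- w * w
  box <- matrix(1 / N, w, w)
  f <- function(m) {
    r <- EBImage::filter2(m, box, boundary = "replicate")
    matrix(as.numeric(r), nrow(m), ncol(m))
  }
  mu_a <- f(a); mu_b <- f(b)
  e_aa <- f(a * a); e_bb <- f(b * b); e_ab <- f(a * b)
  # unbiased sample moments
  va <- (e_aa - mu_a^2) * N / (N - 1)
  vb <- (e_bb - mu_b^2) * N / (N - 1)
  cab <- (e_ab - mu_a * mu_b) * N / (N - 1)
  c1 <- (k1 * data_range)^2
  c2 <- (k2 * data_range)^2
  s <- ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
       ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
  # only complete windows: crop the replicate-padded border
  h <- (w - 1) / 2
  H <- nrow(a); W <- ncol(a)
  mean(s[(1 + h):(H - h), (1 + h):(W - h)])
}

drop_single_channel <- function(x) {
  x <- as_retinal_pixels(x)
  if (is.array(x) && length(dim(x)) == 3) {
    if (dim(x)[3] != 1) stop("expected a single-channel image")
    x <- x[, , 1]
  }
  x
}

#' Cohort synthesis metrics
#'
#' Per-image MAE and SSIM against ground truth plus the cohort mean and SD,
#' matching the mean (SD) reporting shape of synthesis studies.
#'
#' @param pred,truth lists of single-channel images (8-bit scale).
#' @param ids optional image identifiers.
#' @return List with `per_image` (data frame) and `summary` (mean/SD of each
#'   metric).
#' @export
synthesis_metrics <- function(pred, truth, ids = NULL) {
  stopifnot(length(pred) == length(truth))
  if (is.null(ids)) ids <- as.character(seq_along(pred))
  per <- data.frame(
    image_id = ids,
    mae = mapply(function(p, t) mae(p, t), pred, truth),
    ssim = mapply(function(p, t) ssim(drop_single_channel(p),
                                      drop_single_channel(t)), pred, truth))
  list(per_image = per,
       summary = data.frame(metric = c("mae", "ssim"),
                            mean = c(mean(per$mae), mean(per$ssim)),
                            sd = c(sd(per$mae), sd(per$ssim))))
}

# two-sided p for a correlation coefficient via the t transform, df = n - 2
cor_p_value <- function(r, n) {
  if (is.na(r) || n < 3 || abs(r) >= 1) {
    if (!is.na(r) && abs(r) >= 1 && n >= 3) return(0)
    return(NA_real_)
  }
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(t), df = n - 2)
}

#' Vessel-density correlations between two density tables
#'
#' For every region present in both tables, the Pearson and Spearman
#' correlations across images between the reference and candidate densities,
#' with two-sided p-values from the t transform on `n - 2` degrees of
#' freedom and a significance flag at p < 0.05. Zero-variance inputs give
#' `NA` coefficients (correlation undefined).
#'
#' @param reference,candidate `density_report` data frames (columns
#'   `image_id`, `region`, `density`) covering the same images and regions.
#' @param alpha significance level for the flag (default 0.05).
#' @return Data frame with one row per region: `n`, `pearson_r`,
#'   `pearson_p`, `spearman_rho`, `spearman_p` and logical `*_sig` flags.
#' @export
density_correlations <- function(reference, candidate, alpha = 0.05) {
  merged <- merge(reference[, c("image_id", "region", "density")],
                  candidate[, c("image_id", "region", "density")],
                  by = c("image_id", "region"),
                  suffixes = c("_ref", "_cand"))
  if (nrow(merged) == 0) stop("no shared (image, region) rows")
  regions <- intersect(etdrs_region_names, unique(merged$region))
  if (length(regions) == 0) regions <- unique(merged$region)
  rows <- lapply(regions, function(rg) {
    d <- merged[merged$region == rg, ]
    n <- nrow(d)
    if (n < 3) stop("need at least 3 images per region, got ", n)
    x <- d$density_ref; y <- d$density_cand
    if (sd(x) == 0 || sd(y) == 0) {
      r <- NA_real_; rho <- NA_real_
    } else {
      r <- cor(x, y)
      rho <- cor(rank(x), rank(y))
    }
    pr <- cor_p_value(r, n); ps <- cor_p_value(rho, n)
    data.frame(region = rg, n = n, pearson_r = r, pearson_p = pr,
               pearson_sig = !is.na(pr) & pr < alpha,
               spearman_rho = rho, spearman_p = ps,
               spearman_sig = !is.na(ps) & ps < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pixel-level precision-recall curve
#'
#' Thresholds at every distinct score (descending, "score >= threshold"
#' predicts vessel); precision `TP/(TP+FP)`, recall `TP/(TP+FN)`; area under
#' the curve by trapezoidal integration over recall, anchored at recall 0
#' with the first threshold's precision.
#'
#' @param scores numeric scores (matrix or vector; pooled if a list).
#' @param labels binary ground-truth labels of matching length; both classes
#'   must be present.
#' @return An object of class `pr_curve`: data frame `curve` (`threshold`,
#'   `precision`, `recall`) plus `auc` and `prevalence`.
#' @export
pr_curve <- function(scores, labels) {
  if (is.list(scores) && !is.data.frame(scores)) {
    scores <- unlist(lapply(scores, as.numeric))
    labels <- unlist(lapply(labels, as.numeric))
  }
  s <- as.numeric(scores); l <- as.numeric(labels)
  if (length(s) != length(l)) stop("scores and labels differ in length")
  if (!all(l %in% c(0, 1))) stop("labels must be binary")
  P <- sum(l)
  if (P == 0 || P == length(l)) stop("labels contain a single class")
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; l <- l[ord]
  tp <- cumsum(l)
  fp <- cumsum(1 - l)
  last <- which(!duplicated(s, fromLast = TRUE))   # last index of each score
  thr <- s[last]
  precision <- tp[last] / (tp[last] + fp[last])
  recall <- tp[last] / P
  rec <- c(0, recall)
  prec <- c(precision[1], precision)
  auc <- sum(diff(rec) * (head(prec, -1) + tail(prec, -1)) / 2)
  structure(list(curve = data.frame(threshold = thr, precision = precision,
                                    recall = recall),
                 auc = auc, prevalence = P / length(l)),
            class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("<pr_curve> %d thresholds, AUC %.4f (prevalence %.4f)\n",
              nrow(x$curve), x$auc, x$prevalence))
  invisible(x)
}

#' @export
plot.pr_curve <- function(x, ...) {
  plot(x$curve$recall, x$curve$precision, type = "l", xlim = c(0, 1),
       ylim = c(0, 1), xlab = "Recall", ylab = "Precision", ...)
  invisible(x)
}
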
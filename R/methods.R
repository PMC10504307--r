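# S3 methods for the fitted translation model.

#' @export
print.octa_cgan <- function(x, ...) {
  cat(sprintf("<octa_cgan> mode=%s, %d epochs, best epoch %d (%s %.4f)\n",
              x$config$mode, x$config$epochs, x$best_epoch,
              x$config$checkpoint_metric, x$best_metric))
  cat(sprintf("  generator: depth %d, %d parameters\n",
              x$generator$spec$depth, count_parameters(x$generator)))
  if (!is.null(x$discriminator))
    cat(sprintf("  discriminator: %d blocks, %d parameters\n",
                x$discriminator$spec$n_conv_blocks,
                count_parameters(x$discriminator)))
  invisible(x)
}

#' @export
summary.octa_cgan <- function(object, ...) {
  h <- object$history
  res <- list(mode = object$config$mode,
              epochs = nrow(h),
              best_epoch = object$best_epoch,
              best_metric = object$best_metric,
              first_val_l_rec = h$val_l_rec[1],
              best_val_l_rec = h$val_l_rec[object$best_epoch],
              final_val_l_rec = h$val_l_rec[nrow(h)],
              n_params_g = count_parameters(object$generator),
              split = object$split)
  class(res) <- "summary.octa_cgan"
  res
}

#' @export
print.summary.octa_cgan <- function(x, ...) {
  cat(sprintf("Fundus-to-OCT-A model (%s mode)\n", x$mode))
  cat(sprintf("  epochs run          : %d\n", x$epochs))
  cat(sprintf("  best epoch          : %d\n", x$best_epoch))
  cat(sprintf("  validation l_rec    : %.4f (epoch 1) -> %.4f (best)\n",
              x$first_val_l_rec, x$best_val_l_rec))
  cat(sprintf("  generator parameters: %d\n", x$n_params_g))
  cat(sprintf("  split               : %d train / %d val / %d test subjects\n",
              length(x$split$train_ids), length(x$split$val_ids),
              length(x$split$test_ids)))
  invisible(x)
}

#' Predict synthetic OCT-A from fundus input
#'
#' `type = "patch"` runs the generator on a single normalized-or-8-bit patch;
#' `type = "full"` stitches a full-field synthetic image with sliding-window
#' overlap averaging.
#'
#' @param object a fitted `octa_cgan`.
#' @param newdata a fundus [retinal_image()] or patch array.
#' @param type `"patch"` or `"full"`.
#' @param mask optional background mask for `type = "full"`.
#' @param stride_px sliding-window stride for `type = "full"`.
#' @param ... unused.
#' @return Normalized synthetic patch (array) or full-field
#'   [retinal_image()].
#' @export
predict.octa_cgan <- function(object, newdata, type = c("patch", "full"),
                              mask = NULL, stride_px = 8, ...) {
  type <- match.arg(type)
  if (type == "patch") {
    x <- as_retinal_pixels(newdata)
    if (max(x) > 1) x <- normalize_intensity(x)
    return(generator_forward(object$generator, x))
  }
  img <- if (inherits(newdata, "retinal_image")) newdata
         else retinal_image(newdata, "fundus")
  synthesize_full(img, mask, object,
                  stitch_config(patch_px = object$config$patch_px,
                                stride_px = stride_px))
}

#' @export
coef.octa_cgan <- function(object, ...) {
  lapply(object$generator$params, function(p) list(w = p$w, b = p$b))
}

#' Residuals of the fitted model on aligned pairs
#'
#' @param object a fitted `octa_cgan`.
#' @param pairs aligned pairs ([aligned_pairs()]); defaults cannot be
#'   reconstructed, so this argument is required.
#' @param ... unused.
#' @return List of normalized residual images (`target - synthetic`) for the
#'   central patch of each pair.
#' @export
residuals.octa_cgan <- function(object, pairs, ...) {
  S <- object$config$patch_px
  lapply(pairs, function(p) {
    H <- dim(p$x)[1]; W <- dim(p$x)[2]
    r0 <- floor((H - S) / 2); c0 <- floor((W - S) / 2)
    rows <- r0 + seq_len(S); cols <- c0 + seq_len(S)
    x <- normalize_intensity(p$x[rows, cols, , drop = FALSE])
    y <- p$y
    if (is.matrix(y)) dim(y) <- c(dim(y), 1L)
    y <- y[rows, cols, 1, drop = FALSE]
    if (object$config$mode == "synthesis") y <- normalize_intensity(y)
    y - generator_forward(object$generator, x)
  })
}

#' Plot the training history
#'
#' Reconstruction and adversarial loss trajectories on train and validation,
#' with the retained checkpoint marked.
#'
#' @param x a fitted `octa_cgan`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.octa_cgan <- function(x, ...) {
  h <- x$history
  plot(h$epoch, h$train_l_rec, type = "l", col = "grey40",
       xlab = "Epoch", ylab = "Reconstruction loss",
       ylim = range(c(h$train_l_rec, h$val_l_rec)), ...)
  lines(h$epoch, h$val_l_rec, col = "firebrick")
  graphics::abline(v = x$best_epoch, lty = 3)
  legend("topright", legend = c("train", "validation", "best checkpoint"),
         col = c("grey40", "firebrick", "black"), lty = c(1, 1, 3), bty = "n")
  invisible(x)
}

#' Simulate phantom cohorts from the fitted configuration
#'
#' Draws `nsim` fresh phantom subjects (distinct seeds per simulation) and
#' returns the model's full-field synthetic OCT-A for each, which is the
#' model-based analogue of simulating from a fitted model.
#'
#' @param object a fitted `octa_cgan`.
#' @param nsim number of phantoms.
#' @param seed cohort seed.
#' @param template [phantom_spec()] template for the simulated subjects.
#' @param stride_px stitching stride.
#' @param ... unused.
#' @return List of `nsim` elements, each with the phantom `pair` and the
#'   model's `synthetic` full-field image.
#' @export
simulate.octa_cgan <- function(object, nsim = 1, seed = 1L,
                               template = phantom_spec(image_size = 128,
                                                       px_per_mm = 24),
                               stride_px = 8, ...) {
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, nsim))
  lapply(seq_len(nsim), function(i) {
    sp <- template
    sp$seed <- seeds[i]
    pair <- render_phantom_pair(grow_vessel_tree(sp), sp)
    syn <- predict(object, pair$fundus, type = "full", stride_px = stride_px)
    list(pair = pair, synthetic = syn)
  })
}
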
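#' Training configuration
#'
#' Bundles the optimization schedule of the adversarial synthesis mode and of
#' the direct-segmentation mode. Full-scale defaults follow the study recipe:
#' 512-px patches, 20 raw patch draws per epoch expanded by reflection and
#' rotation augmentation to 120 training pairs, 9 validation pairs, 1000
#' epochs, Adam at 2e-4 for both players, reconstruction weight 100; the
#' direct-segmentation mode uses binary cross entropy with Adam at 1e-3.
#'
#' @param mode `"synthesis"` (adversarial, OCT-A intensity target) or
#'   `"direct_segmentation"` (sigmoid head, binary mask target).
#' @param patch_px square patch side; must be divisible by `2^depth` of the
#'   generator.
#' @param raw_draws_per_epoch raw random patch draws per epoch.
#' @param patches_per_epoch_train training pairs per epoch after augmentation
#'   expansion (raw draws are cycled with fresh dihedral transforms).
#' @param patches_per_epoch_val validation pairs (drawn once, reused every
#'   epoch so the checkpoint metric is comparable across epochs).
#' @param epochs training epochs.
#' @param lr_g,lr_d Adam learning rates of generator and discriminator
#'   (synthesis mode).
#' @param lr Adam learning rate of the direct-segmentation mode.
#' @param lambda reconstruction weight in the generator objective.
#' @param norm reconstruction norm, `"l1"` or `"l2"`.
#' @param augment apply joint dihedral (reflection/rotation) augmentation.
#' @param seed seed driving patch sampling, augmentation and weight init.
#' @param checkpoint_metric `"gan_loss"` (validation generator objective) or
#'   `"val_loss"` (validation reconstruction/BCE loss).
#' @param roi_px side of the square macula/disc training regions cut around
#'   the fovea and disc centres, mirroring training on the OCT-A fields of
#'   view only; `NULL` samples patches from the whole raster.
#' @param gen_spec,disc_spec network architecture specs.
#' @return An object of class `train_config`.
#' @export
train_config <- function(mode = c("synthesis", "direct_segmentation"),
                         patch_px = 512, raw_draws_per_epoch = 20,
                         patches_per_epoch_train = 120,
                         patches_per_epoch_val = 9, epochs = 1000,
                         lr_g = 2e-4, lr_d = 2e-4, lr = 1e-3, lambda = 100,
                         norm = c("l1", "l2"), augment = TRUE, seed = 1L,
                         checkpoint_metric = NULL, roi_px = NULL,
                         gen_spec = generator_spec(),
                         disc_spec = discriminator_spec()) {
  mode <- match.arg(mode)
  norm <- match.arg(norm)
  if (lr_g <= 0 || lr_d < 0 || lr <= 0) stop("learning rates must be positive")
  if (patch_px %% 2^gen_spec$depth != 0)
    stop("patch_px must be divisible by 2^generator depth")
  if (is.null(checkpoint_metric))
    checkpoint_metric <- if (mode == "synthesis") "gan_loss" else "val_loss"
  stopifnot(checkpoint_metric %in% c("gan_loss", "val_loss"))
  structure(list(mode = mode, patch_px = as.integer(patch_px),
                 raw_draws_per_epoch = as.integer(raw_draws_per_epoch),
                 patches_per_epoch_train = as.integer(patches_per_epoch_train),
                 patches_per_epoch_val = as.integer(patches_per_epoch_val),
                 epochs = as.integer(epochs), lr_g = lr_g, lr_d = lr_d,
                 lr = lr, lambda = lambda, norm = norm,
                 augment = isTRUE(augment), seed = as.integer(seed),
                 checkpoint_metric = checkpoint_metric,
                 roi_px = if (is.null(roi_px)) NULL else as.integer(roi_px),
                 gen_spec = gen_spec, disc_spec = disc_spec),
            class = "train_config")
}

#' Scaled-down configuration for phantom studies
#'
#' The phantom study conditions: 64-px patches on 128-px phantoms, 20 patch
#' draws per epoch, 150 epochs, compact networks (depth-2 generator with 8
#' base filters, 2-block discriminator). Learning rates, reconstruction
#' weight and checkpoint rule are unchanged from the full-scale recipe.
#'
#' @param mode,epochs,seed overrides passed through to [train_config()].
#' @param ... further overrides of [train_config()] arguments.
#' @return A [train_config()].
#' @export
phantom_train_config <- function(mode = "synthesis", epochs = 150, seed = 1L,
                                 ...) {
  train_config(mode = mode, patch_px = 64, raw_draws_per_epoch = 20,
               patches_per_epoch_train = 20, patches_per_epoch_val = 9,
               epochs = epochs, seed = seed, roi_px = 80,
               gen_spec = generator_spec(depth = 2, base_filters = 8,
                                         max_filters = 64),
               disc_spec = discriminator_spec(n_conv_blocks = 2,
                                              base_filters = 8,
                                              max_filters = 64),
               ...)
}

#' Patient-level split
#'
#' @param train_ids,val_ids,test_ids disjoint character vectors of subject
#'   identifiers; any overlap is rejected so patient-level leakage is
#'   impossible by construction.
#' @return An object of class `subject_split`.
#' @export
subject_split <- function(train_ids, val_ids, test_ids = character(0)) {
  all_ids <- c(train_ids, val_ids, test_ids)
  if (anyDuplicated(all_ids))
    stop("subject ids must not occur in more than one partition: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  if (length(train_ids) == 0 || length(val_ids) == 0)
    stop("train and validation partitions must be non-empty")
  structure(list(train_ids = train_ids, val_ids = val_ids,
                 test_ids = test_ids), class = "subject_split")
}

#' Aligned training pairs from a phantom cohort
#'
#' Brings each subject's OCT-A (and mask) into the fundus frame using the
#' stored rigid transform and packages the co-registered rasters as the
#' sampling units for patch extraction.
#'
#' @param subjects subject list as returned by [load_phantom_dataset()]
#'   (`$subjects`).
#' @param target `"octa"` for synthesis, `"mask"` for direct segmentation.
#' @return List of aligned pairs, each with `subject`, `roi`, `x` (fundus
#'   array, 8-bit) and `y` (target array: 8-bit OCT-A or 0/1 mask).
#' @export
aligned_pairs <- function(subjects, target = c("octa", "mask")) {
  target <- match.arg(target)
  lapply(subjects, function(s) {
    tt <- s$true_transform
    y_img <- if (target == "octa") s$octa else s$mask
    y_al <- if (is_identity_transform(tt)) y_img$pixels
            else apply_similarity_transform(y_img, tt)$pixels
    attr(y_al, "valid") <- NULL
    list(subject = s$id, roi = "full", x = s$fundus$pixels, y = y_al)
  })
}

#' Square training region boxes around the fovea and disc
#'
#' Integer boxes of side `roi_px` centred on the subject's fovea and disc,
#' clamped inside the raster — the phantom analogue of the macular and
#' optic-disc OCT-A fields of view that training is restricted to.
#'
#' @param subject subject entry with `fovea_center`, `disc_center`.
#' @param roi_px box side in pixels.
#' @param shape raster size `(H, W)`.
#' @return Named list (`macula`, `disc`) of `(row0, col0)` 0-based corners.
#' @export
training_roi_boxes <- function(subject, roi_px, shape) {
  clamp_box <- function(center) {
    r0 <- round(center[1]) - roi_px %/% 2
    c0 <- round(center[2]) - roi_px %/% 2
    c(row0 = min(max(r0, 0), shape[1] - roi_px),
      col0 = min(max(c0, 0), shape[2] - roi_px))
  }
  list(macula = clamp_box(subject$fovea_center),
       disc = clamp_box(subject$disc_center))
}

#' Pixel mask of the training regions
#'
#' @inheritParams training_roi_boxes
#' @return Binary `H x W` matrix, 1 inside the union of the macula and disc
#'   training boxes.
#' @export
roi_pixel_mask <- function(subject, roi_px, shape) {
  m <- matrix(0, shape[1], shape[2])
  for (b in training_roi_boxes(subject, roi_px, shape)) {
    m[b["row0"] + seq_len(roi_px), b["col0"] + seq_len(roi_px)] <- 1
  }
  m
}

# split one full-raster aligned pair into its macula and disc ROI pairs
crop_training_rois <- function(pair, subject, roi_px) {
  shape <- dim(pair$x)[1:2]
  boxes <- training_roi_boxes(subject, roi_px, shape)
  y <- pair$y
  if (is.matrix(y)) dim(y) <- c(dim(y), 1L)
  lapply(names(boxes), function(nm) {
    b <- boxes[[nm]]
    rows <- b["row0"] + seq_len(roi_px); cols <- b["col0"] + seq_len(roi_px)
    list(subject = pair$subject, roi = nm,
         x = pair$x[rows, cols, , drop = FALSE],
         y = y[rows, cols, , drop = FALSE])
  })
}

#' Sample random co-located patch pairs
#'
#' Draws `n` patches with uniformly random top-left corners fully inside the
#' aligned rasters; the fundus crop and the co-located target crop are cut
#' with the same window. Sampling consumes the caller's RNG stream, so a
#' fixed seed reproduces the same corner sequence.
#'
#' @param pairs aligned pairs from [aligned_pairs()].
#' @param n number of patches.
#' @param patch_px square patch side; every raster side must be at least this.
#' @return List of patch pairs: `x` (`S x S x 3`), `y` (`S x S x 1`), both on
#'   their native scales, plus `subject` and `roi` provenance.
#' @export
sample_patch_pairs <- function(pairs, n, patch_px) {
  sizes <- vapply(pairs, function(p) min(dim(p$x)[1:2]), numeric(1))
  if (any(sizes < patch_px))
    stop("all ROI images must have sides >= patch_px = ", patch_px)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p <- pairs[[sample.int(length(pairs), 1)]]
    H <- dim(p$x)[1]; W <- dim(p$x)[2]
    r0 <- sample.int(H - patch_px + 1L, 1) - 1L
    c0 <- sample.int(W - patch_px + 1L, 1) - 1L
    rows <- r0 + seq_len(patch_px); cols <- c0 + seq_len(patch_px)
    y <- p$y
    if (is.matrix(y)) dim(y) <- c(dim(y), 1L)
    out[[i]] <- list(x = p$x[rows, cols, , drop = FALSE],
                     y = y[rows, cols, 1, drop = FALSE],
                     subject = p$subject, roi = p$roi,
                     corner = c(r0, c0))
  }
  out
}

# Apply dihedral element k (0..7) to a matrix: k in 0..3 rotates clockwise by
# 90k degrees; k in 4..7 flips horizontally first, then rotates by 90(k-4).
dihedral_matrix <- function(m, k) {
  if (k >= 4) { m <- m[, ncol(m):1, drop = FALSE]; k <- k - 4 }
  for (i in seq_len(k %% 4)) m <- t(m[nrow(m):1, , drop = FALSE])
  m
}

dihedral_array <- function(a, k) {
  if (k == 0) return(a)
  planes <- lapply(seq_len(dim(a)[3]), function(c) dihedral_matrix(a[, , c], k))
  out <- array(vector(typeof(a), 1), c(dim(planes[[1]]), dim(a)[3]))
  for (c in seq_along(planes)) out[, , c] <- planes[[c]]
  out
}

#' Jointly augment a patch pair
#'
#' Applies the same transform, drawn uniformly from the 8-element dihedral
#' group generated by reflections and 90-degree rotations, to both patches so
#' vessel structures stay co-registered.
#'
#' @param p a patch pair from [sample_patch_pairs()].
#' @param k optional dihedral element in `0:7` (drawn uniformly from the
#'   caller's RNG stream when `NULL`).
#' @return The transformed patch pair (with the element recorded as
#'   `$augment`).
#' @export
augment_pair <- function(p, k = NULL) {
  if (dim(p$x)[1] != dim(p$x)[2]) stop("augmentation requires square patches")
  if (is.null(k)) k <- sample.int(8L, 1) - 1L
  p$x <- dihedral_array(p$x, k)
  p$y <- dihedral_array(p$y, k)
  p$augment <- k
  p
}

# Normalize a sampled pair for the given mode.
prep_pair <- function(p, mode) {
  x <- normalize_intensity(p$x)
  y <- if (mode == "synthesis") normalize_intensity(p$y) else {
    if (!all(p$y %in% c(0, 1))) stop("direct_segmentation targets must be binary")
    p$y
  }
  list(x = x, y = y, subject = p$subject)
}

# Per-pixel binary cross entropy with score clamping.
bce_loss <- function(pred, target, eps = 1e-7) {
  p <- pmin(1 - eps, pmax(eps, pred))
  mean(-target * log(p) - (1 - target) * log(1 - p))
}

bce_grad <- function(pred, target, eps = 1e-7) {
  p <- pmin(1 - eps, pmax(eps, pred))
  ((p - target) / (p * (1 - p))) / length(pred)
}

#' One epoch of alternating adversarial optimization
#'
#' For each normalized patch pair: one discriminator Adam step minimizing
#' `-[log D(x, y) + log(1 - D(x, G(x)))]`, then one generator Adam step
#' minimizing `-log D(x, G(x)) + lambda * L_rec`. Losses recorded are the
#' pre-update values for each pair.
#'
#' @param state list with elements `G`, `D`, `opt_g`, `opt_d` (Adam states).
#' @param batch list of normalized pairs (from `prep_pair`).
#' @param config a [train_config()].
#' @return Updated `state` with a `stats` element holding epoch means
#'   (`l_rec`, `l_adv_g`, `l_adv_d`, `l_total_g`).
#' @export
train_epoch <- function(state, batch, config) {
  G <- state$G; D <- state$D
  opt_g <- state$opt_g; opt_d <- state$opt_d
  lam <- config$lambda
  acc <- c(l_rec = 0, l_adv_g = 0, l_adv_d = 0, l_total_g = 0)
  for (bi in seq_along(batch)) {
    b <- batch[[bi]]
    gf <- generator_forward(G, b$x, keep_cache = TRUE)
    g_x <- gf$y
    # --- discriminator step ---
    fr <- discriminator_forward(D, b$x, b$y, keep_cache = TRUE)
    ff <- discriminator_forward(D, b$x, g_x, keep_cache = TRUE)
    adv <- adversarial_loss(fr$score, ff$score)
    l_rec <- reconstruction_loss(b$y, g_x, config$norm)
    if (!is.finite(adv$l_adv_d) || !is.finite(l_rec))
      stop("non-finite loss on pair ", bi, " (subject ", b$subject, ")")
    eps <- 1e-7
    rcl <- min(max(fr$score, eps), 1 - eps)
    fcl <- min(max(ff$score, eps), 1 - eps)
    gd_r <- discriminator_backward(D, fr$cache, -1 / rcl)$grads
    gd_f <- discriminator_backward(D, ff$cache, 1 / (1 - fcl))$grads
    if (config$lr_d > 0) {
      stp <- adam_step(D$params, add_grads(gd_r, gd_f), opt_d, config$lr_d)
      D$params <- stp$params; opt_d <- stp$state
    }
    # --- generator step (against the updated discriminator) ---
    f2 <- discriminator_forward(D, b$x, g_x, keep_cache = TRUE)
    f2c <- min(max(f2$score, eps), 1 - eps)
    l_adv_g <- -log(f2c)
    db <- discriminator_backward(D, f2$cache, -1 / f2c)
    dgx <- db$dy + lam * reconstruction_grad(b$y, g_x, config$norm)
    gg <- generator_backward(G, gf$cache, dgx)
    stp <- adam_step(G$params, gg, opt_g, config$lr_g)
    G$params <- stp$params; opt_g <- stp$state
    acc <- acc + c(l_rec, l_adv_g, adv$l_adv_d,
                   generator_objective(l_rec, l_adv_g, lam))
  }
  state$G <- G; state$D <- D; state$opt_g <- opt_g; state$opt_d <- opt_d
  state$stats <- as.list(acc / length(batch))
  state
}

# Evaluation-only losses on a fixed set of normalized pairs.
eval_patches <- function(G, D, batch, config) {
  acc <- c(l_rec = 0, l_adv_g = 0, l_adv_d = 0, l_total_g = 0)
  for (b in batch) {
    g_x <- generator_forward(G, b$x)
    if (config$mode == "direct_segmentation") {
      l <- bce_loss(g_x, b$y)
      acc <- acc + c(l, 0, 0, l)
    } else {
      l_rec <- reconstruction_loss(b$y, g_x, config$norm)
      dr <- discriminator_forward(D, b$x, b$y)
      df <- discriminator_forward(D, b$x, g_x)
      adv <- adversarial_loss(dr, df)
      acc <- acc + c(l_rec, adv$l_adv_g, adv$l_adv_d,
                     generator_objective(l_rec, adv$l_adv_g, config$lambda))
    }
  }
  as.list(acc / length(batch))
}

# One epoch of direct-segmentation (BCE) optimization.
seg_epoch <- function(state, batch, config) {
  G <- state$G; opt_g <- state$opt_g
  tot <- 0
  for (b in batch) {
    gf <- generator_forward(G, b$x, keep_cache = TRUE)
    l <- bce_loss(gf$y, b$y)
    if (!is.finite(l)) stop("non-finite BCE loss (subject ", b$subject, ")")
    gg <- generator_backward(G, gf$cache, bce_grad(gf$y, b$y))
    stp <- adam_step(G$params, gg, opt_g, config$lr)
    G$params <- stp$params; opt_g <- stp$state
    tot <- tot + l
  }
  state$G <- G; state$opt_g <- opt_g
  state$stats <- list(l_rec = tot / length(batch), l_adv_g = 0, l_adv_d = 0,
                      l_total_g = tot / length(batch))
  state
}

#' Fit the fundus-to-OCT-A translation model
#'
#' The central fitting function. Splits subjects at the patient level, builds
#' aligned pairs, then alternates discriminator/generator Adam steps over
#' randomly sampled, jointly augmented patch pairs (synthesis mode), or
#' minimizes per-pixel binary cross entropy with a sigmoid head
#' (direct-segmentation mode). After every epoch the configured metric is
#' computed on a fixed set of validation patches and the best checkpoint is
#' retained.
#'
#' @param subjects subject list (see [load_phantom_dataset()]).
#' @param split a [subject_split()]; all ids must exist in `subjects`.
#' @param config a [train_config()].
#' @param verbose print a per-epoch line to stderr.
#' @return An object of class `octa_cgan`: the best generator (and
#'   discriminator), the full per-epoch loss history, the best epoch index,
#'   the configuration and the split.
#' @export
fit_octa_cgan <- function(subjects, split, config = phantom_train_config(),
                          verbose = FALSE) {
  stopifnot(inherits(split, "subject_split"), inherits(config, "train_config"))
  ids <- vapply(subjects, `[[`, "", "id")
  missing_ids <- setdiff(c(split$train_ids, split$val_ids), ids)
  if (length(missing_ids) > 0)
    stop("split refers to unknown subjects: ",
         paste(missing_ids, collapse = ", "))
  target <- if (config$mode == "synthesis") "octa" else "mask"
  make_pairs <- function(sel) {
    subj <- subjects[match(sel, ids)]
    ap <- aligned_pairs(subj, target)
    if (is.null(config$roi_px)) return(ap)
    unlist(lapply(seq_along(ap), function(j)
      crop_training_rois(ap[[j]], subj[[j]], config$roi_px)),
      recursive = FALSE)
  }
  tr_pairs <- make_pairs(split$train_ids)
  va_pairs <- make_pairs(split$val_ids)

  seg <- config$mode == "direct_segmentation"
  gspec <- config$gen_spec
  if (seg && gspec$output_activation != "sigmoid") {
    gspec$output_activation <- "sigmoid"
  }
  history <- vector("list", config$epochs)
  best <- list(metric = Inf, epoch = NA_integer_, G = NULL, D = NULL)

  with_seed(config$seed, {
    G <- build_generator(gspec, seed = sample.int(1e6, 1))
    D <- if (!seg) build_discriminator(config$disc_spec,
                                       seed = sample.int(1e6, 1)) else NULL
    state <- list(G = G, D = D, opt_g = adam_init(G$params),
                  opt_d = if (!seg) adam_init(D$params) else NULL)
    val_batch <- lapply(sample_patch_pairs(va_pairs,
                                           config$patches_per_epoch_val,
                                           config$patch_px),
                        prep_pair, mode = config$mode)
    for (ep in seq_len(config$epochs)) {
      raw <- sample_patch_pairs(tr_pairs, config$raw_draws_per_epoch,
                                config$patch_px)
      idx <- rep_len(seq_along(raw), config$patches_per_epoch_train)
      batch <- lapply(idx, function(i) {
        p <- raw[[i]]
        if (config$augment) p <- augment_pair(p)
        prep_pair(p, config$mode)
      })
      state <- if (seg) seg_epoch(state, batch, config)
               else train_epoch(state, batch, config)
      val <- eval_patches(state$G, state$D, val_batch, config)
      metric <- if (config$checkpoint_metric == "gan_loss") val$l_total_g
                else val$l_rec
      history[[ep]] <- data.frame(epoch = ep,
                                  train_l_rec = state$stats$l_rec,
                                  train_l_adv_g = state$stats$l_adv_g,
                                  train_l_adv_d = state$stats$l_adv_d,
                                  train_l_total_g = state$stats$l_total_g,
                                  val_l_rec = val$l_rec,
                                  val_l_adv_g = val$l_adv_g,
                                  val_l_adv_d = val$l_adv_d,
                                  val_l_total_g = val$l_total_g,
                                  val_metric = metric)
      if (metric < best$metric)
        best <- list(metric = metric, epoch = ep, G = state$G, D = state$D)
      if (verbose)
        message(sprintf("epoch %d/%d  train l_rec %.4f  val metric %.4f%s",
                        ep, config$epochs, state$stats$l_rec, metric,
                        if (best$epoch == ep) "  *" else ""))
    }
  })
  structure(list(generator = best$G, discriminator = best$D,
                 best_epoch = best$epoch, best_metric = best$metric,
                 history = do.call(rbind, history), config = config,
                 split = split),
            class = "octa_cgan")
}

#' Train the direct-segmentation variant
#'
#' Same patch sampling and augmentation machinery as the synthesis mode, but
#' the U-Net backbone ends in a sigmoid head and is optimized with per-pixel
#' binary cross entropy (Adam, learning rate 1e-3) against binary vessel
#' masks; the lowest-validation-loss checkpoint is retained.
#'
#' @param subjects subject list with binary masks.
#' @param split a [subject_split()].
#' @param config a [train_config()]; its mode is forced to
#'   `direct_segmentation`.
#' @param verbose print per-epoch progress.
#' @return An `octa_cgan` object (with `config$mode == "direct_segmentation"`).
#' @export
train_direct_segmentation <- function(subjects, split,
                                      config = phantom_train_config(
                                        mode = "direct_segmentation"),
                                      verbose = FALSE) {
  config$mode <- "direct_segmentation"
  config$checkpoint_metric <- "val_loss"
  fit_octa_cgan(subjects, split, config, verbose)
}
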
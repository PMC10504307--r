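make_pair <- function(S = 96, seed = 1) {
  with_seed_test(seed, list(
    subject = "s1", roi = "full",
    x = array(sample(0:255, S * S * 3, TRUE), c(S, S, 3)),
    y = array(sample(0:255, S * S, TRUE), c(S, S, 1))))
}

test_that("a patch-sized ROI forces the single possible corner", {
  p <- make_pair(64)
  got <- with_seed_test(1, sample_patch_pairs(list(p), 3, 64))
  for (g in got) {
    expect_equal(g$corner, c(0, 0))
    expect_identical(g$x, p$x)
  }
  expect_error(sample_patch_pairs(list(p), 1, 96), ">= patch_px")
})

test_that("corner sampling reproduces under a fixed seed and is uniform", {
  p <- make_pair(96)
  c1 <- with_seed_test(7, sample_patch_pairs(list(p), 50, 64))
  c2 <- with_seed_test(7, sample_patch_pairs(list(p), 50, 64))
  expect_identical(lapply(c1, `[[`, "corner"), lapply(c2, `[[`, "corner"))

  draws <- with_seed_test(42, sample_patch_pairs(list(p), 10000, 64))
  corners <- t(vapply(draws, `[[`, numeric(2), "corner"))
  # 33 x 33 corner lattice; chi-square uniformity at p > 0.001
  counts <- table(factor(corners[, 1], levels = 0:32),
                  factor(corners[, 2], levels = 0:32))
  chi <- sum((counts - 10000 / 1089)^2 / (10000 / 1089))
  expect_gt(pchisq(chi, df = 1089 - 1, lower.tail = FALSE), 0.001)
})

test_that("dihedral augmentation covers all 8 elements uniformly", {
  p <- make_pair(8)
  expect_identical(augment_pair(p, k = 0)$x, p$x)
  # reflections are involutions; opposite rotations cancel
  for (k in 4:7) expect_identical(augment_pair(augment_pair(p, k), k)$x, p$x)
  for (k in 1:3)
    expect_identical(augment_pair(augment_pair(p, k), 4 - k)$x, p$x)
  ks <- with_seed_test(3, vapply(seq_len(8000),
                                 function(i) augment_pair(p)$augment,
                                 numeric(1)))
  freq <- tabulate(ks + 1, nbins = 8) / 8000
  expect_true(all(abs(freq - 1 / 8) <= 0.02))
})

test_that("joint augmentation keeps the two patches co-registered", {
  S <- 16
  ramp <- matrix(seq_len(S * S), S, S)
  p <- list(x = array(rep(ramp, 3), c(S, S, 3)), y = array(ramp, c(S, S, 1)),
            subject = "s", roi = "full")
  for (k in 0:7) {
    a <- augment_pair(p, k)
    expect_identical(a$x[, , 1], a$y[, , 1])
  }
  expect_error(augment_pair(list(x = array(0, c(4, 8, 3)),
                                 y = array(0, c(4, 8, 1)))), "square")
})

test_that("zero learning rates freeze parameters and report eval losses", {
  cfg <- phantom_train_config(seed = 1)
  cfg$lr_g <- 0; cfg$lr_d <- 0
  G <- build_generator(cfg$gen_spec, 1); D <- build_discriminator(cfg$disc_spec, 2)
  batch <- lapply(with_seed_test(5, sample_patch_pairs(list(make_pair(96)), 3, 64)),
                  octasyn:::prep_pair, mode = "synthesis")
  st <- list(G = G, D = D, opt_g = octasyn:::adam_init(G$params),
             opt_d = octasyn:::adam_init(D$params))
  st2 <- train_epoch(st, batch, cfg)
  expect_identical(st2$G$params, G$params)
  expect_identical(st2$D$params, D$params)
  # with frozen nets the recorded means equal hand-averaged per-pair losses
  manual <- octasyn:::eval_patches(G, D, batch, cfg)
  expect_equal(st2$stats$l_rec, manual$l_rec, tolerance = 1e-12)
  expect_equal(st2$stats$l_adv_d, manual$l_adv_d, tolerance = 1e-12)
  expect_equal(st2$stats$l_total_g, manual$l_total_g, tolerance = 1e-12)
})

test_that("repeated steps on one pair drive the reconstruction loss down", {
  cfg <- phantom_train_config(seed = 2)
  G <- build_generator(cfg$gen_spec, 3); D <- build_discriminator(cfg$disc_spec, 4)
  batch <- lapply(with_seed_test(6, sample_patch_pairs(list(make_pair(64)), 1, 64)),
                  octasyn:::prep_pair, mode = "synthesis")
  st <- list(G = G, D = D, opt_g = octasyn:::adam_init(G$params),
             opt_d = octasyn:::adam_init(D$params))
  first <- NULL
  for (i in 1:50) {
    st <- train_epoch(st, batch, cfg)
    if (i == 1) first <- st$stats$l_rec
  }
  expect_lt(st$stats$l_rec, first)
})

test_that("patient-level splits reject any leakage", {
  expect_error(subject_split(c("a", "b"), c("b")), "more than one partition")
  expect_error(subject_split(character(0), "a"), "non-empty")
  sp <- subject_split(c("a", "b"), "c", "d")
  expect_s3_class(sp, "subject_split")
})

test_that("the retained checkpoint is the validation-metric argmin", {
  ds <- tiny_cohort(8, seed = 11)
  ids <- names(ds$subjects)
  split <- subject_split(ids[1:5], ids[6:7], ids[8])
  cfg <- phantom_train_config(epochs = 4, seed = 3)
  fit <- fit_octa_cgan(ds$subjects, split, cfg)
  expect_equal(fit$best_epoch, which.min(fit$history$val_metric))
  expect_equal(fit$best_metric, min(fit$history$val_metric))
  one <- fit_octa_cgan(ds$subjects, split,
                       phantom_train_config(epochs = 1, seed = 3))
  expect_equal(one$best_epoch, 1)
  expect_error(fit_octa_cgan(ds$subjects,
                             subject_split("nope", ids[6]), cfg),
               "unknown subjects")
})

test_that("two fits with one seed agree loss for loss", {
  ds <- tiny_cohort(8, seed = 11)
  ids <- names(ds$subjects)
  split <- subject_split(ids[1:5], ids[6:7], ids[8])
  cfg <- phantom_train_config(epochs = 3, seed = 17)
  f1 <- fit_octa_cgan(ds$subjects, split, cfg)
  f2 <- fit_octa_cgan(ds$subjects, split, cfg)
  expect_true(all(abs(f1$history$val_l_rec - f2$history$val_l_rec) < 1e-4))
  expect_true(all(abs(f1$history$train_l_total_g -
                        f2$history$train_l_total_g) < 1e-4))
})

test_that("BCE behaves analytically and rejects non-binary targets", {
  target <- array(c(0, 1), c(4, 4, 1))
  expect_lte(octasyn:::bce_loss(target, target), 1e-6)
  half <- array(0.5, c(4, 4, 1))
  expect_equal(octasyn:::bce_loss(half, target), log(2), tolerance = 1e-12)
  p <- list(x = array(0, c(8, 8, 3)), y = array(0.5, c(8, 8, 1)),
            subject = "s")
  expect_error(octasyn:::prep_pair(p, "direct_segmentation"), "binary")
})

test_that("direct segmentation overfits one pair (BCE strictly decreases)", {
  gspec <- generator_spec(depth = 2, base_filters = 6, max_filters = 24,
                          output_activation = "sigmoid")
  G <- build_generator(gspec, seed = 5)
  pair <- tiny_phantom(3, size = 64)
  x <- normalize_intensity(pair$fundus$pixels[1:32, 1:32, , drop = FALSE])
  y <- pair$vessel_mask$pixels[1:32, 1:32, 1, drop = FALSE]
  opt <- octasyn:::adam_init(G$params)
  losses <- numeric(100)
  for (i in 1:100) {
    fw <- generator_forward(G, x, keep_cache = TRUE)
    losses[i] <- octasyn:::bce_loss(fw$y, y)
    gg <- octasyn:::generator_backward(G, fw$cache,
                                       octasyn:::bce_grad(fw$y, y))
    stp <- octasyn:::adam_step(G$params, gg, opt, 1e-3)
    G$params <- stp$params; opt <- stp$state
  }
  expect_lt(losses[100], losses[1])
  expect_lt(losses[100], 0.5 * losses[1])
})
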
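test_that("degenerate specs are rejected", {
  expect_error(phantom_spec(n_root_vessels = 0), "n_root_vessels")
  expect_error(phantom_spec(radius_decay = 1), "radius_decay")
  expect_error(phantom_spec(radius_decay = 0), "radius_decay")
  expect_error(phantom_spec(min_radius_px = 0), "min_radius_px")
  expect_error(phantom_spec(branch_prob = 1.5), "branch_prob")
  expect_error(phantom_spec(disc_center = c(-5, 10)), "inside")
})

test_that("branching disabled yields exactly the requested unbranched trunks", {
  sp <- phantom_spec(image_size = 128, px_per_mm = 24,
                     disc_center = c(63.5, 63.5), fovea_center = c(8, 8),
                     faz_radius_mm = 0.05, branch_prob = 0,
                     n_root_vessels = 4, seed = 2)
  tree <- grow_vessel_tree(sp)
  expect_true(all(tree$generation == 0))
  expect_equal(sort(unique(tree$root)), 1:4)
  expect_true(all(tree$radius == sp$root_radius_px))
})

test_that("tree growth is deterministic given the seed", {
  sp <- phantom_spec(image_size = 128, px_per_mm = 24, seed = 9)
  expect_identical(as.data.frame(grow_vessel_tree(sp)),
                   as.data.frame(grow_vessel_tree(sp)))
  sp2 <- sp; sp2$seed <- 10L
  expect_false(identical(as.data.frame(grow_vessel_tree(sp)),
                         as.data.frame(grow_vessel_tree(sp2))))
})

test_that("segment radii follow the generation decay law (brute-force walk)", {
  sp <- phantom_spec(image_size = 128, px_per_mm = 24, branch_prob = 0.4,
                     seed = 21)
  tree <- grow_vessel_tree(sp)
  expect_gt(max(tree$generation), 0)
  for (i in seq_len(nrow(tree))) {
    expect_equal(tree$radius[i],
                 sp$root_radius_px * sp$radius_decay^tree$generation[i],
                 tolerance = 1e-12)
    expect_gte(tree$radius[i], sp$min_radius_px)
  }
  # segments stay outside the foveal avascular zone
  faz_px <- sp$faz_radius_mm * sp$px_per_mm
  d_end <- sqrt((tree$r1 - sp$fovea_center[1])^2 +
                (tree$c1 - sp$fovea_center[2])^2)
  expect_true(all(d_end >= faz_px))
})

test_that("an empty tree renders an empty mask and noise-level OCT-A", {
  sp <- phantom_spec(image_size = 64, px_per_mm = 12, seed = 3)
  tree <- grow_vessel_tree(sp)[0, ]
  pair <- render_phantom_pair(tree, sp)
  expect_equal(sum(pair$vessel_mask$pixels), 0)
  expect_lt(mean(pair$octa$pixels), 40)   # background level ~25 with speckle
})

test_that("mask fraction matches the distance-to-segment oracle", {
  sp <- phantom_spec(image_size = 128, px_per_mm = 24, seed = 7)
  tree <- grow_vessel_tree(sp)
  pair <- render_phantom_pair(tree, sp)
  mask <- pair$vessel_mask$pixels[, , 1]
  S <- sp$image_size
  rr <- matrix(0:(S - 1), S, S)
  cc <- matrix(0:(S - 1), S, S, byrow = TRUE)
  inside <- matrix(FALSE, S, S)
  for (i in seq_len(nrow(tree))) {        # naive all-pixel oracle
    dr <- tree$r1[i] - tree$r0[i]; dc <- tree$c1[i] - tree$c0[i]
    L2 <- dr^2 + dc^2
    t <- pmin(1, pmax(0, ((rr - tree$r0[i]) * dr + (cc - tree$c0[i]) * dc) / L2))
    d <- sqrt((rr - tree$r0[i] - t * dr)^2 + (cc - tree$c0[i] - t * dc)^2)
    inside <- inside | (d < tree$radius[i])
  }
  faz_px <- sp$faz_radius_mm * sp$px_per_mm
  inside[(rr - sp$fovea_center[1])^2 + (cc - sp$fovea_center[2])^2 <
           faz_px^2] <- FALSE
  # agree within a +-1 px anti-aliasing band around vessel boundaries
  expect_lt(abs(mean(mask) - mean(inside)), 0.01)
  expect_gt(mean(mask[inside]), 0.95)
})

test_that("OCT-A intensity separates vessel from background on every pair", {
  for (seed in c(1, 12, 33)) {
    pair <- tiny_phantom(seed)
    m <- pair$vessel_mask$pixels[, , 1]
    oc <- pair$octa$pixels[, , 1]
    expect_gt(mean(oc[m == 1]), mean(oc[m == 0]) + 50)
  }
})

test_that("vessel coverage grows with the number of root vessels", {
  fracs <- vapply(c(2, 5, 9), function(n) {
    sp <- phantom_spec(image_size = 128, px_per_mm = 24,
                       n_root_vessels = n, seed = 4)
    mean(render_phantom_pair(grow_vessel_tree(sp), sp)$vessel_mask$pixels)
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
})

test_that("misalignment is recorded as the inverse aligning transform", {
  mis <- similarity_transform(1.04, 5, 2, -1)
  pair <- tiny_phantom(5, misalignment = mis)
  tt <- pair$true_transform
  rt <- compose_transforms(mis, tt)
  expect_equal(rt$scale, 1, tolerance = 1e-10)
  expect_equal(rt$rotation_deg, 0, tolerance = 1e-10)
  expect_equal(c(rt$tx, rt$ty), c(0, 0), tolerance = 1e-10)
})

test_that("dataset generation writes a complete, reproducible manifest", {
  template <- phantom_spec(image_size = 64, px_per_mm = 12)
  d1 <- file.path(tempdir(), "man1"); d2 <- file.path(tempdir(), "man2")
  m1 <- generate_phantom_dataset(d1, 1, seed = 5, template = template)
  expect_length(m1$subjects, 1)
  expect_length(unlist(m1$subjects[[1]]$files), 3)
  expect_true(all(file.exists(
    file.path(d1, unlist(m1$subjects[[1]]$files)))))
  generate_phantom_dataset(d2, 1, seed = 5, template = template)
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))
})

test_that("per-subject seeds are all distinct across a 30-subject cohort", {
  d <- file.path(tempdir(), "man30")
  template <- phantom_spec(image_size = 64, px_per_mm = 12,
                           n_root_vessels = 3)
  m <- generate_phantom_dataset(d, 30, seed = 8, template = template)
  seeds <- vapply(m$subjects, `[[`, numeric(1), "seed")
  expect_length(unique(seeds), 30)
  ids <- vapply(m$subjects, `[[`, character(1), "id")
  expect_length(unique(ids), 30)
})

test_that("images survive the PNG round trip bit-exactly", {
  ds <- tiny_cohort(3, seed = 11)
  s <- ds$subjects[[1]]
  sp <- phantom_spec(image_size = 128, px_per_mm = 24)
  expect_true(all(s$fundus$pixels %in% 0:255))
  expect_true(all(s$mask$pixels %in% c(0, 1)))
  expect_equal(dim(s$fundus$pixels), c(128, 128, 3))
})
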
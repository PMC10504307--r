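small_gspec <- function(...) generator_spec(depth = 2, base_filters = 4,
                                            max_filters = 16, ...)
small_dspec <- function(...) discriminator_spec(n_conv_blocks = 2,
                                                base_filters = 4,
                                                max_filters = 16, ...)

test_that("generator obeys the shape and range contract on random inputs", {
  G <- build_generator(small_gspec(), seed = 1)
  with_seed_test(2, {
    for (i in 1:4) {
      x <- array(runif(32 * 32 * 3, -1, 1), c(32, 32, 3))
      y <- generator_forward(G, x)
      expect_equal(dim(y), c(32, 32, 1))
      expect_true(all(y >= -1 & y <= 1))
    }
  })
})

test_that("builds are deterministic given one seed", {
  x <- with_seed_test(3, array(runif(16 * 16 * 3, -1, 1), c(16, 16, 3)))
  g1 <- generator_forward(build_generator(small_gspec(), seed = 9), x)
  g2 <- generator_forward(build_generator(small_gspec(), seed = 9), x)
  expect_identical(g1, g2)
  g3 <- generator_forward(build_generator(small_gspec(), seed = 10), x)
  expect_false(identical(g1, g3))
  D <- build_discriminator(small_dspec(), seed = 4)
  D2 <- build_discriminator(small_dspec(), seed = 4)
  y <- array(0.1, c(16, 16, 1))
  expect_identical(discriminator_forward(D, x, y),
                   discriminator_forward(D2, x, y))
})

test_that("patch sides must be divisible by 2^depth", {
  G <- build_generator(small_gspec(), seed = 1)
  expect_error(generator_forward(G, array(0, c(30, 30, 3))), "divisible")
})

test_that("parameter count equals the closed-form per-layer sum", {
  spec <- generator_spec(depth = 3, base_filters = 16, filter_growth = 2,
                         max_filters = 1024)
  G <- build_generator(spec, seed = 1)
  # independent arithmetic: conv params = 9 * cin * cout + cout
  conv <- function(cin, cout) 9 * cin * cout + cout
  expected <- conv(3, 16) + conv(16, 32) + conv(32, 64) +       # encoder
    conv(64, 128) +                                             # bottleneck
    conv(128, 64) + conv(128, 64) +                             # up3 + fuse3
    conv(64, 32) + conv(64, 32) +                               # up2 + fuse2
    conv(32, 16) + conv(32, 16) +                               # up1 + fuse1
    conv(16, 1)                                                 # head
  expect_identical(count_parameters(G), expected)
})

test_that("discriminator emits one probability-real scalar", {
  D <- build_discriminator(small_dspec(), seed = 2)
  x <- array(runif(32 * 32 * 3, -1, 1), c(32, 32, 3))
  y <- array(runif(32 * 32, -1, 1), c(32, 32, 1))
  s <- discriminator_forward(D, x, y)
  expect_length(s, 1)
  expect_gt(s, 0); expect_lt(s, 1)
})

test_that("receptive field follows the conv/pool recurrence", {
  # hand-computed: conv3 adds 2*jump, pool adds jump then doubles it
  expect_equal(receptive_field(discriminator_spec(n_conv_blocks = 1)), 4)
  expect_equal(receptive_field(discriminator_spec(n_conv_blocks = 2)), 10)
  expect_equal(receptive_field(discriminator_spec(n_conv_blocks = 3)), 22)
})

test_that("reconstruction loss matches analytic and elementwise values", {
  y <- array(1, c(8, 8, 1)); g <- array(-1, c(8, 8, 1))
  expect_equal(reconstruction_loss(y, y), 0)
  expect_equal(reconstruction_loss(y, g, "l1"), 2)
  expect_equal(reconstruction_loss(y, g, "l2"), 4)
  with_seed_test(5, {
    a <- array(runif(64, -1, 1), c(8, 8, 1))
    b <- array(runif(64, -1, 1), c(8, 8, 1))
    manual_l1 <- sum(abs(a - b)) / 64
    manual_l2 <- sum((a - b)^2) / 64
    expect_equal(reconstruction_loss(a, b, "l1"), manual_l1, tolerance = 1e-14)
    expect_equal(reconstruction_loss(a, b, "l2"), manual_l2, tolerance = 1e-14)
    expect_equal(reconstruction_loss(a, b), reconstruction_loss(b, a))
  })
  expect_error(reconstruction_loss(array(0, c(4, 4, 1)),
                                   array(0, c(5, 5, 1))), "mismatch")
})

test_that("adversarial loss agrees with its closed form", {
  adv <- adversarial_loss(0.5, 0.5)
  expect_equal(adv$game_value, 2 * log(0.5), tolerance = 1e-9)
  expect_equal(adv$l_adv_d, -2 * log(0.5), tolerance = 1e-9)
  expect_equal(adv$l_adv_g, -log(0.5), tolerance = 1e-9)
  # perfect discriminator drives its loss to (nearly) zero
  expect_lt(adversarial_loss(1, 0)$l_adv_d, 1e-6)
  expect_error(adversarial_loss(1.2, 0.5), "\\[0, 1\\]")
  # generator loss falls monotonically as the fake score rises
  grid <- seq(0.01, 0.99, length.out = 100)
  lg <- vapply(grid, function(f) adversarial_loss(0.5, f)$l_adv_g, numeric(1))
  expect_true(all(diff(lg) < 0))
})

test_that("generator objective is affine in lambda with default weight 100", {
  expect_equal(generator_objective(0, 0.7), 0.7)
  expect_equal(generator_objective(0.3, 0.7), 0.7 + 100 * 0.3)
  l_rec <- 0.42; l_adv <- 1.1
  expect_equal(generator_objective(l_rec, l_adv, 200) -
                 generator_objective(l_rec, l_adv, 0), 200 * l_rec)
  expect_error(generator_objective(0.1, 0.1, -1), "nonnegative")
})

test_that("one generator step on a fixed pair lowers its objective", {
  with_seed_test(8, {
    x <- array(runif(32 * 32 * 3, -1, 1), c(32, 32, 3))
    y <- array(runif(32 * 32, -1, 1), c(32, 32, 1))
  })
  G <- build_generator(small_gspec(), seed = 11)
  D <- build_discriminator(small_dspec(), seed = 12)
  objective <- function(G) {
    g_x <- generator_forward(G, x)
    df <- discriminator_forward(D, x, g_x)
    generator_objective(reconstruction_loss(y, g_x),
                        adversarial_loss(0.5, df)$l_adv_g, 100)
  }
  before <- objective(G)
  fw <- generator_forward(G, x, keep_cache = TRUE)
  f2 <- discriminator_forward(D, x, fw$y, keep_cache = TRUE)
  eps <- 1e-7
  fcl <- min(max(f2$score, eps), 1 - eps)
  db <- octasyn:::discriminator_backward(D, f2$cache, -1 / fcl)
  dgx <- db$dy + 100 * octasyn:::reconstruction_grad(y, fw$y)
  gg <- octasyn:::generator_backward(G, fw$cache, dgx)
  stp <- octasyn:::adam_step(G$params, gg, octasyn:::adam_init(G$params), 2e-4)
  G$params <- stp$params
  expect_lt(objective(G), before)
})
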
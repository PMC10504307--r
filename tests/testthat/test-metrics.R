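test_that("mae matches analytic values and an elementwise loop", {
  x <- matrix(runif(64, 0, 255), 8, 8)
  expect_equal(mae(x, x), 0)
  expect_equal(mae(matrix(0, 4, 4), matrix(255, 4, 4)), 255)
  with_seed_test(1, {
    a <- matrix(sample(0:255, 256, TRUE), 16, 16)
    b <- matrix(sample(0:255, 256, TRUE), 16, 16)
  })
  manual <- 0
  for (i in 1:16) for (j in 1:16) manual <- manual + abs(a[i, j] - b[i, j])
  expect_equal(mae(a, b), manual / 256, tolerance = 1e-12)
  expect_equal(mae(a, b), mae(b, a))
  expect_error(mae(a, matrix(0, 4, 4)), "mismatch")
})

test_that("ssim is 1 on identical images and negative under inversion", {
  with_seed_test(2, x <- matrix(sample(0:255, 1024, TRUE), 32, 32))
  expect_equal(ssim(x, x), 1, tolerance = 1e-9)
  expect_lt(ssim(x, 255 - x), 0)
  expect_equal(ssim(x, 255 - x), ssim(255 - x, x))
  expect_error(ssim(matrix(0, 4, 4), matrix(0, 4, 4), window_px = 7),
               "smaller than")
})

test_that("ssim matches a direct window-by-window evaluation", {
  with_seed_test(3, {
    a <- matrix(sample(0:255, 1024, TRUE), 32, 32)
    b <- 0.7 * a + matrix(rnorm(1024, 0, 20), 32, 32)
  })
  w <- 7; c1 <- (0.01 * 255)^2; c2 <- (0.03 * 255)^2
  vals <- c()
  for (i in 1:(32 - w + 1)) for (j in 1:(32 - w + 1)) {
    wa <- a[i:(i + w - 1), j:(j + w - 1)]
    wb <- b[i:(i + w - 1), j:(j + w - 1)]
    va <- var(as.vector(wa)); vb <- var(as.vector(wb))
    cab <- cov(as.vector(wa), as.vector(wb))
    vals <- c(vals, ((2 * mean(wa) * mean(wb) + c1) * (2 * cab + c2)) /
                ((mean(wa)^2 + mean(wb)^2 + c1) * (va + vb + c2)))
  }
  expect_equal(ssim(a, b), mean(vals), tolerance = 1e-8)
})

test_that("cohort synthesis metrics report mean and SD per image", {
  with_seed_test(4, imgs <- lapply(1:4, function(i)
    matrix(sample(0:255, 256, TRUE), 16, 16)))
  res <- synthesis_metrics(imgs, imgs)
  expect_equal(res$per_image$mae, rep(0, 4))
  expect_equal(res$per_image$ssim, rep(1, 4), tolerance = 1e-9)
  expect_equal(res$summary$sd, c(0, 0), tolerance = 1e-9)
})

make_density_tables <- function(n, rho, seed, regions = etdrs_region_names()) {
  with_seed_test(seed, {
    ref <- cand <- NULL
    for (rg in regions) {
      x <- rnorm(n)
      y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
      ids <- sprintf("img%03d", seq_len(n))
      ref <- rbind(ref, data.frame(image_id = ids, region = rg,
                                   density = 50 + 10 * x))
      cand <- rbind(cand, data.frame(image_id = ids, region = rg,
                                     density = 40 + 8 * y))
    }
    list(ref = ref, cand = cand)
  })
}

etdrs_region_names <- function() c("fovea", "superior", "temporal", "nasal",
                                   "inferior")

test_that("identical and affinely related densities correlate perfectly", {
  tabs <- make_density_tables(12, 0.6, seed = 5)
  same <- density_correlations(tabs$ref, tabs$ref)
  expect_true(all(abs(same$pearson_r - 1) < 1e-12))
  expect_true(all(abs(same$spearman_rho - 1) < 1e-12))
  aff <- tabs$ref
  aff$density <- 2 * aff$density + 7
  r <- density_correlations(tabs$ref, aff)
  expect_true(all(abs(r$pearson_r - 1) < 1e-12))
  expect_true(all(r$pearson_sig))
})

test_that("pearson p-values agree with cor.test and spearman equals
           pearson on ranks", {
  tabs <- make_density_tables(15, 0.5, seed = 6)
  res <- density_correlations(tabs$ref, tabs$cand)
  merged <- merge(tabs$ref, tabs$cand, by = c("image_id", "region"))
  for (i in seq_len(nrow(res))) {
    d <- merged[merged$region == res$region[i], ]
    ct <- cor.test(d$density.x, d$density.y)
    expect_equal(res$pearson_r[i], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$pearson_p[i], ct$p.value, tolerance = 1e-10)
    expect_equal(res$spearman_rho[i], cor(rank(d$density.x), rank(d$density.y)),
                 tolerance = 1e-12)
  }
})

test_that("zero-variance densities give undefined correlations", {
  tabs <- make_density_tables(8, 0, seed = 7)
  flat <- tabs$cand
  flat$density <- 33
  res <- density_correlations(tabs$ref, flat)
  expect_true(all(is.na(res$pearson_r)))
  expect_true(all(!res$pearson_sig))
  expect_error(density_correlations(tabs$ref[tabs$ref$image_id == "img001", ],
                                    flat[flat$image_id == "img001", ]),
               "at least 3")
})

test_that("pr curves handle the analytic corner cases", {
  labels <- c(rep(1, 20), rep(0, 80))
  expect_equal(pr_curve(labels, labels)$auc, 1.0)
  flat <- pr_curve(rep(0.5, 100), labels)
  expect_equal(nrow(flat$curve), 1)
  expect_equal(flat$curve$precision, 0.2)      # prevalence
  expect_error(pr_curve(runif(10), rep(1, 10)), "single class")
  expect_error(pr_curve(runif(10), c(rep(0, 9), 0.5)), "binary")
})

test_that("pr curve matches exhaustive confusion-matrix enumeration", {
  with_seed_test(8, {
    scores <- round(runif(500), 2)
    labels <- as.numeric(runif(500) < 0.3)
  })
  pr <- pr_curve(scores, labels)
  P <- sum(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  prec <- rec <- numeric(length(thr))
  for (k in seq_along(thr)) {
    pred <- scores >= thr[k]
    tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
    prec[k] <- tp / (tp + fp); rec[k] <- tp / P
  }
  expect_equal(pr$curve$threshold, thr)
  expect_equal(pr$curve$precision, prec, tolerance = 1e-12)
  expect_equal(pr$curve$recall, rec, tolerance = 1e-12)
  rec2 <- c(0, rec); prec2 <- c(prec[1], prec)
  auc <- sum(diff(rec2) * (prec2[-1] + prec2[-length(prec2)]) / 2)
  expect_equal(pr$auc, auc, tolerance = 1e-12)
})

test_that("random scores drive the PR AUC to the prevalence", {
  with_seed_test(9, {
    labels <- as.numeric(runif(1e5) < 0.25)
    scores <- runif(1e5)
  })
  pr <- pr_curve(scores, labels)
  expect_lt(abs(pr$auc - 0.25), 0.02)
})
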
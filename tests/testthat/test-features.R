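test_that("masks recover a bright disk and stay empty on uniform images", {
  n <- 33L
  disk <- ellipse_fixture(n, 8, 8)
  img <- quick_image(matrix(10, n, n) + 90 * disk)
  m <- compute_mask(img, "rsg", "otsu_threshold")
  # within a 1-pixel boundary band of the true disk
  inner <- ellipse_fixture(n, 7, 7)
  outer <- ellipse_fixture(n, 9, 9)
  expect_true(all(m$pixels[inner]))
  expect_true(!any(m$pixels[!outer]))

  flat <- quick_image(matrix(5, n, n))
  expect_false(any(compute_mask(flat, "rsg")$pixels))

  # hole filling is idempotent
  m1 <- compute_mask(img, "rsg", "morphology_combined")$pixels
  m2 <- EBImage::fillHull(m1 * 1) > 0
  expect_equal(m2, m1)

  # brightfield inversion: dark objects on bright background are foreground
  img_bf <- quick_image(matrix(200, n, n) - 70 * disk)
  mb <- compute_mask(img_bf, "bf")
  expect_true(all(mb$pixels[inner]))
})

test_that("gradient RMS is zero on flat images, blur-monotone and scale-free", {
  n <- 33L
  disk <- 100 * ellipse_fixture(n, 8, 8)
  img <- quick_image(disk + 10)
  mask <- matrix(TRUE, n, n)
  expect_equal(gradient_rms(quick_image(matrix(7, n, n)), "bf", mask), 0)

  sharp <- gradient_rms(img, "bf", mask)
  blurred <- EBImage::filter2(disk + 10, EBImage::makeBrush(19, "Gaussian",
                                                            sigma = 3))
  expect_gt(sharp, gradient_rms(quick_image(blurred), "bf", mask))

  scaled <- quick_image((disk + 10) * 10)
  expect_equal(gradient_rms(scaled, "bf", mask), sharp, tolerance = 1e-12)

  expect_true(is.na(gradient_rms(img, "bf", matrix(FALSE, n, n))))
})

test_that("shape features match analytic oracles and are rotation invariant", {
  sq <- matrix(FALSE, 20, 20)
  sq[6:15, 6:15] <- TRUE
  sf <- shape_features(sq, pixel_size = 1)
  expect_equal(sf$area_um2, 100)
  expect_equal(sf$aspect_ratio, 1.0)

  ell <- ellipse_fixture(51, 20, 5)
  sf2 <- shape_features(ell, pixel_size = 1)
  expect_lt(abs(sf2$aspect_ratio - 0.25), 0.05)
  expect_equal(sf2$major_axis_um, 40, tolerance = 0.05)

  rot <- ellipse_fixture(51, 20, 5, theta = 37 * pi / 180)
  sf3 <- shape_features(rot, pixel_size = 1)
  expect_lt(abs(sf3$aspect_ratio - sf2$aspect_ratio), 0.05)

  expect_true(is.na(shape_features(matrix(FALSE, 5, 5), 1)$area_um2))
})

test_that("co-occurrence statistics match a brute-force oracle", {
  mask4 <- matrix(TRUE, 4, 4)
  # constant image: single co-occurrence cell
  h0 <- haralick_stats(quick_image(matrix(3, 4, 4)), "bf", mask4, 1L, 2L)
  expect_equal(h0$entropy_mean, 0)
  expect_equal(h0$homogeneity_mean, 1)
  expect_equal(h0$entropy_std, 0)

  # checkerboard against the independent loop-based counter
  chk <- matrix(c(0, 1, 0, 1, 1, 0, 1, 0, 0, 1, 0, 1, 1, 0, 1, 0), 4)
  got <- haralick_stats(quick_image(chk), "bf", mask4, 1L, 2L)
  want <- brute_glcm_stats(chk, mask4, 1L, 2L)
  expect_equal(got, want, tolerance = 1e-12)

  # random gray-level images, several granularities and level counts
  set.seed(99)
  for (i in 1:25) {
    m <- matrix(runif(100), 10)
    msk <- matrix(runif(100) > 0.2, 10)
    g <- sample(1:3, 1)
    lv <- sample(c(4L, 8L, 16L), 1)
    got <- haralick_stats(quick_image(m), "bf", msk, g, lv)
    want <- brute_glcm_stats(m, msk, g, lv)
    if (is.null(want)) {
      expect_true(is.na(got$entropy_mean))
    } else {
      expect_equal(got, want, tolerance = 1e-12)
    }
  }

  # mask too small for the offset -> sentinel
  tiny <- matrix(FALSE, 4, 4); tiny[1, 1] <- TRUE; tiny[4, 4] <- TRUE
  expect_true(is.na(haralick_stats(quick_image(chk), "bf", tiny, 1L,
                                   2L)$entropy_mean))
})

test_that("entropy does not decrease when independent noise is added", {
  set.seed(7)
  mask <- matrix(TRUE, 16, 16)
  base <- matrix(rep(seq(0, 1, length.out = 16), each = 16), 16)
  d <- vapply(1:100, function(i) {
    noisy <- base + matrix(rnorm(256, 0, 0.3), 16)
    h1 <- haralick_stats(quick_image(base), "bf", mask, 1L, 8L)$entropy_mean
    h2 <- haralick_stats(quick_image(noisy), "bf", mask, 1L, 8L)$entropy_mean
    h2 - h1
  }, numeric(1))
  expect_gt(mean(d), 0)
})

test_that("intensity-weighted major axis responds to weight placement", {
  ell <- ellipse_fixture(41, 15, 5)
  uni <- quick_image(ell * 1.0)
  sf <- shape_features(ell, pixel_size = 1)
  expect_equal(major_axis_intensity(uni, "bf", ell, 1), sf$major_axis_um,
               tolerance = 1e-6)

  # intensity concentrated at the rod ends stretches the weighted axis
  x <- abs(matrix(rep(seq_len(41), each = 41), 41) - 21)
  ends <- quick_image(ell * (0.05 + x^2))
  expect_gt(major_axis_intensity(ends, "bf", ell, 1), sf$major_axis_um)

  # invariant under intensity scaling
  expect_equal(major_axis_intensity(quick_image(ell * 50), "bf", ell, 1),
               major_axis_intensity(uni, "bf", ell, 1), tolerance = 1e-12)

  expect_true(is.na(major_axis_intensity(quick_image(ell * 0), "bf", ell, 1)))
})

test_that("channel intensity subtracts background and closes the render loop", {
  n <- 33L
  disk <- ellipse_fixture(n, 6, 6)
  img <- quick_image(disk * 2.5 + 7)
  expect_equal(channel_intensity(img, "bf", disk), 2.5 * sum(disk))
  # constant offset leaves the value unchanged
  img2 <- quick_image(disk * 2.5 + 107)
  expect_equal(channel_intensity(img2, "bf", disk),
               channel_intensity(img, "bf", disk))
  expect_equal(channel_intensity(quick_image(matrix(0, n, n)), "bf", disk), 0)
  expect_equal(channel_intensity(img, "bf", matrix(FALSE, n, n)), 0)

  # rendered events: extracted intensity recovers the generator value
  shape <- shape_spec()
  err <- vapply(1:100, function(i) {
    total <- runif(1, 1000, 5000)
    rec <- list(true_label = "active", rsg_intensity = total,
                pi_intensity = 10)
    img <- render_event_image(rec, shape, seed = i + 400L)
    feats <- extract_features(img)
    feats$rsg_intensity / total - 1
  }, numeric(1))
  expect_lt(max(abs(err)), 0.05)
})

test_that("extract_features returns the full canonical schema", {
  rec <- list(true_label = "active", rsg_intensity = 2000, pi_intensity = 15)
  feats <- extract_features(render_event_image(rec, shape_spec(), seed = 8L))
  expect_true(all(feature_columns() %in% names(feats)))
  expect_true(all(vapply(feats, is.finite, logical(1))))
  expect_gt(feats$aspect_ratio, 0)
  expect_lte(feats$aspect_ratio, 1)
})
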
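# Segmentation operations against brute-force oracles and their contracts.

test_that("to_grayscale handles identity, uniform and hand-computed cases", {
  img <- random_image(4, 4, seed = 2)
  expect_equal(to_grayscale(img, c(1, 0, 0)), img[, , 1])
  uni <- array(77, dim = c(3, 3, 3))
  expect_equal(to_grayscale(uni, c(0.2, 0.5, 0.3)), matrix(77, 3, 3))
  px <- array(c(10, 200, 30, 40,   # R
                20, 100, 60, 80,   # G
                30, 50, 90, 120),  # B
              dim = c(2, 2, 3))
  w <- c(0.299, 0.587, 0.114)
  manual <- round(w[1] * px[, , 1] + w[2] * px[, , 2] + w[3] * px[, , 3])
  expect_equal(to_grayscale(px, w), manual)
  expect_error(to_grayscale(img, c(0, 0, 0)), class = "invalid_parameter")
  expect_error(to_grayscale(img, c(-1, 1, 1)), class = "invalid_parameter")
})

test_that("median_filter removes salt noise and matches the brute-force oracle", {
  uni <- matrix(42, 6, 6)
  expect_equal(median_filter(uni, 3), uni)
  salt <- matrix(0, 7, 7); salt[4, 4] <- 255
  expect_equal(median_filter(salt, 3), matrix(0, 7, 7))
  for (seed in 1:3) {
    img <- random_gray(5, 5, seed = seed)
    expect_equal(median_filter(img, 3), median_oracle(img, 3))
  }
  img <- random_gray(9, 9, seed = 4)
  expect_equal(median_filter(img, 5), median_oracle(img, 5))
  expect_error(median_filter(img, 4), class = "invalid_parameter")
})

test_that("median_filter is idempotent on uniform images and range-bounded", {
  for (seed in 1:5) {
    img <- random_gray(8, 8, seed = seed)
    out <- median_filter(img, 3)
    expect_true(min(out) >= min(img) && max(out) <= max(img))
    expect_equal(median_filter(matrix(seed, 5, 5), 3), matrix(seed, 5, 5))
  }
})

test_that("gray_histogram counts levels correctly", {
  expect_equal(unname(gray_histogram(matrix(7, 3, 3))[8]), 1)
  h <- gray_histogram(matrix(c(0, 0, 255, 255), 2, 2))
  expect_equal(unname(h[c(1, 256)]), c(0.5, 0.5))
  img <- random_gray(8, 8, seed = 5)
  h <- gray_histogram(img)
  counts <- vapply(0:255, function(l) sum(img == l), numeric(1))
  expect_equal(as.numeric(h), counts / 64)
  expect_equal(sum(h), 1, tolerance = 1e-12)
})

test_that("otsu_threshold reproduces the closed-form two-level solution", {
  p <- numeric(256); p[51] <- 0.5; p[201] <- 0.5
  ot <- otsu_threshold(p)
  expect_true(ot$threshold >= 50 && ot$threshold <= 199)
  expect_equal(max(ot$criterion, na.rm = TRUE), 0.25 * 150^2)
  expect_equal(ot$class_stats$omega1 + ot$class_stats$omega2, 1, tolerance = 1e-12)
  expect_error(otsu_threshold(c(1, numeric(255))), class = "degenerate_input")
})

test_that("otsu_threshold matches the exhaustive oracle and its identities hold", {
  for (seed in 1:25) {
    p <- random_histogram(seed)
    ot <- otsu_threshold(p)
    orc <- otsu_oracle(p)
    expect_equal(ot$criterion[ot$threshold + 1], orc$g, tolerance = 1e-12)
    # both algebraic forms agree for every candidate threshold
    expect_lt(max(abs(otsu_criterion(p, "product") -
                        otsu_criterion(p, "decomposed")), na.rm = TRUE), 1e-9)
    # omega1 + omega2 = 1 and the mean decomposition at the optimum
    cs <- ot$class_stats
    expect_equal(cs$omega1 + cs$omega2, 1, tolerance = 1e-12)
    expect_equal(cs$omega1 * cs$mu1 + cs$omega2 * cs$mu2, cs$mu, tolerance = 1e-9)
  }
})

test_that("binarize partitions pixels consistently with the histogram classes", {
  expect_false(any(binarize(matrix(10, 3, 3), 10)))
  expect_equal(sum(binarize(matrix(c(0, 0, 255, 255), 2, 2), 100)), 2)
  img <- random_gray(8, 8, seed = 6)
  ot <- otsu_threshold(gray_histogram(img))
  mask <- binarize(img, ot$threshold)
  expect_equal(mean(mask), unname(ot$class_stats$omega2), tolerance = 1e-12)
  expect_equal(mean(img[mask]), unname(ot$class_stats$mu2), tolerance = 1e-9)
})

test_that("morphological_clean removes specks, fills holes, and radius 0 is identity", {
  m <- matrix(FALSE, 12, 12); m[3:10, 3:10] <- TRUE
  expect_identical(morphological_clean(m, 0), m)
  speck <- matrix(FALSE, 9, 9); speck[5, 5] <- TRUE
  expect_false(any(morphological_clean(speck, 1)))
  holed <- m; holed[6, 6] <- FALSE
  expect_true(all(morphological_clean(holed, 1)[4:9, 4:9]))
})

test_that("label_components separates and orders blobs", {
  m <- matrix(FALSE, 10, 10)
  m[2:3, 2:3] <- TRUE; m[7:9, 6:9] <- TRUE
  lab <- label_components(m)
  expect_equal(max(lab), 2)
  expect_true(all(lab[2:3, 2:3] == 1))
  expect_true(all(lab[7:9, 6:9] == 2))
  expect_equal(max(label_components(matrix(FALSE, 3, 3))), 0)
})

test_that("extract_rainbow recovers the patch and keeps its output contract", {
  sc <- make_rainbow_image(scene_spec(noise_sd = 0, sp_rate = 0))
  p <- extract_rainbow(sc$image)
  expect_s3_class(p, "rainbow_patch")
  expect_equal(dim(p$pixels), c(100, 100, 3))
  expect_true(all(abs(p$source_bbox - sc$bbox) <= 2))
  # two symmetric patches -> exactly one comes back (the leftmost)
  sc2 <- make_rainbow_image(scene_spec(n_patches = 2, noise_sd = 0, sp_rate = 0))
  p2 <- extract_rainbow(sc2$image)
  expect_true(all(abs(p2$source_bbox - sc2$bbox) <= 2))
  expect_error(extract_rainbow(array(0, c(30, 30, 3))),
               class = "segmentation_failure")
  # output is 100x100x3 regardless of input size
  sc3 <- make_rainbow_image(scene_spec(width = 220, height = 160,
                                       center = c(80, 70), axes = c(60, 20),
                                       noise_sd = 0, sp_rate = 0))
  expect_equal(dim(extract_rainbow(sc3$image)$pixels), c(100, 100, 3))
})
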
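test_that("background threshold separates strokes from a noisy paper mode", {
  set.seed(1)
  px <- matrix(pmin(pmax(round(rnorm(200 * 300, 240, 3)), 0), 255), 200, 300)
  px[100:110, 50:250] <- 30
  img <- gray_image(px)
  t <- estimate_background_threshold(img)
  expect_gte(t, 60)
  expect_lte(t, 230)
  expect_true(all(px[100:110, 50:250] < t))

  # all-white image: a threshold exists but captures nothing
  t2 <- estimate_background_threshold(gray_image(matrix(255, 10, 10)))
  expect_lt(t2, 255)
  expect_equal(sum(matrix(255, 10, 10) < t2), 0L)

  expect_error(estimate_background_threshold(gray_image(matrix(0, 10, 10))),
               class = "lastkit_validation_error")
})

test_that("binarize_and_clean opens away speckle and is monotone in t", {
  px <- matrix(255, 40, 40)
  px[20, 20] <- 0                       # isolated speckle
  px[5:9, 5:30] <- 30                   # 5-px stroke
  img <- gray_image(px)
  bin <- binarize_and_clean(img, t = 128, opening_radius = 1)
  expect_false(bin$mask[20, 20])        # speckle removed
  expect_true(all(bin$mask[6:8, 7:28])) # stroke interior preserved
  # radius 0 is pure thresholding
  bin0 <- binarize_and_clean(img, t = 128, opening_radius = 0)
  expect_equal(bin0$mask, px < 128)
  # opening result is a subset of the raw mask
  expect_true(all(!bin$mask | bin0$mask))
  # monotone in t
  set.seed(2)
  px2 <- matrix(runif(900, 0, 255), 30, 30)
  img2 <- gray_image(px2)
  m1 <- binarize_and_clean(img2, t = 80, opening_radius = 0)$mask
  m2 <- binarize_and_clean(img2, t = 160, opening_radius = 0)$mask
  expect_true(all(!m1 | m2))
})

test_that("skeletonization thins to ~1 px and preserves topology", {
  bar <- matrix(FALSE, 10, 30)
  bar[4:6, 3:28] <- TRUE
  sk <- skeletonize_mask(bar)
  expect_true(all(colSums(sk$mask[, 5:26]) == 1))   # single-pixel path
  expect_true(all(!sk$mask | bar))                  # subset of input

  two <- matrix(FALSE, 20, 20)
  two[3:6, 3:6] <- TRUE
  two[12:16, 12:16] <- TRUE
  sk2 <- skeletonize_mask(two)
  expect_equal(max(lastkit:::label_components(sk2$mask)), 2L)

  single <- matrix(FALSE, 5, 5)
  single[3, 3] <- TRUE
  expect_equal(skeletonize_mask(single)$mask, single)

  expect_error(skeletonize_mask(matrix(FALSE, 5, 5)),
               class = "lastkit_validation_error")
})

test_that("component labelling is 8-connected", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE; m[3, 3] <- TRUE   # diagonal chain
  m[5, 5] <- TRUE
  lab <- lastkit:::label_components(m)
  expect_equal(max(lab), 2L)
  expect_equal(lab[1, 1], lab[2, 2])
})

test_that("signal form takes the upper envelope with flagged gap interpolation", {
  # horizontal line at row 4 of a 10-row image: y = 10 - 1 - 3 = 6
  m <- matrix(FALSE, 10, 20)
  m[4, 3:18] <- TRUE
  sf <- to_signal_form(m)
  expect_equal(nrow(sf), 16L)
  expect_true(all(sf$y == 6))
  expect_false(any(sf$gap))
  expect_equal(sf$x, 2:17)

  # column with pixels at two rows takes the upper one
  m2 <- matrix(FALSE, 50, 5)
  m2[10, 1:5] <- TRUE
  m2[40, 3] <- TRUE
  sf2 <- to_signal_form(m2)
  expect_equal(sf2$y[3], 50 - 1 - 9)

  # gap column is interpolated and flagged
  m3 <- matrix(FALSE, 10, 7)
  m3[3, c(1, 2, 5, 6, 7)] <- TRUE
  sf3 <- to_signal_form(m3)
  expect_equal(sf3$gap, c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(sf3$y, rep(7, 7))

  # tent-shaped stroke gives a piecewise-linear tent with one maximum
  tm <- tent_mask(w = 41L, h = 30L, t = 1L)
  sft <- to_signal_form(tm)
  expect_equal(which.max(sft$y), 21L)
  expect_lt(max(abs(sft$y - (30 - 1) * (1 - abs(sft$x - 20) / 20) -
                      min(sft$y))), 3)
})

test_that("noise-free preprocessing reproduces the generator envelope", {
  scan <- render_series(small_spec(seed = 2))
  pre <- preprocess_scan(scan$image)
  env <- scan$truth$envelope
  both <- dplyr::inner_join(pre$signal, env, by = "x",
                            suffix = c("_got", "_true"))
  # envelope heights are measured from different origins (page rows vs
  # baseline); compare after removing the constant offset
  off <- stats::median(both$y_got - both$y_true)
  err <- abs(both$y_got - both$y_true - off)
  expect_lt(stats::quantile(err[!both$gap], 0.99),
            scan$truth$spec$stroke_width + 1)
})
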
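test_that("straightening recovers rotated character dimensions", {
  block <- matrix(TRUE, 41, 101)
  st0 <- straighten(block)
  expect_equal(st0$angle, 0, tolerance = 0.5)
  expect_equal(dim(st0$mask), dim(block))

  rot <- lastkit:::rotate_mask(block, 15)
  st <- straighten(rot)
  expect_equal(st$angle, 15, tolerance = 1)
  expect_lt(abs(ncol(st$mask) - 101) / 101, 0.05)
  expect_lt(abs(nrow(st$mask) - 41) / 41, 0.05)

  # a disk is isotropic: rotation angle 0 by convention
  n <- 41
  disk <- outer(seq_len(n), seq_len(n),
                function(r, c) (r - 21)^2 + (c - 21)^2 <= 15^2)
  expect_equal(straighten(disk)$angle, 0)
})

test_that("character features match analytic values on ideal shapes", {
  w <- 60L; h <- 50L; t <- 3L
  roi <- character_roi(open_rect_mask(w, h, t), c(0L, w, 0L, h))
  cs <- plateau_signal(w, h)
  f <- character_features(roi, cs, "R")
  expect_equal(unname(f["width"]), w)
  expect_equal(unname(f["height"]), h)
  expect_equal(unname(f["area"]), sum(roi$mask))
  expect_gt(f["amp_frac"], 0.9)
  expect_lt(abs(f["angle"]), 5)
  expect_gte(f["convex_hull_area"], 0.9 * (w - 1) * (h - 1))

  # tent signal arc length: two slanted sides of an ideal triangle
  wt <- 61L; ht <- 50
  tri_roi <- character_roi(tent_mask(wt, ht, 2L), c(0L, wt, 0L, ht))
  tcs <- tent_signal(wt, ht)
  ft <- character_features(tri_roi, tcs, "T")
  analytic <- 2 * sqrt(((wt - 1) / 2)^2 + ht^2)
  expect_equal(unname(ft["signal_length"]), analytic, tolerance = 0.05)

  # a character identical to its perfect template has dtw_model = 0
  tmpl <- artificial_templates("T", 100L)[[1]]
  ident <- character_signal(tmpl, 0L, 100L)
  fi <- character_features(tri_roi, ident, "T")
  expect_equal(unname(fi["dtw_model"]), 0, tolerance = 1e-9)
})

test_that("template normalization divides spatial features only", {
  roi <- character_roi(open_rect_mask(60L, 50L, 3L), c(0L, 60L, 0L, 50L))
  f <- character_features(roi, plateau_signal(60L, 50), "R")
  n1 <- normalize_to_template(f, f)
  spatial <- c("width", "height", "width_s", "height_s", "area",
               "convex_hull_area", "long_axis", "short_axis", "signal_length")
  expect_equal(unname(n1[paste0(spatial, "_n")]), rep(1, length(spatial)))
  f2 <- f
  f2["width"] <- 2 * f["width"]
  expect_equal(unname(normalize_to_template(f2, f)["width_n"]), 2)
  bad <- f; bad["area"] <- 0
  expect_error(normalize_to_template(f, bad),
               class = "lastkit_validation_error")
})

test_that("NW coefficient reproduces worked values and the LCS identity", {
  expect_equal(nw_coefficient("RTRTRT", "RTRTRT"), 100)
  expect_equal(nw_coefficient("RTTTRT", "RTRTRT"), 5 / 6 * 100)
  expect_equal(nw_coefficient("RRRRRR", "RTRTRT"), 50)
  expect_error(nw_coefficient("R", character(0)),
               class = "lastkit_validation_error")

  # with m=1, p=g=0 the NW score is the LCS length
  set.seed(51)
  for (i in 1:300) {
    n <- sample(1:8, 1)
    e <- sample(c("R", "T"), n, replace = TRUE)
    g <- sample(c("R", "T"), n, replace = TRUE)
    expect_identical(nw_coefficient(e, g), lcs_length(e, g) / n * 100)
  }

  # monotone non-increasing in the number of substitutions
  g <- rep(c("R", "T"), 6)
  prev <- 100
  e <- g
  for (k in c(2, 5, 8, 11)) {
    e[k] <- if (e[k] == "R") "T" else "R"
    now <- nw_coefficient(e, g)
    expect_lte(now, prev + 1e-9)
    prev <- now
  }

  # bounded in [0, 100] for m > 0 >= p, g
  set.seed(52)
  for (i in 1:50) {
    e <- sample(c("R", "T"), 7, replace = TRUE)
    g <- sample(c("R", "T"), 7, replace = TRUE)
    v <- nw_coefficient(e, g, m = 2, p = -1, gap = -1)
    expect_gte(v, 0); expect_lte(v, 100)
  }
})

test_that("series aggregation computes width ratios, MED/IQR and NW", {
  mk <- function(x0, w, label, index, examiner = FALSE) {
    roi <- character_roi(matrix(TRUE, 30, w), c(x0, x0 + w, 0L, 30L),
                         index = index, examiner = examiner)
    cs <- if (label == "R") plateau_signal(w, 30) else tent_signal(w, 30)
    cs$x0 <- x0; cs$x1 <- x0 + w
    list(roi = roi, cs = cs, f = character_features(roi, cs, label))
  }
  # examiner R template + examiner T template, then 3R + 3T examinee,
  # equal widths, gap-free
  labels <- c("R", "T", "R", "T", "R", "T", "R", "T")
  examiner <- c(TRUE, TRUE, rep(FALSE, 6))
  w <- 40L
  parts <- lapply(seq_along(labels), function(i) {
    mk((i - 1L) * w, w, labels[i], i - 1L, examiner[i])
  })
  rec <- series_features(lapply(parts, `[[`, "f"), labels, examiner,
                         lapply(parts, `[[`, "roi"), subject = "X")
  expect_equal(rec$width_ratio_rect, 50)
  expect_equal(rec$width_ratio_tri, 50)
  expect_equal(rec$nw, 100)
  expect_equal(rec$n_characters, 6L)
  expect_equal(rec$aggregates$rect_MED_width_n, 1)

  # all-rectangle series: triangle aggregates are missing-flagged
  labels_r <- c("R", "T", rep("R", 4))
  parts_r <- lapply(seq_along(labels_r), function(i) {
    mk((i - 1L) * w, w, labels_r[i], i - 1L, i <= 2)
  })
  rec_r <- series_features(lapply(parts_r, `[[`, "f"), labels_r,
                           c(TRUE, TRUE, rep(FALSE, 4)),
                           lapply(parts_r, `[[`, "roi"))
  expect_gt(rec_r$width_ratio_rect, 99)
  expect_true(is.na(rec_r$aggregates$tri_MED_width))

  # single examinee character: MED is the value, IQR missing
  parts_1 <- lapply(1:3, function(i) mk((i - 1L) * w, w,
                                        c("R", "T", "R")[i], i - 1L, i <= 2))
  rec_1 <- series_features(lapply(parts_1, `[[`, "f"), c("R", "T", "R"),
                           c(TRUE, TRUE, FALSE),
                           lapply(parts_1, `[[`, "roi"))
  expect_equal(rec_1$aggregates$rect_MED_width, 40)
  expect_true(is.na(rec_1$aggregates$rect_IQR_width))

  # MED/IQR are permutation-invariant: shuffle examinee character order
  ord <- c(1, 2, 5, 7, 3, 8, 4, 6)
  rec_p <- series_features(lapply(parts, `[[`, "f")[ord], labels[ord],
                           examiner[ord], lapply(parts, `[[`, "roi")[ord])
  expect_equal(rec_p$aggregates, rec$aggregates)
})

test_that("normalized features are invariant to uniform scan rescaling", {
  mk <- function(scale) {
    w <- as.integer(40 * scale); h <- as.integer(30 * scale)
    roi <- character_roi(matrix(TRUE, h, w), c(0L, w, 0L, h))
    cs <- plateau_signal(w, h)
    character_features(roi, cs, "R")
  }
  f1 <- mk(1); f2 <- mk(2)
  n1 <- normalize_to_template(f1, f1)
  n2 <- normalize_to_template(f2, f2)
  idx <- grepl("_n$", names(n1))
  expect_equal(n1[idx], n2[idx], tolerance = 1e-9)
})
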
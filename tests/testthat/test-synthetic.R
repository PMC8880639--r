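test_that("rendering is deterministic and respects the label contract", {
  s1 <- render_series(small_spec(seed = 3))
  s2 <- render_series(small_spec(seed = 3))
  expect_identical(s1$image$pixels, s2$image$pixels)
  expect_identical(s1$truth$labels, s2$truth$labels)

  # no perseveration: strictly alternating after the examiner prefix
  lab <- s1$truth$labels
  expect_true(all(lab[-1] != lab[-length(lab)]))

  # full perseveration: every examinee character repeats the first one
  sp <- small_spec(seed = 5, p_perseveration = 1)
  st <- render_series(sp)
  ex <- st$truth$labels[(sp$examiner_n + 1):length(st$truth$labels)]
  expect_true(all(ex == st$truth$labels[sp$examiner_n]))

  expect_equal(length(s1$truth$labels), 3L + 4L)
})

test_that("page overflow and invalid parameters are rejected", {
  expect_error(render_series(small_spec(seed = 1, page_width = 100L)),
               class = "lastkit_validation_error")
  expect_error(synthetic_spec(micrographia_rate = 0),
               class = "lastkit_validation_error")
  expect_error(synthetic_spec(p_perseveration = 2),
               class = "lastkit_validation_error")
})

test_that("truth masks are disjoint and near their analytic boxes", {
  scan <- render_series(small_spec(seed = 8, skew_sd = 4))
  rois <- scan$truth$rois
  # masks are pairwise disjoint by construction of ownership; check bboxes
  # stay within a stroke width of the analytic polyline boxes
  sw <- scan$truth$spec$stroke_width
  bb <- scan$truth$analytic_bbox
  for (i in seq_along(rois)) {
    got_x0 <- rois[[i]]$bbox[1]
    expect_lt(abs(got_x0 - bb[i, 1]), sw + 1)
    got_x1 <- rois[[i]]$bbox[2]
    expect_lt(abs(got_x1 - bb[i, 2]), sw + 1)
  }
  # disjointness on the page
  page <- matrix(0L, nrow(scan$image$pixels), ncol(scan$image$pixels))
  for (r in rois) {
    rows <- (r$bbox[3] + 1):r$bbox[4]
    cols <- (r$bbox[1] + 1):r$bbox[2]
    blk <- page[rows, cols]
    expect_true(all(blk[r$mask] == 0L))
    blk[r$mask] <- 1L
    page[rows, cols] <- blk
  }
})

test_that("perseveration lowers the NW coefficient in expectation", {
  mean_nw <- function(p, seeds = 15) {
    vals <- vapply(seeds * 100 + seq_len(seeds), function(s) {
      sp <- synthetic_spec(n_chars = 12L, examiner_n = 5L,
                           p_perseveration = p, seed = s)
      set.seed(sp$seed)
      # reproduce only the label machinery via the renderer truth
      lab <- render_series(utils::modifyList(sp, list(
        char_width_mean = 40, char_height_mean = 30, stroke_width = 2,
        noise_sd = 0, speckle_rate = 0)))$truth$labels
      ex <- lab[6:17]
      first <- if (lab[5] == "R") "T" else "R"
      nw_coefficient(ex, ideal_alternation(first, 12L))
    }, numeric(1))
    mean(vals)
  }
  m0 <- mean_nw(0)
  m2 <- mean_nw(0.2)
  m5 <- mean_nw(0.5)
  expect_equal(m0, 100)
  expect_gt(m0, m2)
  expect_gt(m2, m5)
})

test_that("perseveration count matches its binomial expectation", {
  p <- 0.3; n <- 12L
  count_nonalt <- function(seed) {
    sp <- synthetic_spec(n_chars = n, examiner_n = 5L, p_perseveration = p,
                         char_width_mean = 40, char_height_mean = 30,
                         stroke_width = 2, noise_sd = 0, speckle_rate = 0,
                         seed = seed)
    lab <- render_series(sp)$truth$labels
    full <- lab[5:17]
    sum(full[-1] == full[-length(full)])
  }
  counts <- vapply(1:200, count_nonalt, numeric(1))
  expect_lt(abs(mean(counts) - p * n), 0.3)
})

test_that("cohorts carry per-group presets and exact bookkeeping", {
  ch <- cohort(n_per_group = c(5, 5, 5), seed = 11)
  expect_equal(nrow(ch), 15L)
  expect_equal(as.integer(table(ch$group)), c(5L, 5L, 5L))
  expect_equal(anyDuplicated(vapply(ch$spec, function(s) s$seed, numeric(1))), 0L)
  pd <- ch$spec[[which(ch$group == "PD")[1]]]
  expect_lt(pd$char_width_mean, 120)
  expect_lt(pd$micrographia_rate, 1)
  psp <- ch$spec[[which(ch$group == "PSP")[1]]]
  expect_gt(psp$p_perseveration, 0.1)
})

test_that("synthetic scans round-trip through the scan reader", {
  scan <- render_series(small_spec(seed = 12, noise_sd = 2,
                                   speckle_rate = 1e-4))
  d <- withr::local_tempdir()
  paths <- write_synthetic_scan(scan, d)
  img <- load_scan(paths["scan"])
  expect_equal(img$pixels, scan$image$pixels)
  meta <- load_sidecar(paths["sidecar"])
  expect_equal(meta$examiner_n, 3L)
  ov <- load_label_overlay(paths["overlay"], img, examiner_n = meta$examiner_n)
  expect_equal(ov$labels, scan$truth$labels)
})
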
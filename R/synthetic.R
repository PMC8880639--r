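# Synthetic LAST scan generator. Renders a left-to-right series of connected
# open rectangles and triangles with exact ground truth (per-character
# masks, labels, envelope), emulating pencil-stroke width, scanner noise and
# speckle, slow baseline drift, per-character size jitter and slant,
# progressive size decay (micrographia) and perseveration errors.

#' Parametrize the synthetic scan generator
#'
#' Defaults emulate a well-executed series at 600 dpi: 5-mm-scale characters
#' (120 x 100 px), moderate pencil width, light scanner noise and a slow
#' sinusoidal drift. Characters are joined at shared baseline nodes — the
#' test is drawn without lifting the pencil — so segmentation is genuinely
#' exercised. Character slant is modelled as a horizontal shear, which keeps
#' the shared baseline nodes on the baseline (as a leaning pen stroke does).
#'
#' @param n_chars Examinee characters (default 12).
#' @param examiner_n Leading examiner characters (default 5).
#' @param char_width_mean,char_height_mean Mean character size in px.
#' @param width_jitter_sd,height_jitter_sd Per-character size jitter SD (px).
#' @param gap_mean Length in px of the baseline connector stroke the pen
#'   draws between consecutive shapes (default 3). The connector is what
#'   makes the signal form dip to the baseline between characters.
#' @param stroke_width Pencil stroke width in px.
#' @param noise_sd Gaussian background noise SD in gray levels.
#' @param speckle_rate Fraction of pixels hit by dark scanner speckle.
#' @param drift_amplitude,drift_period Sinusoidal baseline drift amplitude
#'   (px) and period (px; 0 = one period across the series).
#' @param micrographia_rate Per-character multiplicative size decay applied
#'   to examinee characters (1 = none; values below 1 shrink the series
#'   progressively).
#' @param p_perseveration Probability that an examinee character repeats the
#'   previous shape instead of alternating.
#' @param skew_sd Per-character slant SD in degrees (horizontal shear).
#' @param dpi Nominal scan resolution.
#' @param page_width Optional fixed page width in px; the series must fit.
#' @param seed RNG seed; rendering is deterministic given the spec.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_chars = 12L, examiner_n = 5L,
                           char_width_mean = 120, char_height_mean = 100,
                           width_jitter_sd = 3, height_jitter_sd = 3,
                           gap_mean = 3, stroke_width = 4,
                           noise_sd = 4, speckle_rate = 1e-4,
                           drift_amplitude = 5, drift_period = 0,
                           micrographia_rate = 1.0,
                           p_perseveration = 0, skew_sd = 1.5,
                           dpi = 600, page_width = NULL, seed = 1L) {
  if (n_chars < 1L || examiner_n < 0L) stop_validation("need at least one examinee character")
  if (char_width_mean <= 0 || char_height_mean <= 0 || stroke_width <= 0) {
    stop_validation("sizes must be positive")
  }
  if (p_perseveration < 0 || p_perseveration > 1 || speckle_rate < 0 ||
      speckle_rate > 1) {
    stop_validation("probabilities must lie in [0, 1]")
  }
  if (micrographia_rate <= 0 || micrographia_rate > 1) {
    stop_validation("micrographia_rate must lie in (0, 1]")
  }
  structure(as.list(environment()), class = "synthetic_spec")
}

# Group presets for cohort simulation. Controls draw regular, well-sized
# alternating series; the PD phenotype is smaller characters with reduced
# variability and progressive diminution (micrographia); the PSP phenotype
# is perseveration-prone with irregular sizing and slant.
preset_overrides <- list(
  control = list(),
  pd = list(char_width_mean = 85, char_height_mean = 70,
            width_jitter_sd = 2, height_jitter_sd = 2,
            micrographia_rate = 0.985, p_perseveration = 0.06,
            skew_sd = 2),
  psp = list(char_width_mean = 125, char_height_mean = 105,
             width_jitter_sd = 14, height_jitter_sd = 14,
             p_perseveration = 0.28, skew_sd = 5)
)

#' A preset generator spec for one study group
#'
#' @param preset `"control"`, `"pd"` or `"psp"`.
#' @param ... Overrides passed on to [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
preset_spec <- function(preset = c("control", "pd", "psp"), ...) {
  preset <- match.arg(preset)
  args <- utils::modifyList(preset_overrides[[preset]], list(...))
  do.call(synthetic_spec, args)
}

# Vertex polyline of one character in local coordinates (baseline y = 0).
shape_polyline <- function(shape, w, h) {
  if (shape == "R") {
    rbind(c(0, 0), c(0, h), c(w, h), c(w, 0))
  } else {
    rbind(c(0, 0), c(w / 2, h), c(w, 0))
  }
}

#' Render a synthetic LAST scan with ground truth
#'
#' Draws the examiner prefix (alternating, starting with a rectangle)
#' followed by the examinee continuation with perseveration substitutions,
#' applies jitter/shear/micrographia per character and a global sinusoidal
#' drift, rasterizes at the stroke width and adds Gaussian noise plus dark
#' speckle. The overlay and truth are exact by construction.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_scan` with `image` ([gray_image()]),
#'   `overlay` (RGB array, rectangle strokes red, triangle strokes blue) and
#'   `truth` (labels, per-character [character_roi()] masks, ideal envelope
#'   tibble, spec echo).
#' @export
render_series <- function(spec) {
  set.seed(spec$seed)
  n_total <- spec$examiner_n + spec$n_chars
  labels <- character(n_total)
  if (spec$examiner_n > 0L) {
    labels[seq_len(spec$examiner_n)] <- rep(c("R", "T"),
                                            length.out = spec$examiner_n)
  }
  pers <- runif(spec$n_chars) < spec$p_perseveration
  for (k in seq_len(spec$n_chars)) {
    i <- spec$examiner_n + k
    prev <- if (i > 1L) labels[i - 1L] else "T"
    expected <- if (prev == "R") "T" else "R"
    labels[i] <- if (pers[k]) prev else expected
  }
  widths <- heights <- shears <- numeric(n_total)
  for (i in seq_len(n_total)) {
    if (i <= spec$examiner_n) {
      widths[i] <- spec$char_width_mean + rnorm(1, 0, 2)
      heights[i] <- spec$char_height_mean + rnorm(1, 0, 2)
      shears[i] <- rnorm(1, 0, 0.5)
    } else {
      k <- i - spec$examiner_n
      decay <- spec$micrographia_rate^(k - 1L)
      widths[i] <- max(spec$stroke_width * 4,
                       (spec$char_width_mean + rnorm(1, 0, spec$width_jitter_sd)) * decay)
      heights[i] <- max(spec$stroke_width * 4,
                        (spec$char_height_mean + rnorm(1, 0, spec$height_jitter_sd)) * decay)
      shears[i] <- rnorm(1, 0, spec$skew_sd)
    }
  }
  margin <- ceiling(spec$char_width_mean / 4) + 10
  total_w <- sum(widths) + spec$gap_mean * (n_total - 1L)
  page_w <- ceiling(total_w + 2 * margin)
  if (!is.null(spec$page_width)) {
    if (page_w > spec$page_width) {
      stop_validation("series of width %d px overflows the page (%d px available)",
                      page_w, spec$page_width)
    }
    page_w <- spec$page_width
  }
  max_h <- max(heights)
  base_row_off <- ceiling(spec$drift_amplitude + spec$stroke_width + 8)
  page_h <- ceiling(max_h + spec$drift_amplitude + base_row_off +
                      spec$stroke_width + 16)
  period <- if (spec$drift_period > 0) spec$drift_period else total_w
  drift_at <- function(x) {
    spec$drift_amplitude * sin(2 * pi * (x - margin) / period)
  }
  # sample stroke points per character (page coordinates, up-positive);
  # the pen draws a short baseline connector between consecutive shapes
  cursor <- margin
  char_pts <- vector("list", n_total)
  conn_pts <- vector("list", n_total)
  env_x <- list(); env_y <- list()
  sample_segment <- function(a, b) {
    len <- sqrt(sum((b - a)^2))
    ts <- seq(0, 1, length.out = max(2L, ceiling(len / 0.4)))
    cbind(a[1] + ts * (b[1] - a[1]), a[2] + ts * (b[2] - a[2]))
  }
  # the pen starts on the writing baseline: a short lead-in stroke before
  # the first shape (this is also what anchors the signal shift, whose
  # first sample must sit at the baseline level)
  lead_in <- 2 * spec$stroke_width
  conn_pts[[n_total + 1L]] <- {
    cp <- sample_segment(c(cursor - lead_in, 0), c(cursor, 0))
    cp[, 2] <- cp[, 2] + drift_at(cp[, 1])
    cp
  }
  env_x[[length(env_x) + 1L]] <- conn_pts[[n_total + 1L]][, 1]
  env_y[[length(env_y) + 1L]] <- conn_pts[[n_total + 1L]][, 2]
  for (i in seq_len(n_total)) {
    poly <- shape_polyline(labels[i], widths[i], heights[i])
    lam <- tan(shears[i] * pi / 180)
    poly[, 1] <- poly[, 1] + lam * poly[, 2]          # shear keeps baseline
    poly[, 1] <- poly[, 1] + cursor
    pts <- list()
    for (s in seq_len(nrow(poly) - 1L)) {
      pts[[s]] <- sample_segment(poly[s, ], poly[s + 1L, ])
    }
    pts <- do.call(rbind, pts)
    pts[, 2] <- pts[, 2] + drift_at(pts[, 1])
    char_pts[[i]] <- pts
    env_x[[i]] <- pts[, 1]; env_y[[i]] <- pts[, 2]
    cursor <- cursor + widths[i]
    if (i < n_total && spec$gap_mean > 0) {
      cp <- sample_segment(c(cursor, 0), c(cursor + spec$gap_mean, 0))
      cp[, 2] <- cp[, 2] + drift_at(cp[, 1])
      conn_pts[[i]] <- cp
      env_x[[length(env_x) + 1L]] <- cp[, 1]
      env_y[[length(env_y) + 1L]] <- cp[, 2]
    }
    cursor <- cursor + spec$gap_mean
  }
  # rasterize with disk-shaped pen of radius stroke_width / 2
  rad <- spec$stroke_width / 2
  off <- expand.grid(dr = -ceiling(rad):ceiling(rad),
                     dc = -ceiling(rad):ceiling(rad))
  off <- off[off$dr^2 + off$dc^2 <= rad^2 + 0.25, ]
  owner <- matrix(0L, page_h, page_w)
  conn_ink <- matrix(FALSE, page_h, page_w)
  stamp <- function(pts) {
    col0 <- round(pts[, 1]) + 1L
    row0 <- page_h - base_row_off - round(pts[, 2])
    rr <- rep(row0, each = nrow(off)) + rep(off$dr, times = length(row0))
    cc <- rep(col0, each = nrow(off)) + rep(off$dc, times = length(col0))
    ok <- rr >= 1L & rr <= page_h & cc >= 1L & cc <= page_w
    unique(cbind(rr[ok], cc[ok]))
  }
  for (i in seq_len(n_total)) {
    idx <- stamp(char_pts[[i]])
    free <- owner[idx] == 0L
    owner[idx[free, , drop = FALSE]] <- i
  }
  for (i in seq_along(conn_pts)) {
    if (!is.null(conn_pts[[i]])) conn_ink[stamp(conn_pts[[i]])] <- TRUE
  }
  ink <- owner > 0L | conn_ink
  px <- matrix(245, page_h, page_w)
  if (spec$noise_sd > 0) px <- px + rnorm(length(px), 0, spec$noise_sd)
  px[ink] <- 30 + if (spec$noise_sd > 0) rnorm(sum(ink), 0, spec$noise_sd) else 0
  if (spec$speckle_rate > 0) {
    nspeck <- rbinom(1, length(px), spec$speckle_rate)
    if (nspeck > 0) {
      at <- sample.int(length(px), nspeck)
      px[at] <- runif(nspeck, 0, 80)
    }
  }
  px <- pmin(pmax(px, 0), 255)
  image <- gray_image(round(px), dpi = spec$dpi)
  # overlay: red rectangles, blue triangles on white
  overlay <- array(1, dim = c(page_h, page_w, 3))
  for (ch in 1:3) {
    plane <- overlay[, , ch]
    for (i in seq_len(n_total)) {
      sel <- owner == i
      if (labels[i] == "R") {
        if (ch != 1L) plane[sel] <- 0
      } else {
        if (ch != 3L) plane[sel] <- 0
      }
    }
    overlay[, , ch] <- plane
  }
  rois <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    pix <- which(owner == i, arr.ind = TRUE)
    rr <- range(pix[, 1]); cc <- range(pix[, 2])
    sub <- owner[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE] == i
    rois[[i]] <- character_roi(sub, c(cc[1] - 1L, cc[2], rr[1] - 1L, rr[2]),
                               index = i - 1L, examiner = i <= spec$examiner_n)
  }
  # ideal envelope: per-column maximum height of the analytic stroke points
  ex <- round(unlist(env_x))
  ey <- unlist(env_y)
  env <- tapply(ey, ex, max)
  env_tbl <- tibble(x = as.integer(names(env)),
                    y = as.numeric(env))
  # analytic per-character bounding boxes (pre-rasterization)
  analytic_bbox <- t(vapply(char_pts, function(p) {
    c(min(p[, 1]), max(p[, 1]), min(p[, 2]), max(p[, 2]))
  }, numeric(4)))
  structure(list(
    image = image,
    overlay = overlay,
    truth = list(labels = labels, examiner_n = spec$examiner_n,
                 rois = rois, envelope = env_tbl,
                 analytic_bbox = analytic_bbox,
                 base_row_off = base_row_off,
                 spec = spec)
  ), class = "synthetic_scan")
}

#' @exportS3Method base::print
print.synthetic_scan <- function(x, ...) {
  cat(sprintf("<synthetic_scan> %d x %d px, %d characters (%s), seed %d\n",
              nrow(x$image$pixels), ncol(x$image$pixels),
              length(x$truth$labels), paste(x$truth$labels, collapse = ""),
              x$truth$spec$seed))
  invisible(x)
}

#' Write a rendered synthetic scan to disk
#'
#' Writes the grayscale scan (PNG), the RGB overlay, the sidecar JSON and
#' the truth labels.
#'
#' @param scan A `synthetic_scan`.
#' @param dir Output directory.
#' @param stem File stem (default `"scan"`).
#' @return Invisibly, the written paths.
#' @export
write_synthetic_scan <- function(scan, dir, stem = "scan") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, paste0(stem, ".png"))
  p2 <- file.path(dir, paste0(stem, "_overlay.png"))
  p3 <- file.path(dir, paste0(stem, ".json"))
  png::writePNG(scan$image$pixels / 255, p1)
  png::writePNG(scan$overlay, p2)
  jsonlite::write_json(list(dpi = scan$image$dpi,
                            examiner_n = scan$truth$examiner_n,
                            labels = paste(scan$truth$labels, collapse = "")),
                       p3, auto_unbox = TRUE)
  invisible(c(scan = p1, overlay = p2, sidecar = p3))
}

#' Simulate a three-group cohort
#'
#' Generates per-subject generator specs for the control, PD and PSP
#' presets, re-seeded per subject, together with the group table.
#'
#' @param n_per_group Integer vector of length 3 (control, pd, psp) or a
#'   single count used for all groups.
#' @param seed Master seed; subject seeds are derived deterministically.
#' @param spec_control,spec_pd,spec_psp Optional base specs overriding the
#'   presets.
#' @return A tibble with `subject`, `group` and a `spec` list-column.
#' @export
cohort <- function(n_per_group = c(10L, 10L, 10L), seed = 1L,
                   spec_control = preset_spec("control"),
                   spec_pd = preset_spec("pd"),
                   spec_psp = preset_spec("psp")) {
  if (length(n_per_group) == 1L) n_per_group <- rep(n_per_group, 3L)
  bases <- list(CON = spec_control, PD = spec_pd, PSP = spec_psp)
  ns <- setNames(as.integer(n_per_group), c("CON", "PD", "PSP"))
  rows <- list()
  counter <- 0L
  for (g in names(bases)) {
    for (s in seq_len(ns[[g]])) {
      counter <- counter + 1L
      sp <- bases[[g]]
      sp$seed <- (seed * 10007L + counter * 389L) %% 2147483647L
      rows[[counter]] <- tibble(subject = sprintf("S%03d", counter),
                                group = g, spec = list(sp))
    }
  }
  dplyr::bind_rows(rows)
}

#' Extract the feature table of a simulated cohort
#'
#' Renders each subject's scan and extracts the series feature vector,
#' either from the ground-truth delineations and labels (`mode = "truth"`,
#' the expert-delineation analogue) or by running the full automatic
#' pipeline (`mode = "auto"`).
#'
#' @param cohort_tbl Output of [cohort()].
#' @param mode `"truth"` or `"auto"`.
#' @param config Pipeline configuration for `mode = "auto"`.
#' @return A tibble: one row per subject with `subject`, `group` and the
#'   series features.
#' @export
cohort_features <- function(cohort_tbl, mode = c("truth", "auto"),
                            config = last_config()) {
  mode <- match.arg(mode)
  rows <- vector("list", nrow(cohort_tbl))
  for (i in seq_len(nrow(cohort_tbl))) {
    scan <- render_series(cohort_tbl$spec[[i]])
    rec <- if (mode == "truth") {
      process_truth(scan, subject = cohort_tbl$subject[i],
                    group = cohort_tbl$group[i])
    } else {
      process_scan(scan$image, examiner_n = scan$truth$examiner_n,
                   subject = cohort_tbl$subject[i],
                   group = cohort_tbl$group[i], config = config)$record
    }
    rows[[i]] <- as_tibble(rec)
  }
  dplyr::bind_rows(rows)
}
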
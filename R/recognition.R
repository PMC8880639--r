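# Model selection and rectangle/triangle recognition. Typical characters of
# the scan are promoted to per-class model templates by geometric and
# amplitude heuristics; every remaining character is assigned the class of
# its nearest model under band-constrained dynamic time warping.

#' Default recognition thresholds
#'
#' @param tri_ratio_threshold Enclosing-area ratio below which a character is
#'   a triangle model (rule a) and precondition level of the
#'   smaller-enclosure rule (rule b). Default 0.55.
#' @param hough_frac Horizontal-line fraction above which a character is a
#'   rectangle model (rule c). Default 0.25.
#' @param amp_hi,amp_lo Amplitude-histogram fractions: above `amp_hi` the
#'   character is a rectangle model, below `amp_lo` a triangle model
#'   (rule d). Defaults 0.66 / 0.33.
#' @param amp_level Level on the normalized amplitude scale defining a
#'   "near-maximal" sample. Default 0.80.
#' @param dtw_window DTW band half-width as a fraction of the longer
#'   sequence. Default 0.05.
#' @return A list of thresholds.
#' @export
recognition_config <- function(tri_ratio_threshold = 0.55, hough_frac = 0.25,
                               amp_hi = 0.66, amp_lo = 0.33, amp_level = 0.80,
                               dtw_window = 0.05) {
  list(tri_ratio_threshold = tri_ratio_threshold, hough_frac = hough_frac,
       amp_hi = amp_hi, amp_lo = amp_lo, amp_level = amp_level,
       dtw_window = dtw_window)
}

#' Enclosing-shape and amplitude statistics of one character
#'
#' @param roi A [character_roi()].
#' @param cs The matching [character_signal()].
#' @param config A [recognition_config()].
#' @return A list with `R` (min enclosing rectangle area), `T` (min
#'   enclosing triangle area), `tri_ratio` (`T / (R + T)`), `hough_hfrac`
#'   and `amp_frac`.
#' @export
enclosure_stats <- function(roi, cs, config = recognition_config()) {
  pix <- which(roi$mask, arr.ind = TRUE)
  pts <- cbind(pix[, 2] - 1, nrow(roi$mask) - pix[, 1])
  rect <- min_enclosing_rectangle(pts)
  tri <- min_enclosing_triangle(pts)
  list(
    R = rect$area,
    T = tri$area,
    tri_ratio = tri$area / (rect$area + tri$area),
    hough_hfrac = hough_horizontal_fraction(roi),
    amp_frac = amplitude_fraction(cs, config$amp_level)
  )
}

#' Artificial model templates
#'
#' Fallback signal templates installed when a scan yields no model of a
#' class: a perfect open rectangle (unit plateau) plus two isosceles
#' trapezoids (top side 0.5 and 0.7 of the base) for the rectangle class; a
#' perfect triangle (tent, apex centred) plus two mirrored right triangles
#' (apex at 0.25 and 0.75 of the width) for the triangle class. All are
#' normalized to unit amplitude.
#'
#' @param class `"R"` or `"T"`.
#' @param len Template length in samples.
#' @return List of numeric templates of length `len`.
#' @export
artificial_templates <- function(class = c("R", "T"), len = 100L) {
  class <- match.arg(class)
  u <- seq(0, 1, length.out = len)
  tent <- function(apex) pmax(0, pmin(u / apex, (1 - u) / (1 - apex)))
  trapezoid <- function(top) {
    ramp <- (1 - top) / 2
    pmin(1, pmin(u / ramp, (1 - u) / ramp))
  }
  out <- if (class == "R") {
    list(rep(1, len), trapezoid(0.5), trapezoid(0.7))
  } else {
    list(tent(0.5), tent(0.25), tent(0.75))
  }
  # exact unit amplitude even when the apex falls between samples
  lapply(out, function(v) if (diff(range(v)) > 0) normalize01(v) else v)
}

#' Select per-scan model characters
#'
#' Each character is tested against four rules, in order; the first match
#' promotes it to a model of the indicated class:
#'
#' (a) `tri_ratio = T/(R+T) < 0.55` — triangle model;
#' (b) the smaller enclosing shape wins when its symmetric ratio is also
#'     below 0.55: `R < T` and `R/(R+T) < 0.55` — rectangle model; `T < R`
#'     and `T/(R+T) < 0.55` — triangle model;
#' (c) a near-horizontal line longer than 0.25 of the character width —
#'     rectangle model;
#' (d) amplitude histogram: more than 66% of samples near-maximal —
#'     rectangle model; fewer than 33% — triangle model.
#'
#' Characters promoted to models are excluded from later DTW classification.
#' A class with no selected models receives the three
#' [artificial_templates()]. All model signals are normalized to `[0, 1]`
#' and resampled to the median character width of the scan.
#'
#' @param rois List of [character_roi()].
#' @param signals Matching list of [character_signal()].
#' @param config A [recognition_config()].
#' @return A list of class `last_models`: `rect`, `tri` (lists of
#'   templates), `artificial` (named logical), `model_idx` (named integer
#'   vector: 0-based character index -> class), `len`.
#' @export
select_models <- function(rois, signals, config = recognition_config()) {
  if (length(rois) == 0L) stop_validation("no characters to select models from")
  len <- max(16L, round(median(vapply(signals, function(s) length(s$values),
                                      numeric(1)))))
  rect <- list(); tri <- list()
  model_class <- rep(NA_character_, length(rois))
  rule <- rep(NA_character_, length(rois))
  for (i in seq_along(rois)) {
    st <- tryCatch(enclosure_stats(rois[[i]], signals[[i]], config),
                   error = function(e) NULL)
    if (is.null(st)) next
    cls <- NA_character_
    rect_ratio <- st$R / (st$R + st$T)
    if (st$tri_ratio < config$tri_ratio_threshold) {
      cls <- "T"; rule[i] <- "a"
    } else if (st$R < st$T && rect_ratio < config$tri_ratio_threshold) {
      cls <- "R"; rule[i] <- "b"
    } else if (st$T < st$R && st$tri_ratio < config$tri_ratio_threshold) {
      cls <- "T"; rule[i] <- "b"
    } else if (st$hough_hfrac > config$hough_frac) {
      cls <- "R"; rule[i] <- "c"
    } else if (st$amp_frac > config$amp_hi) {
      cls <- "R"; rule[i] <- "d"
    } else if (st$amp_frac < config$amp_lo) {
      cls <- "T"; rule[i] <- "d"
    }
    if (!is.na(cls)) {
      model_class[i] <- cls
      tmpl <- resample_linear(signals[[i]]$normalized, len)
      if (cls == "R") rect[[length(rect) + 1L]] <- tmpl
      else tri[[length(tri) + 1L]] <- tmpl
    }
  }
  artificial <- c(rect = FALSE, tri = FALSE)
  if (length(rect) == 0L) {
    rect <- artificial_templates("R", len)
    artificial["rect"] <- TRUE
  }
  if (length(tri) == 0L) {
    tri <- artificial_templates("T", len)
    artificial["tri"] <- TRUE
  }
  structure(list(rect = rect, tri = tri, artificial = artificial,
                 model_class = model_class, rule = rule, len = len),
            class = "last_models")
}

#' Band-constrained dynamic time warping distance
#'
#' Classic DTW with steps (i-1, j), (i, j-1), (i-1, j-1), matched
#' boundaries, squared-Euclidean local cost and a Sakoe-Chiba style band:
#' sample `i` of the first sequence may only align with samples `j`
#' satisfying `|i * m/n - j| <= window_frac * max(n, m)`.
#'
#' @param a,b Numeric sequences.
#' @param window_frac Band half-width as a fraction of the longer sequence,
#'   in `(0, 1]`; 1 disables the constraint.
#' @return The cumulative alignment cost (0 for identical sequences).
#' @export
dtw_distance <- function(a, b, window_frac = 0.05) {
  n <- length(a); m <- length(b)
  if (n == 0L || m == 0L) stop_validation("DTW inputs must be non-empty")
  if (window_frac <= 0 || window_frac > 1) {
    stop_validation("window_frac must lie in (0, 1]")
  }
  w <- max(window_frac * max(n, m), abs(n - m), 1)
  prev <- rep(Inf, m + 1L)
  prev[1] <- 0
  for (i in seq_len(n)) {
    cur <- rep(Inf, m + 1L)
    centre <- i * m / n
    jlo <- max(1L, floor(centre - w))
    jhi <- min(m, ceiling(centre + w))
    for (j in jlo:jhi) {
      d <- (a[i] - b[j])^2
      cur[j + 1L] <- d + min(prev[j], prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  out <- prev[m + 1L]
  if (!is.finite(out)) {
    # degenerate band: fall back to the unconstrained path
    warn("DTW band infeasible; falling back to unconstrained alignment")
    return(dtw_distance(a, b, window_frac = 1))
  }
  out
}

#' Classify characters as rectangles or triangles
#'
#' Characters already promoted to models keep their selection class. Every
#' other character is normalized to `[0, 1]`, resampled to the model length
#' and assigned the class of the nearest model by [dtw_distance()]; ties
#' break toward the rectangle class.
#'
#' @param signals List of [character_signal()].
#' @param models A `last_models` set from [select_models()].
#' @param window_frac DTW band fraction (default 0.05).
#' @return Character vector of `"R"` / `"T"` labels; attribute `distances`
#'   holds the per-character model distances.
#' @export
classify_characters <- function(signals, models, window_frac = 0.05) {
  labels <- character(length(signals))
  dists <- vector("list", length(signals))
  for (i in seq_along(signals)) {
    pre <- models$model_class[i]
    if (length(models$model_class) >= i && !is.na(pre)) {
      labels[i] <- pre
      next
    }
    v <- resample_linear(signals[[i]]$normalized, models$len)
    dr <- vapply(models$rect, function(tmp) dtw_distance(v, tmp, window_frac),
                 numeric(1))
    dt <- vapply(models$tri, function(tmp) dtw_distance(v, tmp, window_frac),
                 numeric(1))
    labels[i] <- if (min(dr) <= min(dt)) "R" else "T"
    dists[[i]] <- list(rect = dr, tri = dt)
  }
  attr(labels, "distances") <- dists
  labels
}

#' Per-class recognition Dice score against reference labels
#'
#' Characters are compared position-wise (the segmentation has already been
#' matched); for a class, true positives are characters of that class
#' recognized as such, false negatives its characters recognized otherwise,
#' false positives other characters recognized as the class.
#'
#' @param predicted,reference Character vectors over `"R"`/`"T"`, equal
#'   length.
#' @return Named numeric vector with Dice percentages for `R` and `T`.
#' @export
recognition_dice <- function(predicted, reference) {
  if (length(predicted) != length(reference)) {
    stop_validation("label sequences differ in length")
  }
  out <- c(R = NA_real_, T = NA_real_)
  for (cls in c("R", "T")) {
    tp <- sum(predicted == cls & reference == cls)
    fp <- sum(predicted == cls & reference != cls)
    fn <- sum(predicted != cls & reference == cls)
    out[cls] <- if (2 * tp + fp + fn == 0) NA_real_ else
      2 * tp / (2 * tp + fp + fn) * 100
  }
  out
}
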
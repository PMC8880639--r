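# Per-character and per-series feature extraction, examiner-template
# normalization, and the Needleman-Wunsch sequence-correctness coefficient.

# Spatial features normalized against the examiner template.
.spatial_features <- c("width", "height", "width_s", "height_s", "area",
                       "convex_hull_area", "long_axis", "short_axis",
                       "signal_length")

# Equivalent-ellipse moments of a mask: orientation (degrees, up-positive
# page coordinates, in (-90, 90]) and axis lengths of the ellipse with the
# same normalized second central moments as the pixel region.
mask_ellipse <- function(mask) {
  pix <- which(mask, arr.ind = TRUE)
  x <- pix[, 2] - 1
  y <- nrow(mask) - pix[, 1]           # up-positive
  mx <- mean(x); my <- mean(y)
  # 1/12 accounts for the unit extent of a pixel
  mu20 <- mean((x - mx)^2) + 1 / 12
  mu02 <- mean((y - my)^2) + 1 / 12
  mu11 <- mean((x - mx) * (y - my))
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  angle <- if (common < 1e-6) 0 else 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  if (angle <= -90) angle <- angle + 180
  if (angle > 90) angle <- angle - 180
  list(long_axis = 4 * sqrt(l1), short_axis = 4 * sqrt(max(l2, 0)),
       angle = angle)
}

# Rotate a logical mask by `angle` degrees (counter-clockwise in up-positive
# page coordinates) about its centroid; bilinear interpolation, re-binarized
# at 0.5. The canvas grows to hold the rotated extent.
rotate_mask <- function(mask, angle) {
  if (abs(angle) < 1e-9) return(mask)
  th <- angle * pi / 180
  nr <- nrow(mask); nc <- ncol(mask)
  cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
  diag_len <- ceiling(sqrt(nr^2 + nc^2)) + 2L
  out_r <- diag_len; out_c <- diag_len
  ocx <- (out_c + 1) / 2; ocy <- (out_r + 1) / 2
  gx <- matrix(rep(seq_len(out_c), each = out_r), out_r, out_c)
  gy <- matrix(rep(seq_len(out_r), times = out_c), out_r, out_c)
  dx <- gx - ocx
  dy <- -(gy - ocy)                    # matrix rows grow downward
  # inverse map: rotate by -angle in up-positive coordinates
  sx <- cos(-th) * dx - sin(-th) * dy + cx
  sy_up <- sin(-th) * dx + cos(-th) * dy
  sy <- cy - sy_up
  src <- matrix(0, nr, nc)
  src[mask] <- 1
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  at <- function(r, c) {
    v <- matrix(0, out_r, out_c)
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    v[ok] <- src[cbind(r[ok], c[ok])]
    v
  }
  val <- at(y0, x0) * (1 - fx) * (1 - fy) + at(y0, x0 + 1) * fx * (1 - fy) +
    at(y0 + 1, x0) * (1 - fx) * fy + at(y0 + 1, x0 + 1) * fx * fy
  out <- val >= 0.5
  if (!any(out)) return(mask)
  pix <- which(out, arr.ind = TRUE)
  rr <- range(pix[, 1]); cc <- range(pix[, 2])
  out[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
}

#' Straighten a character by its equivalent-ellipse orientation
#'
#' The orientation of the ellipse with the same normalized second central
#' moments as the character determines a rotation angle; rotating the mask
#' by the negative of that angle aligns skewed characters before their
#' "starred" width/height are measured. Isotropic masks (equal axis lengths)
#' rotate by 0 by convention.
#'
#' @param roi A [character_roi()] or logical mask.
#' @return A list with `mask` (rotated, cropped) and `angle` (degrees).
#' @export
straighten <- function(roi) {
  mask <- if (inherits(roi, "last_roi")) roi$mask else roi
  pix <- which(mask, arr.ind = TRUE)
  if (nrow(pix) < 3L) stop_validation("degenerate character mask")
  ell <- mask_ellipse(mask)
  ang <- if (abs(ell$long_axis - ell$short_axis) < 1e-6) 0 else ell$angle
  list(mask = rotate_mask(mask, -ang), angle = ang)
}

#' Measure one character
#'
#' Computes the full per-character feature map: bounding-box width/height,
#' straightened width/height, ink area, convex hull area, equivalent-ellipse
#' axes and orientation, signal arc length (interpolated gap samples
#' skipped), the near-maximal amplitude fraction, and the DTW distance to
#' the perfect artificial template of the character's class.
#'
#' @param roi A [character_roi()].
#' @param cs The matching [character_signal()].
#' @param label `"R"` or `"T"`.
#' @param window_frac DTW band fraction for the template distance.
#' @return Named numeric vector of features.
#' @export
character_features <- function(roi, cs, label, window_frac = 0.05) {
  mask <- roi$mask
  pix <- which(mask, arr.ind = TRUE)
  if (nrow(pix) < 3L) stop_validation("degenerate character mask")
  width <- roi$bbox[2] - roi$bbox[1]
  height <- roi$bbox[4] - roi$bbox[3]
  st <- straighten(roi)
  ell <- mask_ellipse(mask)
  pts <- cbind(pix[, 2] - 1, nrow(mask) - pix[, 1])
  hull_area <- tryCatch(polygon_area(convex_hull(pts)), error = function(e) 0)
  dy <- diff(cs$values)
  seg_ok <- !(cs$gap[-length(cs$gap)] | cs$gap[-1])
  signal_length <- sum(sqrt(1 + dy[seg_ok]^2))
  amp <- amplitude_fraction(cs)
  template <- artificial_templates(label, len = 100L)[[1]]
  v <- resample_linear(cs$normalized, 100L)
  dtw_model <- dtw_distance(v, template, window_frac)
  c(width = width, height = height,
    width_s = ncol(st$mask), height_s = nrow(st$mask),
    area = sum(mask), convex_hull_area = hull_area,
    long_axis = ell$long_axis, short_axis = ell$short_axis,
    angle = ell$angle, signal_length = signal_length,
    amp_frac = amp, dtw_model = dtw_model)
}

#' Normalize a character's spatial features against an examiner template
#'
#' Every spatial feature (widths, heights, areas, axes, signal length) is
#' divided by the template character's value, yielding `*_n` entries that
#' are comparable across examiners; dimensionless features are untouched.
#'
#' @param f Named feature vector from [character_features()].
#' @param template Feature vector of the examiner's template character of
#'   the same class.
#' @return `f` extended with the `*_n` entries.
#' @export
normalize_to_template <- function(f, template) {
  vals <- template[.spatial_features]
  if (anyNA(vals) || any(vals <= 0)) {
    stop_validation("template character has missing or non-positive spatial features")
  }
  norm <- f[.spatial_features] / vals
  names(norm) <- paste0(.spatial_features, "_n")
  c(f, norm)
}

#' Needleman-Wunsch sequence-correctness coefficient
#'
#' The examinee's label sequence `E` is aligned globally with the ideal
#' alternating sequence `G` using the Needleman-Wunsch scoring matrix
#' (match reward `m`, mismatch penalty `p`, gap penalty `g`, `H(0,0) = 0`)
#' and the score is normalized by the self-alignment of `G`:
#' `NW = max(H_EG) / max(H_GG) * 100`. With the default `m = 1`,
#' `p = g = 0` this equals the longest-common-subsequence length divided by
#' the sequence length, so a perfect series scores 100% and every
#' perseveration lowers the score.
#'
#' @param e,g Character vectors (or single strings) over `"R"`/`"T"`; `e`
#'   is padded with mismatching placeholders or truncated to the length of
#'   `g` when they differ.
#' @param m Match reward (default 1).
#' @param p Mismatch penalty (default 0).
#' @param gap Gap penalty (default 0).
#' @return The NW coefficient as a percentage.
#' @export
nw_coefficient <- function(e, g, m = 1, p = 0, gap = 0) {
  split1 <- function(s) if (length(s) == 1L && nchar(s[1]) > 1L)
    strsplit(s, "")[[1]] else as.character(s)
  e <- split1(e); g <- split1(g)
  if (length(g) == 0L) stop_validation("standard sequence G must be non-empty")
  if (length(e) < length(g)) e <- c(e, rep("_", length(g) - length(e)))
  if (length(e) > length(g)) e <- e[seq_along(g)]
  best_eg <- nw_max_score(e, g, m, p, gap)
  best_gg <- nw_max_score(g, g, m, p, gap)
  if (best_gg == 0) stop_validation("self-alignment score of G is zero; NW undefined")
  best_eg / best_gg * 100
}

# Maximum entry of the Needleman-Wunsch scoring matrix.
nw_max_score <- function(a, b, m, p, gap) {
  n <- length(a); k <- length(b)
  H <- matrix(0, n + 1L, k + 1L)
  H[1, ] <- gap * (0:k)
  H[, 1] <- gap * (0:n)
  for (i in seq_len(n)) {
    sub <- ifelse(a[i] == b, m, p)
    for (j in seq_len(k)) {
      H[i + 1L, j + 1L] <- max(H[i, j] + sub[j], H[i, j + 1L] + gap,
                               H[i + 1L, j] + gap)
    }
  }
  max(H)
}

#' Ideal alternating continuation of the examiner's pattern
#'
#' @param first First expected examinee shape (`"R"` or `"T"`).
#' @param n Sequence length.
#' @return Character vector alternating from `first`.
#' @export
ideal_alternation <- function(first = "T", n = 12L) {
  if (n <= 0L) return(character(0))
  other <- if (first == "R") "T" else "R"
  rep(c(first, other), length.out = n)
}

#' Aggregate per-character features into a series record
#'
#' Examinee characters are normalized against the examiner templates, then
#' summarized per class by the median (MED) and interquartile range (IQR,
#' third minus first linear-interpolation quartile). The record also holds
#' the per-class width ratios (summed character widths over the examinee
#' extent, in percent), the predicted label sequence and its
#' [nw_coefficient()] against the ideal alternation continuing the
#' examiner's pattern.
#'
#' @param features List of named feature vectors ([character_features()]),
#'   one per character, in series order.
#' @param labels Character vector of `"R"`/`"T"` labels.
#' @param examiner Logical vector flagging examiner-drawn characters.
#' @param rois List of [character_roi()] (for widths and the extent).
#' @param subject,group Identifier and group label stored in the record.
#' @param nw_m,nw_p,nw_g NW scoring parameters.
#' @return An object of class `last_record`.
#' @export
series_features <- function(features, labels, examiner, rois,
                            subject = "subject", group = NA_character_,
                            nw_m = 1, nw_p = 0, nw_g = 0) {
  stopifnot(length(features) == length(labels),
            length(labels) == length(examiner),
            length(labels) == length(rois))
  if (!any(!examiner)) stop_validation("no examinee characters in the series")
  templates <- list()
  for (cls in c("R", "T")) {
    ti <- which(examiner & labels == cls)
    if (length(ti) > 0L) templates[[cls]] <- features[[ti[1]]]
  }
  ex_idx <- which(!examiner)
  per_char <- vector("list", length(ex_idx))
  for (k in seq_along(ex_idx)) {
    i <- ex_idx[k]
    f <- features[[i]]
    tmpl <- templates[[labels[i]]]
    if (!is.null(tmpl)) f <- normalize_to_template(f, tmpl)
    per_char[[k]] <- tibble(index = rois[[i]]$index, label = labels[i],
                            !!!as.list(f))
  }
  chars <- dplyr::bind_rows(per_char)
  feature_cols <- setdiff(names(chars), c("index", "label"))
  agg <- list()
  for (cls in c("R", "T")) {
    sub <- chars[chars$label == cls, feature_cols, drop = FALSE]
    prefix <- if (cls == "R") "rect" else "tri"
    for (fc in feature_cols) {
      v <- sub[[fc]]
      v <- v[!is.na(v)]
      agg[[paste0(prefix, "_MED_", fc)]] <-
        if (length(v) >= 1L) median(v) else NA_real_
      agg[[paste0(prefix, "_IQR_", fc)]] <-
        if (length(v) >= 2L) diff(quantile(v, c(0.25, 0.75), names = FALSE,
                                           type = 7)) else NA_real_
    }
  }
  ex_rois <- rois[ex_idx]
  extent <- max(vapply(ex_rois, function(r) r$bbox[2], numeric(1))) -
    min(vapply(ex_rois, function(r) r$bbox[1], numeric(1)))
  widths <- vapply(ex_rois, function(r) r$bbox[2] - r$bbox[1], numeric(1))
  ex_labels <- labels[ex_idx]
  width_ratio_rect <- sum(widths[ex_labels == "R"]) / extent * 100
  width_ratio_tri <- sum(widths[ex_labels == "T"]) / extent * 100
  first_expected <- infer_first_expected(labels, examiner)
  g <- ideal_alternation(first_expected, length(ex_labels))
  nw <- nw_coefficient(ex_labels, g, m = nw_m, p = nw_p, gap = nw_g)
  structure(list(
    subject = subject, group = group,
    sequence = paste(ex_labels, collapse = ""),
    examiner_sequence = paste(labels[examiner], collapse = ""),
    characters = chars,
    aggregates = agg,
    width_ratio_rect = width_ratio_rect,
    width_ratio_tri = width_ratio_tri,
    nw = nw,
    n_characters = length(ex_idx),
    templates = templates
  ), class = "last_record")
}

# The shape the examinee should draw first: the alternation continues the
# examiner's prefix; without a usable prefix, default to rectangle first.
infer_first_expected <- function(labels, examiner) {
  ex <- labels[examiner]
  if (length(ex) == 0L) return("R")
  if (ex[length(ex)] == "R") "T" else "R"
}

#' @exportS3Method base::print
print.last_record <- function(x, ...) {
  cat(sprintf("<last_record> subject %s%s: %d characters, sequence %s, NW = %.1f%%\n",
              x$subject, if (is.na(x$group)) "" else paste0(" (", x$group, ")"),
              x$n_characters, x$sequence, x$nw))
  invisible(x)
}

#' Flatten a series record to a one-row tibble
#'
#' @param x A `last_record`.
#' @param ... Unused.
#' @return One row with subject, group, width ratios, NW, character count
#'   and every per-class MED/IQR aggregate.
#' @export
as_tibble.last_record <- function(x, ...) {
  tibble(subject = x$subject, group = x$group,
         n_characters = x$n_characters,
         sequence = x$sequence,
         width_ratio_rect = x$width_ratio_rect,
         width_ratio_tri = x$width_ratio_tri,
         nw = x$nw,
         !!!x$aggregates)
}
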
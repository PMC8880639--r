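# Character separation: locate the columns where the aligned signal returns
# to the baseline, split the binary image and signal at those columns, and
# score segmentations against expert masks.

#' Construct a character region of interest
#'
#' @param mask Logical sub-image (TRUE = ink), cropped to the bounding box.
#' @param bbox Integer vector `c(x0, x1, y0, y1)`, 0-based half-open page
#'   coordinates (columns `[x0, x1)`, rows `[y0, y1)`).
#' @param index 0-based position in the series, left to right.
#' @param examiner TRUE when the character was drawn by the examiner.
#' @return An object of class `last_roi`.
#' @export
character_roi <- function(mask, bbox, index = 0L, examiner = FALSE) {
  if (!any(mask)) stop_validation("a character ROI must contain ink")
  if (nrow(mask) != bbox[4] - bbox[3] || ncol(mask) != bbox[2] - bbox[1]) {
    stop_validation("ROI mask dimensions do not match its bounding box")
  }
  structure(list(mask = mask, bbox = as.integer(bbox),
                 index = as.integer(index), examiner = isTRUE(examiner)),
            class = "last_roi")
}

#' @exportS3Method base::print
print.last_roi <- function(x, ...) {
  cat(sprintf("<last_roi #%d%s> bbox [%d,%d) x [%d,%d), %d ink px\n",
              x$index, if (x$examiner) " examiner" else "",
              x$bbox[1], x$bbox[2], x$bbox[3], x$bbox[4], sum(x$mask)))
  invisible(x)
}

#' Construct a per-character signal segment
#'
#' @param values Aligned-signal samples over the character's columns.
#' @param x0,x1 0-based half-open column range.
#' @param gap Logical vector flagging interpolated samples.
#' @return An object of class `last_charsignal` with a `normalized` field
#'   (values rescaled to `[0, 1]` by the per-character min/max).
#' @export
character_signal <- function(values, x0, x1, gap = rep(FALSE, length(values))) {
  if (x1 - x0 != length(values)) {
    stop_validation("character signal range does not match its sample count")
  }
  structure(list(x0 = as.integer(x0), x1 = as.integer(x1),
                 values = as.numeric(values),
                 normalized = normalize01(values),
                 gap = gap),
            class = "last_charsignal")
}

#' Find the columns separating adjacent characters
#'
#' Adjacent characters of the series meet at the writing baseline, so the
#' aligned signal dips towards zero between them. Separating columns are the
#' local minima of the aligned signal whose value falls below `valley_frac`
#' times a robust signal maximum (the 95th percentile); runs of adjacent
#' qualifying minima (plateaus) collapse to their midpoint.
#'
#' @param a A `last_aligned` tibble from [adaptive_baseline()], or a numeric
#'   vector.
#' @param valley_frac Fraction of the robust maximum below which a local
#'   minimum counts as a baseline valley (default 0.10).
#' @param merge_tol Qualifying minima closer than this many columns are
#'   treated as one valley (default 3; jagged skeleton envelopes can split
#'   a single baseline valley into minima a pixel or two apart).
#' @return Sorted integer vector of 0-based separating columns (possibly
#'   empty).
#' @export
find_separating_columns <- function(a, valley_frac = 0.10, merge_tol = 3L) {
  if (inherits(a, "last_aligned") || is.data.frame(a)) {
    v <- a$aligned
    xs <- a$x
  } else {
    v <- as.numeric(a)
    xs <- seq_along(v) - 1L
  }
  n <- length(v)
  if (n < 3L) return(integer(0))
  robust_max <- as.numeric(quantile(v, 0.95, names = FALSE))
  thr <- valley_frac * robust_max
  is_min <- c(FALSE, v[2:(n - 1L)] <= v[1:(n - 2L)] &
                v[2:(n - 1L)] <= v[3:n], FALSE)
  qual <- which(is_min & v < thr)
  if (length(qual) == 0L) return(integer(0))
  # collapse runs of adjacent/near-adjacent qualifying minima to their midpoint
  breaks <- c(0L, which(diff(qual) > merge_tol), length(qual))
  out <- integer(length(breaks) - 1L)
  for (k in seq_len(length(breaks) - 1L)) {
    run <- qual[(breaks[k] + 1L):breaks[k + 1L]]
    out[k] <- as.integer(round(mean(xs[run])))
  }
  sort(out)
}

#' Split the series into per-character ROIs and signal segments
#'
#' Vertical strips of half-width `strip_halfwidth` around every separating
#' column are erased from the binary image, the remaining 8-connected
#' components are labelled, and undersized fragments (area below
#' `min_area_frac` of the median component area — typically askew stroke
#' remnants) are merged into the component whose column interval overlaps
#' theirs most, or dropped if none overlaps. Characters are ordered by
#' centroid column; the aligned signal is cut over each character's bounding
#' box.
#'
#' @param bin A `last_binary` (the cleaned binary image, not the skeleton).
#' @param a A `last_aligned` tibble covering the ink extent.
#' @param cols Sorted separating columns from [find_separating_columns()].
#' @param strip_halfwidth Half-width of the erased strip in px; the default
#'   estimates the stroke width from the binary image.
#' @param min_area_frac Fraction of the median component area below which a
#'   component is treated as a fragment (default 0.05).
#' @param examiner_n Leading characters flagged as examiner-drawn (default 0;
#'   the pipeline passes the sidecar value).
#' @param refine_wide Width-refinement factor: a component wider than this
#'   multiple of the median character width is re-cut at the deepest
#'   interior minimum of its signal segment (slanted neighbours can
#'   overhang a junction and mask its valley in the upper envelope). `NULL`
#'   disables the refinement.
#' @return A list with `rois` (list of [character_roi()]) and `signals`
#'   (list of [character_signal()]), both ordered left to right.
#' @export
split_characters <- function(bin, a, cols, strip_halfwidth = NULL,
                             min_area_frac = 0.05, examiner_n = 0L,
                             refine_wide = 1.6) {
  mask <- bin$mask
  if (is.null(strip_halfwidth)) {
    strip_halfwidth <- max(1L, round(estimate_stroke_width(mask) / 2))
  }
  out <- split_once(mask, a, cols, strip_halfwidth, min_area_frac, examiner_n)
  if (!is.null(refine_wide) && length(out$rois) >= 3L) {
    # a slanted neighbour's stroke can overhang a junction and mask its
    # valley in the upper envelope; re-cut components that are far wider
    # than the median character at the deepest interior minimum
    for (round in 1:3) {
      widths <- vapply(out$rois, function(r) r$bbox[2] - r$bbox[1], numeric(1))
      wide <- which(widths > refine_wide * median(widths))
      extra <- integer(0)
      for (k in wide) {
        s <- out$signals[[k]]
        n <- length(s$values)
        inner <- seq.int(ceiling(n * 0.25), floor(n * 0.75))
        if (length(inner) < 3L) next
        extra <- c(extra, s$x0 + inner[which.min(s$values[inner])] - 1L)
      }
      if (length(extra) == 0L) break
      cols <- sort(unique(c(cols, extra)))
      out <- split_once(mask, a, cols, strip_halfwidth, min_area_frac,
                        examiner_n)
    }
  }
  out
}

split_once <- function(mask, a, cols, strip_halfwidth, min_area_frac,
                       examiner_n) {
  cut <- mask
  for (cc in cols) {
    lo <- max(1L, cc + 1L - strip_halfwidth)
    hi <- min(ncol(mask), cc + 1L + strip_halfwidth)
    cut[, lo:hi] <- FALSE
  }
  lab <- label_components(cut)
  ncomp <- max(lab)
  if (ncomp == 0L) stop_validation("no components remain after strip erasure")
  stats <- component_stats(lab, ncomp)
  med_area <- median(stats$area)
  big <- stats$area >= min_area_frac * med_area
  assign_to <- seq_len(ncomp)
  for (k in which(!big)) {
    ov <- pmin(stats$x1[big], stats$x1[k]) - pmax(stats$x0[big], stats$x0[k])
    if (length(ov) == 0L || max(ov) <= 0) {
      assign_to[k] <- NA_integer_          # dropped: overlaps no character
    } else {
      assign_to[k] <- which(big)[which.max(ov)]
    }
  }
  # askew fragments: a sizeable component whose column span lies (almost)
  # inside a larger component's span is a severed stroke piece, not a
  # character of its own — fold it into its container
  for (k in which(big)) {
    w_k <- stats$x1[k] - stats$x0[k] + 1
    others <- setdiff(which(big), k)
    if (length(others) == 0L) next
    ov <- pmin(stats$x1[others], stats$x1[k]) -
      pmax(stats$x0[others], stats$x0[k]) + 1
    cand <- others[ov >= 0.6 * w_k & stats$area[others] > stats$area[k]]
    if (length(cand) > 0L) {
      target <- cand[which.max(stats$area[cand])]
      big[k] <- FALSE
      assign_to[k] <- target
      assign_to[assign_to == k] <- target
    }
  }
  keep <- sort(which(big))
  rois <- list()
  sigs <- list()
  ord <- order(stats$cx[keep])
  idx <- 0L
  for (k in keep[ord]) {
    members <- which(assign_to == k)
    sel <- matrix(FALSE, nrow(mask), ncol(mask))
    sel[lab %in% members] <- TRUE
    pix <- which(sel, arr.ind = TRUE)
    rr <- range(pix[, 1]); cc <- range(pix[, 2])
    sub <- sel[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
    bbox <- c(cc[1] - 1L, cc[2], rr[1] - 1L, rr[2])
    roi <- character_roi(sub, bbox, index = idx, examiner = idx < examiner_n)
    in_range <- a$x >= bbox[1] & a$x < bbox[2]
    if (!any(in_range)) next
    sig <- character_signal(a$aligned[in_range], min(a$x[in_range]),
                            max(a$x[in_range]) + 1L, a$gap[in_range])
    idx <- idx + 1L
    rois[[idx]] <- roi
    sigs[[idx]] <- sig
  }
  list(rois = rois, signals = sigs)
}

component_stats <- function(lab, ncomp) {
  pix <- which(lab > 0L, arr.ind = TRUE)
  labs <- lab[lab > 0L]
  area <- tabulate(labs, nbins = ncomp)
  x0 <- tapply(pix[, 2], labs, min)
  x1 <- tapply(pix[, 2], labs, max)
  cx <- tapply(pix[, 2], labs, mean)
  list(area = area, x0 = as.numeric(x0), x1 = as.numeric(x1),
       cx = as.numeric(cx))
}

# Median stroke width estimated from the foreground: twice the median
# distance from an ink pixel to the nearest background pixel.
estimate_stroke_width <- function(mask) {
  if (!any(mask)) return(1)
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1)))
  2 * median(dm[mask])
}

#' Jaccard similarity of two binary masks
#'
#' `|A intersect B| / |A union B|`; 1 when both masks are empty.
#'
#' @param a,b Logical matrices of identical dimensions.
#' @return A fraction in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop_validation("jaccard: mask dimensions differ")
  u <- sum(a | b)
  if (u == 0L) return(1)
  sum(a & b) / u
}

# Jaccard between two ROIs placed on a common page.
roi_jaccard <- function(r1, r2) {
  x0 <- min(r1$bbox[1], r2$bbox[1]); x1 <- max(r1$bbox[2], r2$bbox[2])
  y0 <- min(r1$bbox[3], r2$bbox[3]); y1 <- max(r1$bbox[4], r2$bbox[4])
  place <- function(r) {
    m <- matrix(FALSE, y1 - y0, x1 - x0)
    m[(r$bbox[3] - y0 + 1L):(r$bbox[4] - y0),
      (r$bbox[1] - x0 + 1L):(r$bbox[2] - x0)] <- r$mask
    m
  }
  jaccard(place(r1), place(r2))
}

#' Score an automatic segmentation against expert character masks
#'
#' Each manual ROI is matched greedily to the unmatched automatic ROI with
#' the highest Jaccard index; a match is accepted when the Jaccard exceeds
#' `jac_threshold`. Accepted matches are true positives, unmatched manual
#' ROIs false negatives, unmatched automatic ROIs false positives, and the
#' Sorensen-Dice score `2TP / (2TP + FP + FN)` is returned as a percentage.
#'
#' @param auto,manual Lists of [character_roi()] objects from the same scan.
#' @param jac_threshold Acceptance threshold on the Jaccard index
#'   (default 0.70).
#' @return A list with `dice` (percentage), `tp`, `fp`, `fn` and the
#'   `matches` tibble.
#' @export
segmentation_dice <- function(auto, manual, jac_threshold = 0.70) {
  if (length(auto) == 0L && length(manual) == 0L) {
    stop_validation("segmentation_dice: both ROI lists are empty")
  }
  used <- rep(FALSE, length(auto))
  rows <- list()
  tp <- 0L
  for (m in seq_along(manual)) {
    if (length(auto) == 0L) break
    js <- vapply(seq_along(auto), function(a) {
      if (used[a]) -1 else roi_jaccard(manual[[m]], auto[[a]])
    }, numeric(1))
    best <- which.max(js)
    if (js[best] > jac_threshold) {
      used[best] <- TRUE
      tp <- tp + 1L
      rows[[length(rows) + 1L]] <- tibble(manual = m - 1L, auto = best - 1L,
                                          jaccard = js[best])
    }
  }
  fn <- length(manual) - tp
  fp <- length(auto) - tp
  dice <- 2 * tp / (2 * tp + fp + fn) * 100
  list(dice = dice, tp = tp, fp = fp, fn = fn,
       matches = if (length(rows)) dplyr::bind_rows(rows) else
         tibble(manual = integer(), auto = integer(), jaccard = numeric()))
}
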
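# Background removal, binarization, morphological cleaning, thinning and
# conversion of the trace to its one-dimensional signal form.

#' Estimate the binarization threshold from the background histogram
#'
#' A LAST scan is dominated by white paper, so the tallest high-intensity
#' histogram mode identifies the background. The threshold is placed at the
#' low-intensity foot of that mode: the lowest intensity from which the
#' (smoothed) histogram rises monotonically to the mode, minus a safety margin
#' of 3 gray levels. Pixels darker than the threshold are ink candidates.
#'
#' @param img A [gray_image()].
#' @param smooth Half-width of the moving-average histogram smoother in gray
#'   levels (default 2).
#' @return A threshold `t` in `[0, 255]`.
#' @export
estimate_background_threshold <- function(img, smooth = 2L) {
  px <- as.vector(img$pixels)
  counts <- tabulate(pmin(pmax(floor(px), 0), 255) + 1L, nbins = 256L)
  k <- 2L * smooth + 1L
  sm <- as.vector(stats::filter(counts, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- counts[is.na(sm)]
  hi <- 130:256                      # candidate background intensities > 128
  if (all(counts[hi] == 0)) {
    stop_validation("no paper background detected (no histogram mode above intensity 128)")
  }
  mode_bin <- hi[which.max(sm[hi])]
  v <- mode_bin
  while (v > 1L && sm[v - 1L] <= sm[v] && sm[v - 1L] > 0) v <- v - 1L
  max(0L, (v - 1L) - 3L)             # bin index is intensity + 1
}

#' Threshold a scan and clean it by morphological opening
#'
#' Foreground is `intensity < t`; a binary opening with a disk-shaped
#' structuring element then removes scanning speckle enhanced by
#' binarization. The result is always a subset of the raw thresholded mask.
#'
#' @param img A [gray_image()].
#' @param t Intensity threshold in `[0, 255]`; see
#'   [estimate_background_threshold()].
#' @param opening_radius Disk radius in pixels; the default scales the
#'   1-px-at-600-dpi convention with resolution. `0` disables the opening.
#' @return An object of class `last_binary`: list with logical matrix `mask`
#'   (TRUE = ink), `threshold` and `opening_radius`.
#' @export
binarize_and_clean <- function(img, t = estimate_background_threshold(img),
                               opening_radius = max(1L, round(img$dpi / 600))) {
  if (t < 0 || t > 255) stop_validation("threshold must lie in [0, 255]")
  raw <- img$pixels < t
  mask <- raw
  if (opening_radius > 0 && any(raw)) {
    brush <- EBImage::makeBrush(2L * opening_radius + 1L, shape = "disc")
    opened <- EBImage::opening(EBImage::Image(raw * 1), brush)
    mask <- EBImage::imageData(opened) > 0.5
    mask <- mask & raw               # opening never adds foreground
  }
  structure(list(mask = mask, threshold = t, opening_radius = opening_radius),
            class = "last_binary")
}

#' @exportS3Method base::print
print.last_binary <- function(x, ...) {
  cat(sprintf("<last_binary> %d x %d px, %d ink pixels (t = %g, opening r = %d)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$threshold,
              x$opening_radius))
  invisible(x)
}

# Neighbour shift of a padded logical matrix: dr, dc in {-1, 0, 1}.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  p[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
}

#' Thin a binary trace to a one-pixel-wide skeleton
#'
#' Iterative two-subcycle thinning (Zhang-Suen scheme): boundary pixels are
#' peeled while connectivity is preserved, producing an 8-connected skeleton
#' that is a subset of the input and keeps its connected-component count.
#'
#' @param bin A `last_binary` from [binarize_and_clean()], or a logical
#'   matrix.
#' @return A `last_binary` whose mask is the skeleton.
#' @export
skeletonize_mask <- function(bin) {
  mask <- if (inherits(bin, "last_binary")) bin$mask else bin
  if (!any(mask)) stop_validation("cannot skeletonize an empty foreground")
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      # ordered 8-neighbourhood p2..p9 starting north, clockwise
      p2 <- shift_mat(mask, -1L, 0L); p3 <- shift_mat(mask, -1L, 1L)
      p4 <- shift_mat(mask, 0L, 1L);  p5 <- shift_mat(mask, 1L, 1L)
      p6 <- shift_mat(mask, 1L, 0L);  p7 <- shift_mat(mask, 1L, -1L)
      p8 <- shift_mat(mask, 0L, -1L); p9 <- shift_mat(mask, -1L, -1L)
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (pass == 1L) {
        cond <- !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      del <- mask & bsum >= 2 & bsum <= 6 & a == 1 & cond
      if (any(del)) {
        mask[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  structure(list(mask = mask,
                 threshold = if (inherits(bin, "last_binary")) bin$threshold else NA_real_,
                 opening_radius = if (inherits(bin, "last_binary")) bin$opening_radius else NA_integer_),
            class = "last_binary")
}

# 8-connected component labelling. EBImage::bwlabel is 4-connected, so labels
# touching diagonally are merged with a union-find pass.
label_components <- function(mask) {
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n > 1L) {
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    union_pairs <- function(a, b) {
      keep <- a > 0L & b > 0L & a != b
      for (k in which(keep)) {
        ra <- find(a[k]); rb <- find(b[k])
        if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
      }
    }
    # diagonal adjacencies missed by 4-connectivity
    nr <- nrow(lab); nc <- ncol(lab)
    union_pairs(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1]))
    union_pairs(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))
    roots <- vapply(seq_len(n), find, integer(1))
    relab <- match(roots, sort(unique(roots)))
    lab[lab > 0L] <- relab[lab[lab > 0L]]
  }
  lab
}

#' Reduce a skeleton to its one-dimensional signal form
#'
#' For every column between the first and last ink column, the height of the
#' uppermost skeleton pixel is recorded in up-positive page coordinates
#' (`y = image_height - 1 - row`). Columns crossed by no skeleton pixel are
#' linearly interpolated and flagged in `gap`.
#'
#' The upper envelope is the representation on which amplitude-based shape
#' recognition operates: an open rectangle maps to a plateau near its maximum
#' while a triangle maps to a tent.
#'
#' @param skel A `last_binary` skeleton (or logical matrix).
#' @return A tibble of class `last_signal` with columns `x` (0-based column
#'   index), `y` (height in px) and `gap` (logical), and attribute
#'   `img_height`.
#' @export
to_signal_form <- function(skel) {
  mask <- if (inherits(skel, "last_binary")) skel$mask else skel
  if (!any(mask)) stop_validation("cannot take the signal form of an empty skeleton")
  h <- nrow(mask)
  cols_with <- which(colSums(mask) > 0L)
  x0 <- min(cols_with); x1 <- max(cols_with)
  xs <- x0:x1
  top_row <- apply(mask[, xs, drop = FALSE], 2, function(col) {
    w <- which(col)
    if (length(w) == 0L) NA_integer_ else w[1]
  })
  y <- h - 1 - (top_row - 1)
  gap <- is.na(y)
  if (any(gap)) {
    y <- approx(xs[!gap], y[!gap], xout = xs, rule = 2)$y
  }
  out <- tibble(x = xs - 1L, y = as.numeric(y), gap = gap)
  class(out) <- c("last_signal", class(out))
  attr(out, "img_height") <- h
  out
}

#' Run the full preprocessing chain on a scan
#'
#' Threshold estimation, binarization with opening, thinning and signal-form
#' extraction in one call.
#'
#' @param img A [gray_image()].
#' @param opening_radius Passed to [binarize_and_clean()].
#' @return A list with `binary`, `skeleton` and `signal`.
#' @export
preprocess_scan <- function(img, opening_radius = max(1L, round(img$dpi / 600))) {
  t <- estimate_background_threshold(img)
  bin <- binarize_and_clean(img, t, opening_radius)
  if (!any(bin$mask)) stop_validation("no ink found after binarization")
  skel <- skeletonize_mask(bin)
  list(binary = bin, skeleton = skel, signal = to_signal_form(skel))
}
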
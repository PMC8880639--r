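# Enclosing-shape geometry and line analysis used for model selection:
# minimum-area enclosing rectangle (rotating calipers), minimum-area
# enclosing triangle (flush-side candidate enumeration) and the Hough-based
# horizontal-line fraction.

# Convex hull of a two-column point matrix, counter-clockwise, no repeats.
convex_hull <- function(points) {
  h <- grDevices::chull(points)          # clockwise in standard orientation
  points[rev(h), , drop = FALSE]
}

check_points <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2L || nrow(points) < 3L) {
    stop_validation("need at least 3 two-dimensional points")
  }
  storage.mode(points) <- "double"
  h <- convex_hull(points)
  if (nrow(h) < 3L || polygon_area(h) < 1e-12) {
    stop_validation("degenerate (collinear) point set")
  }
  h
}

#' Minimum-area enclosing rectangle
#'
#' The minimum-area rectangle of arbitrary orientation containing a point
#' set. One side of the optimum is flush with a convex-hull edge, so the
#' rectangle is found by rotating calipers over the hull edges.
#'
#' @param points Two-column matrix of point coordinates.
#' @return A list with `area` and `corners` (4 x 2 matrix, in order).
#' @export
min_enclosing_rectangle <- function(points) {
  h <- check_points(points)
  n <- nrow(h)
  e <- h[c(2:n, 1), ] - h
  len <- sqrt(rowSums(e^2))
  best <- NULL
  for (i in which(len > 0)) {
    u <- e[i, ] / len[i]
    v <- c(-u[2], u[1])
    pu <- h %*% u
    pv <- h %*% v
    du <- max(pu) - min(pu)
    dv <- max(pv) - min(pv)
    area <- du * dv
    if (is.null(best) || area < best$area) {
      corners <- rbind(
        min(pu) * u + min(pv) * v,
        max(pu) * u + min(pv) * v,
        max(pu) * u + max(pv) * v,
        min(pu) * u + max(pv) * v
      )
      best <- list(area = area, corners = corners)
    }
  }
  best
}

# Intersection of two lines given as (point, direction); NULL when parallel.
line_intersect <- function(a1, d1, a2, d2) {
  det <- d1[1] * (-d2[2]) - (-d2[1]) * d1[2]
  if (abs(det) < 1e-12) return(NULL)
  rhs <- a2 - a1
  t <- (rhs[1] * (-d2[2]) - (-d2[1]) * rhs[2]) / det
  a1 + t * d1
}

#' Minimum-area enclosing triangle
#'
#' The minimum-area triangle containing a point set. By the standard
#' optimality condition at least one side is flush with a convex-hull edge
#' and the midpoint of every side touches the hull; consequently the optimum
#' has either three flush sides, or two flush sides and a third side whose
#' midpoint is a hull vertex. Both candidate families are enumerated
#' exhaustively (O(n^3) in the hull size) and the smallest containing
#' triangle is returned.
#'
#' @param points Two-column matrix of point coordinates.
#' @return A list with `area` and `corners` (3 x 2 matrix).
#' @export
min_enclosing_triangle <- function(points) {
  h <- check_points(points)
  n <- nrow(h)
  idx2 <- c(2:n, 1)
  dirs <- h[idx2, , drop = FALSE] - h
  len <- sqrt(rowSums(dirs^2))
  keep <- len > 1e-12
  anchors <- h[keep, , drop = FALSE]
  dirs <- dirs[keep, , drop = FALSE] / len[keep]
  m <- nrow(anchors)
  scale <- max(apply(h, 2, function(v) diff(range(v))))
  tol <- 1e-9 * max(scale, 1)
  best <- NULL
  consider <- function(tri) {
    if (is.null(tri)) return()
    # orient counter-clockwise
    a2 <- (tri[2, 1] - tri[1, 1]) * (tri[3, 2] - tri[1, 2]) -
      (tri[2, 2] - tri[1, 2]) * (tri[3, 1] - tri[1, 1])
    if (abs(a2) < 1e-12) return()
    if (a2 < 0) tri <- tri[c(1, 3, 2), ]
    if (!all(point_in_tri(tri, h, tol))) return()
    area <- as.numeric(abs(a2)) / 2
    if (is.null(best) || area < best$area) best <<- list(area = area, corners = tri)
  }
  # family 1: three flush sides
  for (i in seq_len(m - 2)) for (j in (i + 1):(m - 1)) for (k in (j + 1):m) {
    v1 <- line_intersect(anchors[i, ], dirs[i, ], anchors[j, ], dirs[j, ])
    v2 <- line_intersect(anchors[j, ], dirs[j, ], anchors[k, ], dirs[k, ])
    v3 <- line_intersect(anchors[k, ], dirs[k, ], anchors[i, ], dirs[i, ])
    if (is.null(v1) || is.null(v2) || is.null(v3)) next
    consider(rbind(v1, v2, v3))
  }
  # family 2: two flush sides, third side bisected by a hull vertex w:
  # endpoints P on line i and Q on line j with (P + Q)/2 = w.
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    apex <- line_intersect(anchors[i, ], dirs[i, ], anchors[j, ], dirs[j, ])
    if (is.null(apex)) next
    det <- dirs[i, 1] * dirs[j, 2] - dirs[j, 1] * dirs[i, 2]
    if (abs(det) < 1e-12) next
    for (w in seq_len(n)) {
      rhs <- 2 * h[w, ] - anchors[i, ] - anchors[j, ]
      t <- (rhs[1] * dirs[j, 2] - dirs[j, 1] * rhs[2]) / det
      s <- (dirs[i, 1] * rhs[2] - rhs[1] * dirs[i, 2]) / det
      p <- anchors[i, ] + t * dirs[i, ]
      q <- anchors[j, ] + s * dirs[j, ]
      consider(rbind(apex, p, q))
    }
  }
  if (is.null(best)) stop_numerical("no valid enclosing triangle found")
  best
}

# Vectorized point-in-triangle for a CCW triangle.
point_in_tri <- function(tri, pts, tol) {
  inside <- rep(TRUE, nrow(pts))
  for (i in 1:3) {
    a <- tri[i, ]; b <- tri[i %% 3 + 1, ]
    cr <- (b[1] - a[1]) * (pts[, 2] - a[2]) - (b[2] - a[2]) * (pts[, 1] - a[1])
    inside <- inside & cr >= -tol
  }
  inside
}

#' Longest near-horizontal line fraction of a character (Hough analysis)
#'
#' A Hough-style sweep over near-horizontal orientations: for each angle
#' within `angle_tol` of horizontal, ink pixels are binned by their
#' perpendicular offset (1-px bins); the longest line is the widest column
#' span collected by any bin, and the returned fraction divides it by the
#' bounding-box width. Open rectangles score close to 1 (full-width top
#' stroke) while triangles, whose strokes are steeply slanted, stay low.
#'
#' @param roi A [character_roi()] (or a logical mask).
#' @param angle_tol Angular tolerance from horizontal in degrees (default 5).
#' @param angle_step Sweep resolution in degrees (default 0.5).
#' @return The longest near-horizontal line length divided by the character
#'   width, in `[0, ~1]`.
#' @export
hough_horizontal_fraction <- function(roi, angle_tol = 5, angle_step = 0.5) {
  mask <- if (inherits(roi, "last_roi")) roi$mask else roi
  if (!any(mask)) stop_validation("empty character mask")
  pix <- which(mask, arr.ind = TRUE)
  x <- pix[, 2] - 1
  y <- nrow(mask) - pix[, 1]           # up-positive
  width <- ncol(mask)
  angles <- seq(-angle_tol, angle_tol, by = angle_step) * pi / 180
  best <- 0
  for (al in angles) {
    rho <- round(y * cos(al) - x * sin(al))
    along <- x * cos(al) + y * sin(al)
    for (b in unique(rho)) {
      sel <- rho == b
      span <- length(unique(round(along[sel])))
      if (span > best) best <- span
    }
  }
  best / width
}

#' Fraction of near-maximal samples in a character's normalized signal
#'
#' The share of samples whose normalized amplitude exceeds `level` (default
#' 0.8). An open rectangle's signal form is a plateau near its maximum, so
#' the fraction approaches 1; an ideal triangle's tent yields
#' `1 - level` (0.2 at the default level).
#'
#' @param cs A [character_signal()].
#' @param level Amplitude level on the normalized `[0, 1]` scale.
#' @return A fraction in `[0, 1]`.
#' @export
amplitude_fraction <- function(cs, level = 0.8) {
  if (diff(range(cs$values)) <= 0) {
    stop_validation("zero-amplitude character segment")
  }
  mean(cs$normalized > level)
}
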
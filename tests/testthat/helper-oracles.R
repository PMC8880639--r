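# Independent oracles used by the geometry, DTW and NW tests.

# Brute-force longest-common-subsequence length (classic DP, index-based).
lcs_length <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n == 0L || m == 0L) return(0L)
  L <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    L[i + 1L, j + 1L] <- if (a[i] == b[j]) L[i, j] + 1L else
      max(L[i, j + 1L], L[i + 1L, j])
  }
  L[n + 1L, m + 1L]
}

# Exhaustive DTW by memoized recursion over the full (unbanded) lattice,
# written independently of the package's iterative band implementation.
dtw_oracle <- function(a, b) {
  n <- length(a); m <- length(b)
  memo <- matrix(NA_real_, n, m)
  rec <- function(i, j) {
    if (i < 1 || j < 1) return(Inf)
    if (!is.na(memo[i, j])) return(memo[i, j])
    d <- (a[i] - b[j])^2
    v <- if (i == 1 && j == 1) d else d + min(rec(i - 1, j - 1),
                                              rec(i - 1, j), rec(i, j - 1))
    memo[i, j] <<- v
    v
  }
  rec(n, m)
}

# Minimum-area enclosing rectangle by scanning hull-edge orientations
# directly on the raw points (no rotating-calipers structure shared with
# the implementation).
rect_oracle <- function(pts) {
  h <- pts[grDevices::chull(pts), , drop = FALSE]
  n <- nrow(h)
  angs <- atan2(h[c(2:n, 1), 2] - h[, 2], h[c(2:n, 1), 1] - h[, 1])
  best <- Inf
  for (th in angs) {
    u <- c(cos(th), sin(th)); v <- c(-sin(th), cos(th))
    a <- diff(range(pts %*% u)) * diff(range(pts %*% v))
    best <- min(best, a)
  }
  best
}

# Minimum-area enclosing triangle oracle: one side flush with each hull
# edge in turn, the other two sides swept as support lines over an angle
# grid (vectorized), followed by Nelder-Mead refinement of the best grid
# point. Support halfplanes whose normals do not positively span the plane
# are rejected (they do not bound a triangle).
tri_oracle <- function(pts, grid_deg = 3, refine = TRUE) {
  h <- pts[rev(grDevices::chull(pts)), , drop = FALSE]   # counter-clockwise
  n <- nrow(h)
  supp <- function(th) {
    m <- outer(h[, 1], cos(th)) + outer(h[, 2], sin(th))
    m[cbind(max.col(t(m)), seq_along(th))]
  }
  tri_area <- function(t0, t1, t2) {
    c0 <- cos(t0); s0 <- sin(t0); h0 <- supp(t0)
    c1 <- cos(t1); s1 <- sin(t1); h1 <- supp(t1)
    c2 <- cos(t2); s2 <- sin(t2); h2 <- supp(t2)
    inter <- function(ca, sa, ha, cb, sb, hb) {
      d <- ca * sb - cb * sa
      list(x = (ha * sb - hb * sa) / d, y = (ca * hb - cb * ha) / d, d = d)
    }
    p01 <- inter(c0, s0, h0, c1, s1, h1)
    p02 <- inter(c0, s0, h0, c2, s2, h2)
    p12 <- inter(c1, s1, h1, c2, s2, h2)
    area <- abs((p02$x - p01$x) * (p12$y - p01$y) -
                  (p02$y - p01$y) * (p12$x - p01$x)) / 2
    # each pairwise vertex must satisfy the remaining constraint, and the
    # three normals must positively span the plane (bounded intersection)
    ok <- (p01$x * c2 + p01$y * s2 <= h2 + 1e-9) &
      (p02$x * c1 + p02$y * s1 <= h1 + 1e-9) &
      (p12$x * c0 + p12$y * s0 <= h0 + 1e-9) &
      abs(p01$d) > 1e-9 & abs(p02$d) > 1e-9 & abs(p12$d) > 1e-9
    a0 <- t0 %% (2 * pi); a1 <- t1 %% (2 * pi); a2 <- t2 %% (2 * pi)
    lo <- pmin(a0, a1, a2); hi <- pmax(a0, a1, a2)
    mid <- a0 + a1 + a2 - lo - hi
    max_gap <- pmax(mid - lo, hi - mid, lo + 2 * pi - hi)
    area[!ok | max_gap >= pi] <- Inf
    area
  }
  # outward normal angles of the CCW hull edges are the flush-base candidates
  edge_dir <- atan2(h[c(2:n, 1), 2] - h[, 2], h[c(2:n, 1), 1] - h[, 1])
  base_angles <- edge_dir - pi / 2
  grid <- seq(0, 2 * pi, by = grid_deg * pi / 180)
  gg <- expand.grid(t1 = grid, t2 = grid)
  starts <- list()
  for (t0 in base_angles) {
    a <- tri_area(rep(t0, nrow(gg)), gg$t1, gg$t2)
    k <- which.min(a)
    if (is.finite(a[k])) starts[[length(starts) + 1L]] <- c(t0, gg$t1[k], gg$t2[k])
  }
  bpar <- starts[[1]]
  # refinement uses an explicit hull-containment objective: the algebraic
  # feasibility mask above can pass near-degenerate configurations
  feas_area <- function(ths) {
    cs <- cos(ths); ss <- sin(ths)
    hs <- vapply(ths, function(t) max(h %*% c(cos(t), sin(t))), numeric(1))
    V <- matrix(NA_real_, 3, 2)
    for (k in 1:3) {
      i <- k; j <- k %% 3 + 1
      d <- cs[i] * ss[j] - cs[j] * ss[i]
      if (abs(d) < 1e-12) return(1e9)
      V[k, ] <- c((hs[i] * ss[j] - hs[j] * ss[i]) / d,
                  (cs[i] * hs[j] - cs[j] * hs[i]) / d)
    }
    s_tri <- (V[2, 1] - V[1, 1]) * (V[3, 2] - V[1, 2]) -
      (V[2, 2] - V[1, 2]) * (V[3, 1] - V[1, 1])
    if (abs(s_tri) < 1e-12) return(1e9)
    s <- sign(s_tri)                   # orientation fixed by the triangle
    for (k in 1:3) {
      a <- V[k, ]; b <- V[k %% 3 + 1, ]
      cr <- (b[1] - a[1]) * (h[, 2] - a[2]) - (b[2] - a[2]) * (h[, 1] - a[1])
      if (any(s * cr < -1e-9)) return(1e9)
    }
    abs((V[2, 1] - V[1, 1]) * (V[3, 2] - V[1, 2]) -
          (V[2, 2] - V[1, 2]) * (V[3, 1] - V[1, 1])) / 2
  }
  best <- Inf
  for (bp in starts) {
    best <- min(best, feas_area(bp))
    if (refine) {
      o <- stats::optim(bp[2:3],
                        function(p) feas_area(c(bp[1], p[1], p[2])),
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 4000))
      best <- min(best, o$value)
    }
  }
  best
}
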
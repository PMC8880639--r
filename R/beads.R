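# BEADS baseline estimation: the signal form y is modelled as a low-pass
# baseline f, sparse positive peaks x (the characters) and noise w. x is
# recovered by majorization-minimization of
#   F(x) = 1/2 ||H(y - x)||^2 + lam0 * sum theta_eps(x_n; r)
#          + lam1 * sum phi([D1 x]_n) + lam2 * sum phi([D2 x]_n)
# where H is the high-pass complement of a banded zero-phase low-pass filter
# with cut-off fc, D1/D2 are first/second difference operators, theta_eps is
# an asymmetric sparsity penalty (asymmetry r) and phi a smoothed absolute
# value. The baseline estimate is f = L(y - x).

#' BEADS solver parameters
#'
#' @param fc Low-pass cut-off in cycles/sample, in `(0, 0.5)`. The default
#'   1e-4 is the pipeline convention for 600-dpi series signals; standalone
#'   uses should match `fc` to the drift content of the signal.
#' @param r Asymmetry of the sparse amplitude penalty (`> 0`); larger values
#'   penalize negative peaks more heavily.
#' @param lam0,lam1,lam2 Sparsity weights for the peak amplitude and its
#'   first/second differences (all `> 0`).
#' @param eps Smoothing constant of the penalty functions.
#' @param n_iter Majorization-minimization iterations.
#' @param d Order of the banded low-pass filter (1 or 2).
#' @param max_doublings Cap on the adaptive doubling loop of
#'   [adaptive_baseline()].
#' @return A list of class `beads_params`.
#' @export
beads_params <- function(fc = 1e-4, r = 1, lam0 = 1, lam1 = 2 * lam0,
                         lam2 = 2 * lam0, eps = 1e-6, n_iter = 30L, d = 1L,
                         max_doublings = 10L) {
  if (fc <= 0 || fc >= 0.5) stop_validation("fc must lie in (0, 0.5)")
  if (lam0 <= 0 || lam1 <= 0 || lam2 <= 0) stop_validation("lambda weights must be positive")
  if (r <= 0) stop_validation("asymmetry r must be positive")
  if (n_iter < 1L) stop_validation("n_iter must be at least 1")
  structure(list(fc = fc, r = r, lam0 = lam0, lam1 = lam1, lam2 = lam2,
                 eps = eps, n_iter = as.integer(n_iter), d = as.integer(d),
                 max_doublings = as.integer(max_doublings)),
            class = "beads_params")
}

# Banded zero-phase filter matrices A, B such that H = A^{-1} B is high-pass
# with half-power point fc. a = b + t * lowpass-kernel with
# t = ((1 - cos wc)/(1 + cos wc))^d.
beads_filter <- function(d, fc, n) {
  conv_full <- function(u, v) convolve(u, rev(v), type = "open")
  b1 <- c(1, -1)
  if (d > 1L) for (i in seq_len(d - 1L)) b1 <- conv_full(b1, c(-1, 2, -1))
  b <- conv_full(b1, c(-1, 1))
  omc <- 2 * pi * fc
  t0 <- ((1 - cos(omc)) / (1 + cos(omc)))^d
  a <- 1
  for (i in seq_len(d)) a <- conv_full(a, c(1, 2, 1))
  a <- b + t0 * a
  band <- function(coef) {
    Matrix::bandSparse(n, n, k = -d:d,
                       diagonals = lapply(seq_along(coef),
                                          function(i) rep(coef[i], n)))
  }
  list(A = band(a), B = band(b))
}

#' Decompose a signal into sparse peaks and a low-pass baseline (BEADS)
#'
#' Minimizes the BEADS objective by majorization-minimization. The objective
#' is non-increasing across iterations; a repeated increase raises a
#' numerical error.
#'
#' @param y Numeric signal of length at least 16.
#' @param p A [beads_params()] object.
#' @return A list with `peaks` (the sparse component \eqn{\hat x}), `baseline`
#'   (\eqn{\hat f}) and `objective` (per-iteration objective values).
#' @export
beads_solve <- function(y, p = beads_params()) {
  if (!is.numeric(y) || length(y) < 16L) {
    stop_validation("beads_solve needs a numeric signal of length >= 16")
  }
  if (any(!is.finite(y))) stop_validation("signal contains non-finite values")
  n <- length(y)
  eps0 <- p$eps; eps1 <- p$eps; r <- p$r
  fl <- beads_filter(p$d, p$fc, n)
  A <- fl$A; B <- fl$B
  Hmul <- function(v) as.vector(B %*% Matrix::solve(A, v))
  D1 <- Matrix::bandSparse(n - 1L, n, k = 0:1,
                           diagonals = list(rep(-1, n - 1L), rep(1, n - 1L)))
  D2 <- Matrix::bandSparse(n - 2L, n, k = 0:2,
                           diagonals = list(rep(1, n - 2L), rep(-2, n - 2L),
                                            rep(1, n - 2L)))
  D <- rbind(D1, D2)
  BTB <- Matrix::crossprod(B)
  wvec <- c(rep(p$lam1, n - 1L), rep(p$lam2, n - 2L))
  bvec <- rep((1 - r) / 2, n)
  dvec <- as.vector(BTB %*% Matrix::solve(A, y)) -
    p$lam0 * as.vector(Matrix::crossprod(A, bvec))
  phi <- function(v) abs(v) - eps1 * log(abs(v) + eps1)
  wfun <- function(v) 1 / (abs(v) + eps1)
  theta <- function(v) {
    mid <- abs(v) <= eps0
    sum(v[v > eps0]) - r * sum(v[v < -eps0]) +
      sum((1 + r) / (4 * eps0) * v[mid]^2 + (1 - r) / 2 * v[mid] +
            eps0 * (1 + r) / 4)
  }
  objective <- function(x) {
    0.5 * sum(Hmul(y - x)^2) + p$lam0 * theta(x) +
      p$lam1 * sum(phi(diff(x))) + p$lam2 * sum(phi(diff(x, differences = 2)))
  }
  x <- y
  gam <- numeric(n)
  obj <- numeric(p$n_iter)
  obj_prev <- objective(x)
  for (it in seq_len(p$n_iter)) {
    Lam <- Matrix::Diagonal(x = wvec * wfun(as.vector(D %*% x)))
    big <- abs(x) > eps0
    gam[!big] <- (1 + r) / (4 * eps0)
    gam[big] <- (1 + r) / (4 * abs(x[big]))
    M <- 2 * p$lam0 * Matrix::Diagonal(x = gam) +
      Matrix::crossprod(D, Lam %*% D)
    S <- BTB + Matrix::crossprod(A, M %*% A)
    cand <- as.vector(A %*% Matrix::solve(S, dvec))
    if (any(!is.finite(cand))) {
      stop_numerical("BEADS solver produced non-finite iterates; solver diverged")
    }
    # safeguarded step: back-track toward the previous iterate if numerical
    # error in the ill-conditioned solve breaks the MM descent property
    alpha <- 1
    obj_cand <- objective(cand)
    while (obj_cand > obj_prev && alpha > 1e-4) {
      alpha <- alpha / 2
      obj_cand <- objective(x + alpha * (cand - x))
    }
    if (obj_cand > obj_prev) {
      obj[it:p$n_iter] <- obj_prev      # no improving step: stalled
      break
    }
    x <- x + alpha * (cand - x)
    obj[it] <- obj_cand
    obj_prev <- obj_cand
  }
  f <- y - x - Hmul(y - x)
  list(peaks = x, baseline = f, objective = obj)
}

#' Estimate and remove the baseline of a series signal adaptively
#'
#' The signal is shifted so its first sample is zero, then BEADS is run with
#' `lam0 = 1/sd(y)`, `lam1 = lam2 = 2 * lam0` and asymmetry `r = 1/var(y)`
#' (population denominators). If the estimated baseline overshoots the signal
#' (its maximum exceeds the signal maximum), one of the derivative weights is
#' doubled — alternately `lam1` then `lam2` — and the decomposition is
#' recomputed, up to `max_doublings` times.
#'
#' @param y Numeric signal (a `last_signal` tibble is also accepted).
#' @param params A [beads_params()]; `lam0`, `lam1`, `lam2` and `r` are
#'   overridden by the data-driven rule above.
#' @return A tibble of class `last_aligned` with columns `x`, `raw` (shifted
#'   input), `baseline`, `aligned` (`raw - baseline`), `peaks` and `gap`;
#'   attributes `params_used` and `doublings` (with a warning flag when the
#'   cap was exhausted).
#' @export
adaptive_baseline <- function(y, params = beads_params()) {
  gap <- NULL
  xs <- NULL
  if (inherits(y, "last_signal") || is.data.frame(y)) {
    gap <- y$gap
    xs <- y$x
    y <- y$y
  }
  if (length(y) < 16L) stop_validation("signal too short for baseline estimation")
  if (sd_n(y) == 0) stop_validation("constant signal: baseline is undefined")
  raw <- y - y[1]
  lam0 <- 1 / sd_n(raw)
  r <- 1 / var_n(raw)
  p <- params
  p$lam0 <- lam0; p$lam1 <- 2 * lam0; p$lam2 <- 2 * lam0; p$r <- r
  sol <- beads_solve(raw, p)
  doublings <- 0L
  exhausted <- FALSE
  while (max(sol$baseline) > max(raw)) {
    if (doublings >= p$max_doublings) {
      exhausted <- TRUE
      warn("adaptive baseline: doubling cap reached before the baseline was tamed")
      break
    }
    if (doublings %% 2L == 0L) p$lam1 <- 2 * p$lam1 else p$lam2 <- 2 * p$lam2
    doublings <- doublings + 1L
    sol <- beads_solve(raw, p)
  }
  out <- tibble(
    x = if (is.null(xs)) seq_along(raw) - 1L else xs,
    raw = raw,
    baseline = sol$baseline,
    aligned = raw - sol$baseline,
    peaks = sol$peaks,
    gap = if (is.null(gap)) FALSE else gap
  )
  class(out) <- c("last_aligned", class(out))
  attr(out, "params_used") <- p
  attr(out, "doublings") <- doublings
  attr(out, "doubling_cap_hit") <- exhausted
  out
}
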
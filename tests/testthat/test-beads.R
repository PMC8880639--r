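test_that("beads_solve handles trivial and invalid inputs", {
  z <- rep(0, 32)
  sol <- beads_solve(z, beads_params(fc = 0.01))
  expect_equal(max(abs(sol$peaks)), 0, tolerance = 1e-8)
  expect_equal(max(abs(sol$baseline)), 0, tolerance = 1e-8)
  expect_error(beads_solve(c(1, 2, 3)), class = "lastkit_validation_error")
  expect_error(beads_solve(c(rep(1, 20), NA_real_)),
               class = "lastkit_validation_error")
  expect_error(beads_params(fc = 0.7), class = "lastkit_validation_error")
  expect_error(beads_params(lam0 = -1), class = "lastkit_validation_error")
})

test_that("a slow sinusoid with no peaks is recovered as baseline", {
  n <- 1000
  y <- 10 * sin(2 * pi * seq_len(n) / n)
  p <- beads_params(fc = 5e-3, lam0 = 0.05, r = 10)
  sol <- beads_solve(y / max(abs(y)), p)
  rmse <- sqrt(mean((sol$baseline - y / max(abs(y)))^2))
  expect_lt(rmse, 0.05)
  expect_lt(max(abs(sol$peaks)), 0.1)
})

test_that("sinusoid baseline plus tent peaks separates into components", {
  set.seed(11)
  n <- 2000
  base <- 20 * sin(2 * pi * seq_len(n) / n)
  pk <- numeric(n)
  centres <- c(200, 600, 1000, 1400, 1800)
  for (c0 in centres) for (j in -25:25) {
    pk[c0 + j] <- max(pk[c0 + j], 50 * (1 - abs(j) / 25))
  }
  y <- base + pk + rnorm(n, 0, 0.4)
  sc <- max(abs(y - y[1]))
  yn <- (y - y[1]) / sc
  p <- beads_params(fc = 3e-3, lam0 = 0.02, r = 1 / lastkit:::var_n(yn))
  sol <- beads_solve(yn, p)
  rmse <- sqrt(mean((sol$baseline - (base - y[1]) / sc)^2)) / (20 / sc)
  expect_lt(rmse, 0.05)
  # peak estimate is concentrated where the tents are
  on_peak <- pk > 10
  expect_gt(mean(sol$peaks[on_peak]), 5 * mean(abs(sol$peaks[!on_peak])))
  # objective is non-increasing
  expect_true(all(diff(sol$objective) <= 1e-9))
})

test_that("adaptive_baseline conserves the signal and absorbs constants", {
  set.seed(9)
  y <- rnorm(500, 0, 0.01)
  a <- adaptive_baseline(y)
  expect_true(all(a$aligned + a$baseline == a$raw))   # exact, element-wise
  expect_lt(max(abs(a$baseline)), 3 * 0.01)
  # shift invariance: constant offsets are absorbed by the initial shift
  a2 <- adaptive_baseline(y + 57.3)
  expect_equal(a2$aligned, a$aligned, tolerance = 1e-6)
  # data-driven parameter rule (population denominators)
  p <- attr(a, "params_used")
  raw <- y - y[1]
  expect_equal(p$lam0, 1 / lastkit:::sd_n(raw))
  expect_equal(p$r, 1 / lastkit:::var_n(raw))
  expect_error(adaptive_baseline(rep(2, 100)),
               class = "lastkit_validation_error")
})

test_that("an overshooting baseline triggers the lambda doubling loop", {
  y <- c(rep(0, 50), -exp(-((1:100) - 50)^2 / 100), rep(0, 50))
  expect_warning(
    a <- adaptive_baseline(y, beads_params(fc = 0.01, d = 2)),
    "doubling cap"
  )
  expect_gte(attr(a, "doublings"), 1L)
  p <- attr(a, "params_used")
  expect_gt(p$lam1, 2 * p$lam0)
  expect_true(attr(a, "doubling_cap_hit"))
})

test_that("the MM iterate matches a general-purpose optimizer on a small problem", {
  # independent check of the objective minimization: compare the solver's
  # objective value against stats::optim (BFGS) from several starts
  set.seed(4)
  n <- 60
  y <- sin(2 * pi * seq_len(n) / n) + c(rep(0, 25), rep(1.5, 10), rep(0, 25)) +
    rnorm(n, 0, 0.05)
  p <- beads_params(fc = 0.02, lam0 = 0.3, lam1 = 0.6, lam2 = 0.6, r = 5,
                    n_iter = 120L)
  sol <- beads_solve(y, p)
  fl <- lastkit:::beads_filter(p$d, p$fc, n)
  H <- function(x) as.vector(fl$B %*% Matrix::solve(fl$A, x))
  eps <- p$eps
  theta <- function(v) {
    mid <- abs(v) <= eps
    sum(v[v > eps]) - p$r * sum(v[v < -eps]) +
      sum((1 + p$r) / (4 * eps) * v[mid]^2 + (1 - p$r) / 2 * v[mid] +
            eps * (1 + p$r) / 4)
  }
  phi <- function(v) abs(v) - eps * log(abs(v) + eps)
  fobj <- function(x) {
    0.5 * sum(H(y - x)^2) + p$lam0 * theta(x) +
      p$lam1 * sum(phi(diff(x))) + p$lam2 * sum(phi(diff(x, differences = 2)))
  }
  best_ref <- Inf
  for (start in list(y, rep(0, n), y / 2)) {
    o <- stats::optim(start, fobj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
    best_ref <- min(best_ref, o$value)
  }
  expect_lte(fobj(sol$peaks), best_ref * (1 + 1e-3))
})
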
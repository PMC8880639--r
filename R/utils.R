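# Internal helpers shared across modules.

stop_validation <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "lastkit_validation_error")
}

stop_io <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "lastkit_io_error")
}

stop_numerical <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "lastkit_numerical_error")
}

# Population (denominator N) standard deviation / variance.
sd_n <- function(x) sqrt(mean((x - mean(x))^2))
var_n <- function(x) mean((x - mean(x))^2)

# Linear resampling of a numeric vector to length `n`.
resample_linear <- function(v, n) {
  if (length(v) == n) return(v)
  if (length(v) == 1L) return(rep(v, n))
  approx(seq_along(v), v, xout = seq(1, length(v), length.out = n))$y
}

# Rescale to [0, 1]; constant vectors map to 0.
normalize01 <- function(v) {
  r <- range(v)
  if (diff(r) <= 0) return(rep(0, length(v)))
  (v - r[1]) / diff(r)
}

# Shoelace area of a polygon given as a two-column matrix of vertices.
polygon_area <- function(p) {
  n <- nrow(p)
  i2 <- c(2:n, 1)
  abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2
}
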
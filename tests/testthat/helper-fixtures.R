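# Shared fixture builders. Everything is generated in code at test time.

# A small, fast generator spec (4 examinee characters, ~60-px characters).
small_spec <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_chars = 4L, examiner_n = 3L,
         char_width_mean = 60, char_height_mean = 50,
         width_jitter_sd = 2, height_jitter_sd = 2,
         stroke_width = 3, noise_sd = 0, speckle_rate = 0,
         drift_amplitude = 2, seed = seed),
    list(...)
  )
  do.call(synthetic_spec, args)
}

# An ideal tent (triangle) character signal of a given width/height.
tent_signal <- function(width = 60L, height = 50) {
  half <- (width - 1) / 2
  v <- height * (1 - abs(seq_len(width) - 1 - half) / half)
  character_signal(v, 0L, width)
}

# An ideal plateau (open rectangle) signal: ramps up/down over `edge`
# columns at the sides, flat at `height` in between.
plateau_signal <- function(width = 60L, height = 50, edge = 2L) {
  v <- rep(height, width)
  v[seq_len(edge)] <- height * seq_len(edge) / (edge + 1)
  v[width + 1 - seq_len(edge)] <- height * seq_len(edge) / (edge + 1)
  character_signal(v, 0L, width)
}

# A filled axis-aligned block mask as a character ROI.
block_roi <- function(w = 40L, h = 20L, index = 0L) {
  character_roi(matrix(TRUE, h, w), c(0L, w, 0L, h), index = index)
}

# An open-rectangle stroke mask (top + two sides), stroke thickness `t`.
open_rect_mask <- function(w = 60L, h = 50L, t = 3L) {
  m <- matrix(FALSE, h, w)
  m[seq_len(t), ] <- TRUE                 # top stroke
  m[, seq_len(t)] <- TRUE                 # left stroke
  m[, w + 1 - seq_len(t)] <- TRUE         # right stroke
  m
}

# An open-triangle (tent) stroke mask.
tent_mask <- function(w = 61L, h = 50L, t = 2L) {
  m <- matrix(FALSE, h, w)
  half <- (w - 1) / 2
  for (x in seq_len(w)) {
    y <- round(h * (1 - abs(x - 1 - half) / half))
    rows <- (h - y + 1):min(h, h - y + t)
    rows <- rows[rows >= 1 & rows <= h]
    m[rows, x] <- TRUE
  }
  m
}

# Random convex-position point set with at least 3 hull vertices.
random_points <- function(n = 8L, lim = 3) {
  repeat {
    pts <- matrix(runif(2L * n, -lim, lim), ncol = 2)
    if (length(grDevices::chull(pts)) >= 3L) return(pts)
  }
}

# A three-group feature table of iid Gaussian features.
null_feature_table <- function(n_per_group = 20L, n_features = 10L) {
  tab <- tibble::tibble(group = rep(c("CON", "PD", "PSP"),
                                    each = n_per_group))
  for (f in seq_len(n_features)) tab[[paste0("f", f)]] <- rnorm(3L * n_per_group)
  tab
}
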
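# Shared fixtures: analytic disk phantoms and a small, fast fan geometry.

# disk with 4x supersampled (anti-aliased) edge so rasters approximate the
# continuous disk that analytic oracles describe
make_disk <- function(n = 96, r = 25, mu = 1, pixel_size = 1) {
  ctr <- (n + 1) / 2
  sub <- c(-0.375, -0.125, 0.125, 0.375)
  cov <- matrix(0, n, n)
  for (dx in sub) for (dy in sub) {
    d <- outer(seq_len(n) - ctr + dy, seq_len(n) - ctr + dx,
               function(a, b) sqrt(a^2 + b^2))
    cov <- cov + (d <= r)
  }
  image_grid(cov / 16 * mu, pixel_size, c(0, mu))
}

small_geom <- function(n = 96, views = 240) {
  default_fan_geometry(n, n_views = views)
}

# radial distance map of a square image, in pixels
radius_map <- function(n) {
  ctr <- (n + 1) / 2
  outer(seq_len(n) - ctr, seq_len(n) - ctr, function(a, b) sqrt(a^2 + b^2))
}

expect_rel_equal <- function(actual, expected, tol = 1e-6) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-12), tol)
}
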
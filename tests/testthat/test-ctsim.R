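test_that("projection of a zero image is zero and the operator is linear", {
  g <- small_geom(64, 60)
  zero <- image_grid(matrix(0, 64, 64))
  expect_true(all(forward_project(zero, g)$values == 0))

  a <- make_ellipse_phantom(phantom_spec(seed = 1, size = 64))
  b <- make_ellipse_phantom(phantom_spec(seed = 2, size = 64))
  ab <- image_grid(a$pixels + b$pixels, 1, c(0, 2))
  sa <- forward_project(a, g)$values
  sb <- forward_project(b, g)$values
  sab <- forward_project(ab, g)$values
  expect_lt(max(abs(sab - (sa + sb))), 1e-9)
  # nonnegativity for nonnegative images
  expect_true(all(sa >= -1e-12))
})

test_that("fan-beam projection reproduces analytic disk chords within 1%", {
  n <- 96; r <- 25
  disk <- make_disk(n, r)
  g <- small_geom(n, 40)
  sino <- forward_project(disk, g)
  dsd <- g$source_iso + g$iso_det
  s <- (seq_len(g$n_det) - (g$n_det + 1) / 2) * g$det_pitch
  # perpendicular distance of each ray from the isocenter
  t_iso <- g$source_iso * s / sqrt(dsd^2 + s^2)
  central <- which(abs(t_iso) < 0.6 * r)
  chord <- 2 * sqrt(r^2 - t_iso[central]^2)
  for (v in c(1, 11, 27)) {
    rel <- abs(sino$values[v, central] - chord) / (2 * r)
    expect_lt(max(rel), 0.01)
  }
})

test_that("truncation keeps the stated number of centred channels", {
  g <- fan_geometry(n_views = 4, source_iso = 100, iso_det = 100,
                    n_det = 1000, det_pitch = 0.3)
  sino <- sinogram(matrix(1, 4, 1000), g)
  tr <- truncate_sinogram(sino, 0.3)
  expect_equal(ncol(tr$values), 700)
  expect_equal(tr$retained, c(151L, 850L))
  # ratio 0 is the identity
  expect_identical(truncate_sinogram(sino, 0)$values, sino$values)
  expect_error(truncate_sinogram(sino, 1), "ratio")
  expect_error(truncate_sinogram(sinogram(matrix(1, 4, 10),
    fan_geometry(4, 100, 100, 10, 0.3)), 0.5), "8 channels")
})

test_that("truncation removes the disk's outer chords in every view", {
  disk <- make_disk(96, 38)
  g <- small_geom(96, 40)
  full <- forward_project(disk, g)
  tr <- truncate_sinogram(full, 0.5)
  expect_true(all(dim(tr$values) == c(40, round(0.5 * g$n_det))))
  # census of the untruncated sinogram: every view had nonzero signal in
  # the deleted channels (the disk out-spans the retained FOV), so every
  # view loses part of its line-integral mass
  removed_cols <- setdiff(seq_len(g$n_det), tr$retained[1]:tr$retained[2])
  removed_mass <- rowSums(full$values[, removed_cols, drop = FALSE])
  expect_true(all(removed_mass > 0))
  expect_true(all(rowSums(tr$values) < rowSums(full$values)))
})

test_that("FBP is linear at zero and accurate on an untruncated disk", {
  g <- small_geom(96, 240)
  zero_sino <- sinogram(matrix(0, 240, g$n_det), g)
  expect_true(all(fbp_reconstruct(zero_sino, 64)$pixels == 0))

  disk <- make_disk(96, 25)
  rec <- fbp_reconstruct(forward_project(disk, g), 96)
  # interior RMSE below 5% of mu, excluding a 2-pixel edge band
  rr <- radius_map(96) * rec$pixel_size
  interior <- rr <= (25 - 2)
  expect_lt(sqrt(mean((rec$pixels[interior] - 1)^2)), 0.05)
})

test_that("truncated FBP shows centre-to-edge cupping that grows with ratio", {
  ph <- make_ellipse_phantom(phantom_spec(seed = 3, size = 96,
                                          n_inclusions = 3))
  g <- small_geom(96, 240)
  outer_minus_central <- function(ratio) {
    pr <- simulate_truncated_pair(ph, g, ratio, 96)
    prof <- radial_bias_profile(pr$artifact, pr$reference, 10)
    c(outer = prof[10], central = prof[1])
  }
  b30 <- outer_minus_central(0.3)
  b50 <- outer_minus_central(0.5)
  expect_gt(b30["outer"], b30["central"])
  expect_gt(b50["outer"], b50["central"])
  # cupping monotone in the truncation ratio
  expect_gte(b50["outer"] - b50["central"], b30["outer"] - b30["central"])
})

test_that("simulated pairs are pixel-aligned and degrade with truncation", {
  ph <- make_ellipse_phantom(phantom_spec(seed = 5, size = 96,
                                          n_inclusions = 3))
  g <- small_geom(96, 240)
  pr0 <- simulate_truncated_pair(ph, g, 0, 96)
  rr <- radius_map(96) * pr0$artifact$pixel_size
  interior <- rr <= 0.9 * max(rr[inscribed_mask(96)])
  expect_lt(sqrt(mean((pr0$artifact$pixels - pr0$reference$pixels)[interior]^2)),
            0.05)
  pr3 <- simulate_truncated_pair(ph, g, 0.3, 96)
  mk <- inscribed_mask(96)
  expect_lt(ssim(pr3$reference, pr3$artifact, mask = mk),
            ssim(pr0$reference, pr0$artifact, mask = mk))
})

test_that("resampling onto the same grid reproduces the phantom", {
  ph <- make_ellipse_phantom(phantom_spec(seed = 5, size = 64))
  rs <- resample_to_grid(ph, 64, 1)
  expect_equal(rs$pixels, ph$pixels, tolerance = 1e-9)
})

test_that("sinogram TSV round trip preserves values and geometry", {
  disk <- make_disk(64, 20)
  g <- small_geom(64, 30)
  sino <- truncate_sinogram(forward_project(disk, g), 0.3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sinogram(sino, f)
  back <- read_sinogram(f)
  expect_equal(back$values, sino$values, tolerance = 1e-9)
  expect_equal(back$retained, sino$retained)
  expect_equal(back$geometry$n_det, sino$geometry$n_det)
})
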
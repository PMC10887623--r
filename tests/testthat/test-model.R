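tiny_model <- function(bc = 4, seed = 1, use_polar = TRUE) {
  build_model(net_config(base_channels = bc, seed = seed), use_polar)
}

test_that("architecture counts match the stated design", {
  m <- tiny_model()
  expect_length(m$encoder$layers, 5)
  expect_length(m$dec_content$layers, 5)
  expect_length(m$dec_full$layers, 5)
  n_resample <- function(net) sum(vapply(net$layers, function(l) l$s == 2, NA))
  expect_equal(n_resample(m$encoder), 3)
  expect_equal(n_resample(m$dec_content), 3)
  expect_equal(n_resample(m$dec_full), 3)
  # G and Gt have separate weights
  expect_false(identical(m$dec_content$layers[[1]]$par$W,
                         m$dec_full$layers[[1]]$par$W))
})

test_that("encoder halves resolution three times; decoders mirror it", {
  m <- tiny_model()
  x <- matrix(rnorm(64 * 32), 64, 32)
  l <- encode(m, x)
  expect_equal(dim(l)[1:2], c(8, 4))
  expect_equal(dim(l)[3], 4 * m$cfg$base_channels)
  y <- decode_content(m, l)
  expect_equal(dim(y), c(64, 32))
  expect_true(all(abs(y) < 1))               # tanh-bounded output
  yt <- decode_full(m, l)
  expect_equal(dim(yt), c(64, 32))
  expect_true(all(abs(yt) < 1))
  expect_error(encode(m, matrix(0, 60, 32)), "divisible")
})

test_that("encoding is deterministic and finite", {
  m <- tiny_model()
  set.seed(5)
  x <- matrix(rnorm(64 * 32), 64, 32)
  expect_identical(encode(m, x), encode(m, x))
  expect_true(all(is.finite(encode(m, x))))
  b <- forward_cycle(m, x, matrix(rnorm(64 * 32), 64, 32))
  for (nm in c("I_hat_p", "I_tilde_pt", "J_tilde_p", "J_hat_pt", "J_hat_p"))
    expect_true(all(is.finite(b[[nm]])), info = nm)
})

test_that("artifact-code identity holds exactly", {
  m <- tiny_model()
  set.seed(6)
  I <- matrix(rnorm(64 * 32), 64, 32); J <- matrix(rnorm(64 * 32), 64, 32)
  b <- forward_cycle(m, I, J)
  # t_I + E(I_hat_p) == l_I (exact up to one floating-point rounding)
  expect_equal(b$t_I + b$l_Ihat, b$l_I, tolerance = 1e-14)
  # matches an elementwise loop and the exported operation
  t2 <- extract_artifact_code(m, b$l_I, b$I_hat_p)
  naive <- b$l_I
  for (ii in seq_along(naive)) naive[ii] <- b$l_I[ii] - b$l_Ihat[ii]
  expect_equal(t2, naive, tolerance = 1e-12)
  # self-cancellation: encoding the image whose encoding is l_I gives t = 0
  t0 <- extract_artifact_code(m, encode(m, b$I_hat_p), b$I_hat_p)
  expect_true(all(t0 == 0))
})

test_that("zero artifact code reduces synthesis to self-reconstruction", {
  m <- tiny_model()
  set.seed(7)
  J <- matrix(rnorm(64 * 32), 64, 32)
  lJ <- encode(m, J)
  expect_identical(synthesize_artifacted(m, array(0, dim(lJ)), lJ),
                   decode_full(m, lJ))
  expect_error(synthesize_artifacted(m, array(0, c(2, 2, 2)), lJ), "shape")
})

test_that("the single shared encoder serves every encoding in the cycle", {
  m <- tiny_model()
  set.seed(8)
  I <- matrix(rnorm(64 * 32), 64, 32); J <- matrix(rnorm(64 * 32), 64, 32)
  b <- forward_cycle(m, I, J)
  expect_identical(b$l_I, encode(m, I))
  expect_identical(b$l_J, encode(m, J))
  expect_identical(b$l_Ihat, encode(m, b$I_hat_p))
  expect_identical(b$l_Jhat, encode(m, b$J_hat_pt))
  # and the final image is the content decoding of that shared encoding
  expect_identical(b$J_hat_p, decode_content(m, encode(m, b$J_hat_pt)))
})

test_that("discriminator scores one patch per input/16 region and is local", {
  m <- tiny_model()
  x <- matrix(rnorm(64 * 32), 64, 32)
  s <- discriminate(m, x, "D")
  expect_equal(dim(s), c(4, 2))
  # locality: perturbing one 8x8 corner moves nearby scores far more than
  # distant ones (instance normalization couples all patches weakly, so
  # the comparison is relative, not absolute)
  m2 <- tiny_model(bc = 2)
  set.seed(99)
  big <- matrix(rnorm(128 * 128), 128, 128)
  s1 <- discriminate(m2, big, "Dt")
  pert <- big; pert[1:8, 1:8] <- pert[1:8, 1:8] + 5
  s2 <- discriminate(m2, pert, "Dt")
  d <- abs(s2 - s1)
  expect_gt(max(d[1:3, 1:3]), 5 * max(d[6:8, 6:8]))
})

test_that("circular angular padding keeps encodings seam-free", {
  m <- tiny_model()
  ph <- make_ellipse_phantom(phantom_spec(seed = 9, size = 64,
                                          n_inclusions = 3))
  p <- to_polar(ph, n_rho = 32, n_phi = 64)
  x <- 2 * p$values - 1
  l1 <- encode(m, x)
  # rolling the angle rows by one latent step (8 rows) rolls the latent
  xr <- x[c(9:64, 1:8), ]
  l2 <- encode(m, xr)
  l1r <- l1[c(2:8, 1), , , drop = FALSE]
  rmse <- sqrt(mean((l2 - l1r)^2))
  expect_lt(rmse, 0.05 * diff(range(l1)))
})

test_that("weight initialization is seeded and reproducible", {
  m1 <- tiny_model(seed = 3); m2 <- tiny_model(seed = 3)
  expect_identical(m1$encoder$layers[[2]]$par$W, m2$encoder$layers[[2]]$par$W)
  m3 <- tiny_model(seed = 4)
  expect_false(identical(m1$encoder$layers[[2]]$par$W,
                         m3$encoder$layers[[2]]$par$W))
})

test_that("checkpoint save/load round trips the model", {
  m <- tiny_model()
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, f, window = c(-0.1, 1.2), extra = list(note = "x"))
  ck <- load_checkpoint(f)
  expect_equal(ck$window, c(-0.1, 1.2))
  set.seed(10)
  x <- matrix(rnorm(64 * 32), 64, 32)
  expect_identical(encode(ck$model, x), encode(m, x))
})
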